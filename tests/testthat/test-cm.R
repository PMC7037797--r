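test_that("annealing ladders pin their endpoints and are geometric", {
  s <- make_schedule(3000, 310, 18)
  expect_equal(nrow(s), 18)
  expect_equal(s$temperature[1], 3000)
  expect_equal(s$temperature[18], 310)
  # geometric: constant ratio
  expect_equal(sd(diff(log(s$temperature))), 0, tolerance = 1e-12)
  s2 <- make_schedule(749.4, 310, 9)
  expect_equal(nrow(s2), 9)
  expect_equal(range(s2$temperature), c(310, 749.4))
  s3 <- make_schedule(310, 310, 5)
  expect_true(all(s3$temperature == 310))
  expect_error(make_schedule(3000, 310, 1), "t_start == t_end")
  expect_error(make_schedule(100, 310, 5), "t_start >= t_end")
})

test_that("Metropolis acceptance follows the Boltzmann factor", {
  set.seed(1)
  expect_true(all(replicate(50, metropolis_accept(-5, 310))))
  # analytic identity: dE = kT ln 2 accepts half the time
  de <- 0.0019872 * 310 * log(2)
  acc <- mean(replicate(2e4, metropolis_accept(de, 310)))
  expect_equal(acc, 0.5, tolerance = 0.02 / 0.5)
  acc2 <- mean(replicate(2e4, metropolis_accept(1, 310)))
  expect_equal(acc2, exp(-1 / 0.61603), tolerance = 0.025)
  expect_error(metropolis_accept(NaN, 310), "finite")
  expect_error(metropolis_accept(1, 0), "positive")
})

test_that("a move changes exactly two free dihedrals and one bond angle", {
  h <- build_ideal_helix(strrep("A", 26))
  sp <- hinge_spec(h, 17)
  expect_equal(nrow(sp$dihedrals), 10)  # phi+psi of 5 residues
  expect_length(sp$region, 5)
  set.seed(5)
  for (rep in 1:5) {
    h2 <- propose_move(h, sp)
    ic1 <- internal_coords(h)
    ic2 <- internal_coords(h2)
    d <- abs(helixcm:::wrap_angle(c(ic2$phi - ic1$phi, ic2$psi - ic1$psi)))
    expect_equal(sum(d > 1e-6, na.rm = TRUE), 2)
    expect_equal(sum(abs(ic2$tau - ic1$tau) > 1e-6), 1)
    expect_true(all(abs(helixcm:::wrap_angle(ic2$omega - ic1$omega)) < 1e-6,
                    na.rm = TRUE))
    # untouched residues keep their coordinates
    pre <- helix_coords(h, residues = 1:10)
    expect_equal(helix_coords(h2, residues = 1:10), pre, tolerance = 1e-9)
  }
})

test_that("proline hinges get the proline dihedral windows with omega freed", {
  h <- build_ideal_helix(c(rep("ALA", 10), "PRO", rep("ALA", 6)))
  sp <- hinge_spec(h, 11)
  pro <- sp$dihedrals[sp$dihedrals$residue_index == 11, ]
  expect_setequal(pro$name, c("phi", "psi", "omega"))
  expect_equal(pro$lo[pro$name == "phi"], -120)
  expect_equal(pro$hi[pro$name == "phi"], 40)
  expect_equal(pro$lo[pro$name == "psi"], -70)
  expect_equal(unlist(pro[pro$name == "omega", c("lo", "hi")]),
               c(lo = -160, hi = 160))
  set.seed(2)
  for (rep in 1:20) {
    h2 <- propose_move(h, sp)
    ic <- internal_coords(h2)
    expect_gt(ic$phi[11], -120)
    expect_lt(ic$phi[11], 40)
  }
})

test_that("biased proposals stay inside the retained memory bins", {
  h <- build_ideal_helix(strrep("A", 14))
  sp <- hinge_spec(h, 9)
  mem <- tidyr::crossing(sp$dihedrals[, c("residue_index", "name")],
                         tibble::tibble(bin_start = 55, bin_end = 65,
                                        count = 1L, retained = TRUE))
  set.seed(3)
  for (rep in 1:10) {
    h2 <- propose_move(h, sp, memory = mem)
    ic <- internal_coords(h2)
    changed <- c(ic$phi, ic$psi)
    changed <- changed[!is.na(changed) &
                         abs(helixcm:::wrap_angle(changed + 63)) > 1e-6 &
                         abs(helixcm:::wrap_angle(changed + 42)) > 1e-6]
    expect_true(all(changed >= 55 & changed <= 65))
  }
  empty <- mem
  empty$retained <- FALSE
  expect_error(propose_move(h, sp, memory = empty), "retention threshold")
})

test_that("a flat energy surface samples dihedrals uniformly", {
  h <- build_ideal_helix(strrep("A", 12))
  sp <- hinge_spec(h, 7)
  sp$dihedrals <- sp$dihedrals[sp$dihedrals$residue_index == 7 &
                                 sp$dihedrals$name == "psi", ]
  ch <- sample_fixed_temperature(h, sp, flat_ff(), temperature = 310,
                                 n_steps = 5e4, seed = 4)
  x <- ch[[1]]
  counts <- table(cut(x, breaks = seq(-180, 180, by = 30)))
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})

test_that("fixed-temperature sampling recovers the Boltzmann marginal", {
  h <- build_ideal_helix(strrep("A", 12))
  sp <- hinge_spec(h, 7)
  sp$dihedrals <- sp$dihedrals[sp$dihedrals$residue_index == 7 &
                                 sp$dihedrals$name == "psi", ]
  ch <- sample_fixed_temperature(h, sp, torsion_only_ff(), temperature = 310,
                                 n_steps = 2e4, seed = 11)
  beta <- 1 / (0.0019872 * 310)
  grid <- seq(-180, 180, by = 0.05)
  dens <- exp(-beta * (1 + cos(3 * grid * pi / 180)))
  cdf <- cumsum(dens / sum(dens))
  ks <- suppressWarnings(ks.test(ch[[1]], approxfun(grid, cdf)))
  expect_lt(as.numeric(ks$statistic), 0.05)
})

test_that("acceptance rate does not increase as temperature drops", {
  h <- build_ideal_helix(strrep("A", 12))
  sp <- hinge_spec(h, 7)
  rates <- sapply(1:4, function(seed) {
    sapply(c(3000, 1000, 310), function(T) {
      ch <- sample_fixed_temperature(h, sp, default_forcefield(),
                                     temperature = T, n_steps = 3000,
                                     seed = seed, record_stride = 0)
      attr(ch, "acceptance_rate")
    })
  })
  avg <- rowMeans(rates)
  expect_true(all(diff(avg) <= 0))
})

test_that("the two-phase run emits the requested ensemble and memory map", {
  h <- build_ideal_helix(strrep("A", 20))
  sp <- hinge_spec(h, 13)
  run <- run_cm(h, sp, exploratory = quick_explore(), biased = quick_biased(),
                n_output = 25, seed = 7)
  expect_length(run$ensemble, 25)
  expect_equal(nrow(run$energies), 25)
  expect_true(all(run$memory$count >= 0))
  # per-dihedral counts sum to the number of accepted exploratory states
  tot <- sum(run$acceptance$accepted[run$acceptance$phase == "exploratory"])
  per_dih <- dplyr::summarise(
    dplyr::group_by(run$memory, residue_index, name),
    n = sum(count), .groups = "drop")
  expect_true(all(per_dih$n == tot))
  # retained bins all carry population
  expect_true(all(run$memory$count[run$memory$retained] > 0))
  g <- glance(run)
  expect_equal(g$n_conformers, 25)
  expect_equal(nrow(tidy(run)), 25)
})

test_that("biased-phase samples fall inside the exploratory retained support", {
  h <- build_ideal_helix(strrep("A", 20))
  sp <- hinge_spec(h, 13)
  run <- run_cm(h, sp, exploratory = quick_explore(), biased = quick_biased(),
                n_output = 40, seed = 19)
  ics <- lapply(run$ensemble, internal_coords)
  for (k in seq_len(nrow(sp$dihedrals))) {
    ri <- sp$dihedrals$residue_index[k]
    nm <- sp$dihedrals$name[k]
    bins <- run$memory[run$memory$residue_index == ri &
                         run$memory$name == nm & run$memory$retained, ]
    vals <- vapply(ics, function(ic) ic[[nm]][ic$residue_index == ri],
                   numeric(1))
    inside <- vapply(vals, function(v) {
      any(v >= bins$bin_start - 1e-6 & v <= bins$bin_end + 1e-6)
    }, logical(1))
    expect_true(all(inside))
  }
})

test_that("identical seeds reproduce a run bit for bit", {
  h <- build_ideal_helix(strrep("A", 20))
  sp <- hinge_spec(h, 13)
  r1 <- run_cm(h, sp, exploratory = quick_explore(), biased = quick_biased(),
               n_output = 10, seed = 3)
  r2 <- run_cm(h, sp, exploratory = quick_explore(), biased = quick_biased(),
               n_output = 10, seed = 3)
  expect_identical(r1$energies, r2$energies)
  expect_identical(r1$ensemble, r2$ensemble)
  expect_identical(r1$memory, r2$memory)
})

test_that("ensembles superpose exactly on their anchor segment", {
  h <- build_ideal_helix(strrep("A", 20))
  copies <- list(h, random_rigid_motion(h, 1), random_rigid_motion(h, 2))
  sup <- superpose_ensemble(copies, anchor = 3:18)
  r <- trajectory_rmsd(sup, residues = 3:18, atoms = c("N", "CA", "C"))
  expect_true(all(r$rmsd < 1e-6))
  expect_error(superpose_ensemble(copies, anchor = 1:2), "at least 3")
})

test_that("superposition preserves distal spread while zeroing the anchor", {
  k1 <- build_kinked_helix(strrep("A", 25), hinge = 13, bend = 20, wobble = 0)
  k2 <- build_kinked_helix(strrep("A", 25), hinge = 13, bend = 20, wobble = 120)
  frames <- list(k1$helix, random_rigid_motion(k2$helix, 5))
  sup <- superpose_ensemble(frames, anchor = 1:13)
  anchor_rmsd <- trajectory_rmsd(sup, residues = 1:13, atoms = c("N", "CA", "C"))
  expect_lt(anchor_rmsd$rmsd[2], 0.2)
  distal <- trajectory_rmsd(sup, residues = 20:25, superpose = FALSE)
  expect_gt(distal$rmsd[2], 2)
})

test_that("memory maps serialise as TSV", {
  h <- build_ideal_helix(strrep("A", 20))
  sp <- hinge_spec(h, 13)
  run <- run_cm(h, sp, exploratory = quick_explore(), biased = quick_biased(),
                n_output = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_memory_map(run$memory, f)
  d <- read.delim(f)
  expect_named(d, c("dihedral", "bin_start", "bin_end", "count", "retained"))
  expect_equal(nrow(d), nrow(run$memory))
})
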