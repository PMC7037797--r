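two_atom_complex <- function(r, q1 = 1, q2 = 1, eps = 0, rmin = 3.9) {
  list(atoms = tibble::tibble(
    residue_index = c(1L, 2L), residue_name = c("LIG", "PCK"),
    chain = c("L", "A"), atom = c("L1", "P1"), element = "C",
    x = c(0, r), y = 0, z = 0),
    ff = forcefield(charges = c("LIG:L1" = q1, "PCK:P1" = q2),
                    lj = list(C = c(eps = eps, rmin = rmin)),
                    dielectric = list(model = "distance", coefficient = 2)))
}

test_that("Coulomb term matches the closed form under eps(r) = 2r", {
  tc <- two_atom_complex(3.32)
  e <- evaluate_energy(tc$atoms, tc$ff, group_a = 1, group_b = 2)
  expect_equal(e$coulomb, 332.0636 / (2 * 3.32^2), tolerance = 1e-12)
  expect_equal(e$total, e$torsional + e$lennard_jones + e$coulomb,
               tolerance = 1e-10)
})

test_that("Lennard-Jones equals -eps exactly at r_min and pairs beyond cutoffs vanish", {
  tc <- two_atom_complex(3.9, q1 = 0, q2 = 0, eps = 0.2)
  e <- evaluate_energy(tc$atoms, tc$ff, group_a = 1, group_b = 2)
  expect_equal(e$lennard_jones, -0.2, tolerance = 1e-12)
  far <- two_atom_complex(25)
  e2 <- evaluate_energy(far$atoms, far$ff, group_a = 1, group_b = 2,
                        cutoff_elec = 20)
  expect_equal(e2$coulomb, 0)
})

test_that("group-pair energy is symmetric and invariant under rigid motion", {
  set.seed(1)
  atoms <- tibble::tibble(
    residue_index = rep(1:2, each = 3), residue_name = rep(c("LIG", "PCK"), each = 3),
    chain = rep(c("L", "A"), each = 3),
    atom = c("L1", "L2", "L3", "P1", "P2", "P3"), element = "C",
    x = rnorm(6, sd = 2), y = rnorm(6, sd = 2), z = rnorm(6, sd = 2) + 4)
  ff <- forcefield(charges = setNames(runif(6, -1, 1),
                                      paste0(rep(c("LIG:L", "PCK:P"), each = 3), 1:3)),
                   lj = list(C = c(eps = 0.1, rmin = 3.8)))
  eab <- evaluate_energy(atoms, ff, group_a = 1:3, group_b = 4:6)
  eba <- evaluate_energy(atoms, ff, group_a = 4:6, group_b = 1:3)
  expect_equal(eab$total, eba$total, tolerance = 1e-12)
  moved <- random_rigid_motion(atoms, seed = 9)
  em <- evaluate_energy(moved, ff, group_a = 1:3, group_b = 4:6)
  expect_equal(em$total, eab$total, tolerance = 1e-8)
})

test_that("with infinite cutoffs and constant dielectric Coulomb matches a direct double loop", {
  set.seed(3)
  n <- 8
  atoms <- tibble::tibble(
    residue_index = 1:n, residue_name = "PCK", chain = "A",
    atom = paste0("P", 1:n), element = "C",
    x = rnorm(n, sd = 3), y = rnorm(n, sd = 3), z = rnorm(n, sd = 3))
  q <- runif(n, -1, 1)
  ff <- forcefield(charges = setNames(q, paste0("PCK:P", 1:n)),
                   lj = list(C = c(eps = 0, rmin = 3.9)),
                   dielectric = list(model = "constant", coefficient = 4))
  e <- evaluate_energy(atoms, ff, cutoff_nb = Inf, cutoff_elec = Inf,
                       bonds = matrix(0L, 0, 2))
  # brute-force oracle
  oracle <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((atoms[i, c("x", "y", "z")] - atoms[j, c("x", "y", "z")])^2))
    oracle <- oracle + 332.0636 * q[i] * q[j] / (4 * r)
  }
  expect_equal(e$coulomb, oracle, tolerance = 1e-12)
})

test_that("1-2 and 1-3 bonded pairs are excluded from nonbonded sums", {
  h <- build_ideal_helix("AAA")
  ff <- default_forcefield()
  e_all <- evaluate_energy(h, ff, bonds = matrix(0L, 0, 2))
  e_excl <- evaluate_energy(h, ff)
  # exclusions remove the strongly repulsive short-range bonded pairs
  expect_lt(e_excl$total, e_all$total)
})

test_that("parameter errors name the offending atom and singularities are caught", {
  tc <- two_atom_complex(3)
  ff_noq <- forcefield(charges = c("LIG:L1" = 1),
                       lj = list(C = c(eps = 0, rmin = 3.9)))
  expect_error(evaluate_energy(tc$atoms, ff_noq, group_a = 1, group_b = 2),
               "PCK, P1")
  tc0 <- two_atom_complex(0)
  expect_error(evaluate_energy(tc0$atoms, tc0$ff, group_a = 1, group_b = 2),
               "singularity")
  expect_error(evaluate_energy(tc$atoms, tc$ff, cutoff_nb = -1), "positive")
})

test_that("torsion series evaluates the cosine closed form", {
  terms <- data.frame(amplitude = 1, periodicity = 3, phase = 0)
  expect_equal(torsion_energy(180, terms), 0, tolerance = 1e-12)
  expect_equal(torsion_energy(0, terms), 2, tolerance = 1e-12)
  # minima located by dense circular grid search
  grid <- seq(-180, 179.95, by = 0.05)
  e <- torsion_energy(grid, terms)
  n <- length(e)
  is_min <- e < e[c(n, seq_len(n - 1))] & e < e[c(seq_len(n - 1) + 1, 1)]
  expect_equal(sort(round(grid[is_min])), c(-180, -60, 60))  # 180 == -180
  # periodicity 360/gcd
  expect_equal(torsion_energy(13, terms), torsion_energy(13 + 120, terms),
               tolerance = 1e-12)
  expect_error(torsion_energy(0, data.frame()), "empty")
})

test_that("force-field files round trip through the YAML format", {
  ff <- default_forcefield()
  expect_equal(ff$lj$N[["rmin"]], 3.45)
  expect_equal(ff$dielectric$model, "distance")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("charges:", "  \"*:*\": 0.5", "lj:", "  \"C\": [0.1, 3.8]",
               "torsions:", "  phi:", "    - [1.0, 2, 90.0]",
               "dielectric:", "  model: constant", "  coefficient: 2.0"), f)
  ff2 <- read_forcefield(f)
  expect_equal(unname(ff2$charges["*:*"]), 0.5)
  expect_equal(ff2$torsions$phi$periodicity, 2)
  expect_equal(ff2$dielectric$coefficient, 2)
})
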