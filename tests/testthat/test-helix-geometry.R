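test_that("axis fitting recovers the construction axis of an ideal helix", {
  h <- build_ideal_helix(strrep("A", 20))
  ax <- fit_helix_axis(h)
  expect_lt(ax$residual, 0.1)
  # independent oracle: the true axis is the screw axis of the rigid
  # transform mapping each CA onto the next (rotation eigenvector)
  ca <- helix_coords(h, atoms = "CA")
  a <- ca[1:19, ]; b <- ca[2:20, ]
  s <- svd(t(sweep(a, 2, colMeans(a))) %*% sweep(b, 2, colMeans(b)))
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  ev <- eigen(R)
  screw <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  screw <- screw / sqrt(sum(screw^2))
  ang <- acos(abs(sum(ax$direction * screw))) * 180 / pi
  expect_lt(ang, 1)
  expect_error(fit_helix_axis(helix_coords(h, atoms = "CA")[1:4, ]),
               "at least 5")
})

test_that("fitted axes are equivariant under rotation", {
  h <- build_ideal_helix(strrep("A", 15))
  ax <- fit_helix_axis(h)
  R <- helixcm:::rotation_matrix(c(1, 2, 3), 77)
  hr <- h
  xyz <- as.matrix(h[, c("x", "y", "z")]) %*% t(R)
  hr$x <- xyz[, 1]; hr$y <- xyz[, 2]; hr$z <- xyz[, 3]
  axr <- fit_helix_axis(hr)
  expect_equal(axr$direction, as.numeric(R %*% ax$direction),
               tolerance = 1e-6)
})

test_that("a collinear trace is flagged degenerate", {
  ca <- cbind(seq(0, 10, length.out = 8), 0, 0)
  expect_warning(ax <- fit_helix_axis(ca), "collinear")
  expect_true(ax$degenerate)
  expect_lt(ax$residual, 1e-8)
})

test_that("a straight helix shows no kink", {
  h <- build_ideal_helix(strrep("A", 25))
  g <- compute_kink(h, 13)
  expect_lt(g$bend, 1)
  expect_lt(abs(g$face_shift), 2)
  expect_false(g$wobble_reliable)
  expect_error(compute_kink(h, 3), "terminus")
})

test_that("constructed kinks are recovered across the bend/face-shift grid", {
  for (b in c(5, 20, 40)) {
    for (fs in c(0, -30, 90)) {
      k <- build_kinked_helix(strrep("A", 25), hinge = 13, bend = b,
                              wobble = 60, face_shift = fs)
      g <- compute_kink(k$helix, 13)
      expect_equal(g$bend, b, tolerance = 1 / b)
      expect_lt(abs(helixcm:::wrap_angle(g$face_shift - fs)), 2)
      if (b >= 10) {
        expect_lt(abs(helixcm:::wrap_angle(g$wobble - 60)), 5)
      }
    }
  }
})

test_that("kink descriptors are invariant under rigid-body motion", {
  k <- build_kinked_helix(strrep("A", 25), hinge = 13, bend = 20,
                          wobble = -120, face_shift = 30)
  g0 <- compute_kink(k$helix, 13)
  for (seed in 1:3) {
    g <- compute_kink(random_rigid_motion(k$helix, seed), 13)
    expect_equal(g$bend, g0$bend, tolerance = 1e-6)
    expect_equal(g$wobble, g0$wobble, tolerance = 1e-5)
    expect_equal(g$face_shift, g0$face_shift, tolerance = 1e-5)
  }
})

test_that("kabsch_rmsd matches closed forms and a rotation-grid oracle", {
  a <- matrix(rnorm(15), 5, 3)
  expect_equal(kabsch_rmsd(a, a), 0, tolerance = 1e-12)
  b <- random_rigid_motion(
    tibble::tibble(x = a[, 1], y = a[, 2], z = a[, 3]), 2)
  expect_lt(kabsch_rmsd(a, as.matrix(b[, c("x", "y", "z")])), 1e-9)
  # two 4-point sets displaced by a constant vector: raw RMSD is the shift
  p <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  q <- sweep(p, 2, c(3, 4, 0), `+`)
  expect_equal(kabsch_rmsd(p, q, superpose = FALSE), 5, tolerance = 1e-12)
  expect_lt(kabsch_rmsd(p, q, superpose = TRUE), 1e-12)
  expect_error(kabsch_rmsd(p, q[1:3, ]), "differ in size")

  # dense grid over rotations (Euler angles) as an independent oracle
  set.seed(8)
  a5 <- matrix(rnorm(15), 5, 3)
  b5 <- matrix(rnorm(15), 5, 3)
  fitted <- kabsch_rmsd(a5, b5)
  ac <- sweep(a5, 2, colMeans(a5))
  bc <- sweep(b5, 2, colMeans(b5))
  best <- Inf
  angs <- seq(0, 350, by = 10)
  for (al in angs) for (be in seq(0, 170, by = 10)) for (ga in angs) {
    R <- helixcm:::rotation_matrix(c(0, 0, 1), al) %*%
      helixcm:::rotation_matrix(c(0, 1, 0), be) %*%
      helixcm:::rotation_matrix(c(0, 0, 1), ga)
    best <- min(best, sqrt(mean(rowSums((ac - bc %*% t(R))^2))))
  }
  expect_lt(fitted, best + 1e-9)   # optimal beats every grid rotation
  expect_lt(best - fitted, 1e-1)   # and the grid approaches it
})

test_that("trajectory RMSD behaves on constant, noisy and sized inputs", {
  h <- build_ideal_helix(strrep("A", 10))
  const <- trajectory_rmsd(list(h, h, h))
  expect_equal(const$rmsd, c(0, 0, 0), tolerance = 1e-12)
  # isotropic Gaussian noise of sd sigma gives RMSD ~ sigma * sqrt(3)
  sigma <- 0.3
  set.seed(21)
  noisy <- lapply(1:40, function(i) {
    hh <- h
    hh$x <- hh$x + rnorm(nrow(hh), sd = sigma)
    hh$y <- hh$y + rnorm(nrow(hh), sd = sigma)
    hh$z <- hh$z + rnorm(nrow(hh), sd = sigma)
    hh
  })
  r <- trajectory_rmsd(c(list(h), noisy), superpose = FALSE)
  expect_equal(mean(r$rmsd[-1]), sigma * sqrt(3),
               tolerance = 0.1)
  r50 <- trajectory_rmsd(rep(list(h), 50))
  expect_equal(nrow(r50), 50)
  expect_error(trajectory_rmsd(list(h, h), residues = 99), "empty")
})

test_that("kink tables render at one decimal with the documented columns", {
  rows <- tibble::tibble(helix = "TMH1", hinge = "T1.44",
                         bend = 13.0, wobble = 172.4, face_shift = 3.0)
  out <- format_kink_table(rows)
  expect_equal(unname(unlist(out[1, ])),
               c("TMH1", "T1.44", "13.0", "172.4", "3.0"))
  expect_equal(format_kink_table(
    tibble::tibble(helix = "TMH6", hinge = "T6.43", bend = 9.94,
                   wobble = 0, face_shift = 0))$Bend, "9.9")
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- format_kink_table(rows[0, ], path = f)
  expect_equal(nrow(empty), 0)
  expect_equal(length(readLines(f)), 1)  # header only
})
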