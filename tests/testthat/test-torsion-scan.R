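test_that("zero rotatable bonds yield exactly one conformer", {
  cs <- enumerate_and_minimize(toy_chain(), chain_rotatable()[0, ], chain_ff())
  expect_length(cs$energies, 1)
  expect_equal(cs$global_min_index, 1L)
})

test_that("a 3-fold torsion yields three minima near +/-60 and 180", {
  cs <- enumerate_and_minimize(toy_chain(), chain_rotatable(), chain_ff())
  expect_length(cs$energies, 3)
  found <- helixcm:::wrap_angle(cs$torsions[, 1])
  for (m in c(-60, 60, 180)) {
    expect_true(any(abs(helixcm:::wrap_angle(found - m)) < 2))
  }
  # grid-search oracle on the closed-form potential agrees
  grid <- seq(-179.95, 180, by = 0.05)
  e <- torsion_energy(grid, data.frame(amplitude = 1, periodicity = 3,
                                       phase = 0))
  oracle <- sort(grid[which(diff(sign(diff(e))) == 2) + 1])
  for (m in oracle) {
    expect_true(any(abs(helixcm:::wrap_angle(found - m)) < 2))
  }
  expect_equal(cs$energies[cs$global_min_index], min(cs$energies))
})

test_that("n 3-fold bonds start from a 3^n grid and dedup keeps distinct minima", {
  atoms <- tibble::tibble(
    name = paste0("C", 1:5), element = "C",
    x = c(0, 1.5, 2.2, 3.7, 4.4), y = c(0, 0, 1.3, 1.3, 2.6),
    z = c(0, 0, 0, 0.5, 0.5))
  mol <- molecule(atoms, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  rot <- tibble::tibble(a = c(1, 2), b = c(2, 3), c = c(3, 4), d = c(4, 5),
                        fold = 3, class = "chi1")
  ff <- forcefield(charges = c("*:*" = 0),
                   lj = list(C = c(eps = 0, rmin = 3.9)),
                   torsions = list(chi1 = data.frame(amplitude = 1,
                                                     periodicity = 3,
                                                     phase = 0)))
  cs <- enumerate_and_minimize(mol, rot, ff)
  # 3^2 starts collapse onto 9 distinct torsion-pair minima
  expect_equal(length(cs$energies), 9)
  expect_true(all(diff(cs$energies) >= -1e-9))
})

test_that("ring bonds are rejected as non-rotatable", {
  atoms <- tibble::tibble(name = paste0("C", 1:4), element = "C",
                          x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
  ring <- molecule(atoms, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  rot <- tibble::tibble(a = 1, b = 2, c = 3, d = 4, fold = 3, class = "chi1")
  expect_error(enumerate_and_minimize(ring, rot, chain_ff()), "ring")
})

test_that("dedup is order-independent", {
  cs1 <- enumerate_and_minimize(toy_chain(), chain_rotatable(), chain_ff())
  shifted <- helixcm:::mol_set_torsion(toy_chain(), c(1, 2, 3, 4), 150)
  cs2 <- enumerate_and_minimize(shifted, chain_rotatable(), chain_ff())
  t1 <- helixcm:::wrap_angle(cs1$torsions[, 1])
  t2 <- helixcm:::wrap_angle(cs2$torsions[, 1])
  expect_equal(length(t1), length(t2))
  # same retained set up to circular distance
  for (v in t1) {
    expect_true(any(abs(helixcm:::wrap_angle(t2 - v)) < 2))
  }
})

test_that("finer seeding never raises the global minimum", {
  coarse <- enumerate_and_minimize(toy_chain(), chain_rotatable(), chain_ff())
  extra <- helixcm:::mol_set_torsion(toy_chain(), c(1, 2, 3, 4), 30)
  fine <- enumerate_and_minimize(extra, chain_rotatable(), chain_ff())
  expect_lte(min(fine$energies), min(coarse$energies) + 1e-9)
})

test_that("conformational cost equals the closed-form torsion displacement", {
  cs <- enumerate_and_minimize(toy_chain(), chain_rotatable(), chain_ff())
  gmin <- cs$conformers[[cs$global_min_index]]
  # docked pose identical to the global minimum costs nothing
  expect_equal(conformational_cost(gmin, gmin, chain_rotatable(), chain_ff()),
               0, tolerance = 1e-6)
  # displace the single torsion to a point of known potential value
  terms <- data.frame(amplitude = 1, periodicity = 3, phase = 0)
  th_min <- helixcm:::mol_torsion(gmin, c(1, 2, 3, 4))
  docked <- helixcm:::mol_set_torsion(gmin, c(1, 2, 3, 4), 100)
  dV <- torsion_energy(100, terms) - torsion_energy(th_min, terms)
  cost <- conformational_cost(docked, gmin, chain_rotatable(), chain_ff())
  expect_equal(cost, dV, tolerance = 1e-3)
  expect_gte(cost, 0)
})

test_that("topology mismatches are rejected", {
  other <- molecule(tibble::tibble(name = c("C1", "C2"), element = "C",
                                   x = c(0, 1.5), y = 0, z = 0),
                    rbind(c(1, 2)))
  expect_error(conformational_cost(toy_chain(), other, chain_rotatable(),
                                   chain_ff()),
               "mismatched topology")
})

test_that("conformer sets tidy into one row per conformer", {
  cs <- enumerate_and_minimize(toy_chain(), chain_rotatable(), chain_ff())
  td <- tidy(cs)
  expect_equal(nrow(td), 3)
  expect_true(all(c("conformer", "energy", "torsion_1") %in% names(td)))
  g <- glance(cs)
  expect_equal(g$n_conformers, 3)
})
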