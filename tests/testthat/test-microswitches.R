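test_that("chi1 windows map the canonical rotamers and partition the circle", {
  expect_equal(classify_chi1(-60), "g+")
  expect_equal(classify_chi1(180), "trans")
  expect_equal(classify_chi1(65), "g-")
  # every angle gets exactly one label
  grid <- seq(-179.9, 180, by = 0.1)
  labs <- classify_chi1(grid)
  expect_true(all(labs %in% c("g+", "g-", "trans")))
  expect_equal(sum(labs == "g+") + sum(labs == "g-") + sum(labs == "trans"),
               length(grid))
  # window boundaries are half-open
  expect_equal(classify_chi1(c(-120, 0, 120)), c("g+", "g-", "trans"))
})

test_that("the ionic lock forms inside the distance/angle criterion", {
  near <- lock_structure(2.9)
  il <- detect_ionic_lock(near$structure, near$bw, donor = "3.50",
                          acceptor = "6.50")
  expect_equal(il$status, "formed")
  expect_equal(il$distance, 2.9, tolerance = 1e-6)
  expect_equal(il$donor_atom, "NH1")
  far <- lock_structure(6.0)
  expect_equal(detect_ionic_lock(far$structure, far$bw, donor = "3.50",
                                 acceptor = "6.50")$status, "broken")
  # boundary is inclusive
  edge <- lock_structure(3.5)
  expect_equal(detect_ionic_lock(edge$structure, edge$bw, donor = "3.50",
                                 acceptor = "6.50")$status, "formed")
})

test_that("missing side chains give an indeterminate lock, not a crash", {
  near <- lock_structure(2.9)
  s <- near$structure
  s <- s[!(s$residue_index == 1 &
             s$atom %in% c("NE", "NH1", "NH2")), ]
  expect_warning(
    il <- detect_ionic_lock(as_helix(s), near$bw, donor = "3.50",
                            acceptor = "6.50"),
    "indeterminate")
  expect_equal(il$status, "indeterminate")
})

test_that("lock detection is invariant under rigid motion", {
  near <- lock_structure(3.2)
  for (seed in 1:3) {
    moved <- random_rigid_motion(near$structure, seed)
    il <- detect_ionic_lock(moved, near$bw, donor = "3.50", acceptor = "6.50")
    expect_equal(il$status, "formed")
    expect_equal(il$distance, 3.2, tolerance = 1e-6)
  }
})

test_that("aromatic contacts classify by distance and interplanar angle", {
  a <- hexagon_ring(0)
  expect_equal(classify_aromatic(a, hexagon_ring(3.8))$class, "parallel")
  # perpendicular ring with centroid on the first ring's normal axis
  b <- hexagon_ring(0)
  perp <- cbind(b[, 1], b[, 3], b[, 2])
  perp[, 3] <- perp[, 3] + 5
  expect_equal(classify_aromatic(a, perp)$class, "T-stack")
  expect_equal(classify_aromatic(a, hexagon_ring(9))$class, "none")
  # tilted
  R <- helixcm:::rotation_matrix(c(1, 0, 0), 45)
  tilt <- hexagon_ring(0) %*% t(R)
  tilt[, 3] <- tilt[, 3] + 4.5
  expect_equal(classify_aromatic(a, tilt)$class, "tilted-T")
  # edge-to-face: perpendicular ring displaced in-plane
  e2f <- cbind(b[, 1] + 5, b[, 3], b[, 2])
  expect_equal(classify_aromatic(a, e2f)$class, "edge-to-face")
})

test_that("aromatic classification is symmetric and rejects bent rings", {
  a <- hexagon_ring(0)
  b <- hexagon_ring(4)
  expect_equal(classify_aromatic(a, b)$class, classify_aromatic(b, a)$class)
  expect_equal(classify_aromatic(a, b)$centroid_distance,
               classify_aromatic(b, a)$centroid_distance)
  bent <- a
  bent[1, 3] <- 0.8
  expect_error(classify_aromatic(bent, b), "not planar")
})

test_that("ring extraction finds the template rings of F/Y/W/H", {
  h <- build_ideal_helix(c("ALA", "PHE", "TRP", "HIS", "ALA"))
  expect_equal(nrow(helixcm:::ring_coords(h, 2)), 6)
  expect_equal(nrow(helixcm:::ring_coords(h, 3, "five")), 5)
  expect_equal(nrow(helixcm:::ring_coords(h, 4)), 5)
  expect_error(helixcm:::ring_coords(h, 1), "no aromatic ring")
})

test_that("contact audits count satisfied interactions and flag unresolvable ones", {
  # synthetic triad: three serines pulled within hydrogen-bonding reach
  s1 <- build_ideal_helix(c("SER"), start_index = 1)
  place <- function(template, index, target_og) {
    t <- build_ideal_helix(c("SER"), start_index = index)
    shift <- target_og - atom_xyz(t, index, "OG")
    t$x <- t$x + shift[1]; t$y <- t$y + shift[2]; t$z <- t$z + shift[3]
    t
  }
  og1 <- atom_xyz(s1, 1, "OG")
  # equilateral triangle of OG atoms, 2.8 A on every side
  near <- as_helix(dplyr::bind_rows(
    as.data.frame(s1),
    as.data.frame(place(s1, 2, og1 + c(2.8, 0, 0))),
    as.data.frame(place(s1, 3, og1 + c(1.4, 2.8 * sin(pi / 3), 0)))))
  bw <- assign_bw_numbers(near, anchors = c("1" = 1, "2" = 2, "7" = 3))
  expected <- data.frame(a = c("1.50", "2.50", "7.50"),
                         b = c("2.50", "7.50", "1.50"))
  audit <- contact_audit(near, bw, expected)
  expect_equal(attr(audit, "n_satisfied"), 3)
  expect_equal(attr(audit, "n_total"), 3)
  # pulled apart: 0/3
  apart <- as_helix(dplyr::bind_rows(
    as.data.frame(s1),
    as.data.frame(place(s1, 2, og1 + c(8, 0, 0))),
    as.data.frame(place(s1, 3, og1 + c(4, 8 * sin(pi / 3), 0)))))
  audit2 <- contact_audit(apart, bw, expected)
  expect_equal(attr(audit2, "n_satisfied"), 0)
  # a label missing from the map is unresolvable, not an error
  audit3 <- contact_audit(near, bw, data.frame(a = "4.50", b = "1.50"))
  expect_equal(audit3$status, "unresolvable")
})

test_that("the sodium-pocket audit reports presence of the polar set", {
  h <- build_ideal_helix(c("ASN", "ALA", "ASP", "ALA", "SER"))
  bw <- assign_bw_numbers(h, anchors = c("1" = 1, "2" = 3, "3" = 5))
  pocket <- audit_sodium_pocket(h, bw, residues = c("1.50", "2.50", "3.50",
                                                    "7.49"))
  expect_equal(pocket$present, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(pocket$residue_name[1:3], c("ASN", "ASP", "SER"))
})

test_that("switch reports bundle lock, toggle rotamers and pocket audit", {
  near <- lock_structure(2.9)
  rep <- switch_report(near$structure, near$bw, toggle = c("3.50", "6.50"),
                       donor = "3.50", acceptor = "6.50")
  expect_s3_class(rep, "switch_report")
  expect_equal(rep$ionic_lock$status, "formed")
  expect_equal(nrow(rep$toggle), 2)
  expect_true(all(rep$toggle$rotamer %in% c("g+", "g-", "trans")))
  f <- withr::local_tempfile(fileext = ".json")
  write_switch_report(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$ionic_lock[[1]]$status, "formed")
})
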