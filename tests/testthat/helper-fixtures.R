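# Shared fixtures, built in code.

# Force field with no nonbonded terms and a single 3-fold torsion on psi:
# energy depends only on the sampled dihedral.
torsion_only_ff <- function(amplitude = 1, periodicity = 3, phase = 0,
                            class = "psi") {
  tor <- list()
  tor[[class]] <- data.frame(amplitude = amplitude,
                             periodicity = periodicity, phase = phase)
  forcefield(
    charges = c("*:*" = 0),
    lj = list(C = c(eps = 0, rmin = 3.9), N = c(eps = 0, rmin = 3.45),
              O = c(eps = 0, rmin = 3.3), S = c(eps = 0, rmin = 3.95)),
    torsions = tor)
}

# Completely flat energy surface.
flat_ff <- function() {
  forcefield(charges = c("*:*" = 0),
             lj = list(C = c(eps = 0, rmin = 3.9), N = c(eps = 0, rmin = 3.45),
                       O = c(eps = 0, rmin = 3.3), S = c(eps = 0, rmin = 3.95)))
}

# Regular planar hexagon of "ring" atoms (C6, bond length ~1.39 A).
hexagon_ring <- function(z = 0, r = 1.39) {
  t(sapply(0:5, function(k) c(r * cos(k * pi / 3), r * sin(k * pi / 3), z)))
}

# Four-atom chain with one rotatable central bond.
toy_chain <- function() {
  molecule(
    tibble::tibble(name = c("C1", "C2", "C3", "C4"), element = "C",
                   x = c(0, 1.5, 2.2, 3.7), y = c(0, 0, 1.3, 1.3),
                   z = c(0, 0, 0, 0.5)),
    rbind(c(1, 2), c(2, 3), c(3, 4)))
}

chain_rotatable <- function() {
  tibble::tibble(a = 1, b = 2, c = 3, d = 4, fold = 3, class = "chi1")
}

chain_ff <- function(amplitude = 1, periodicity = 3, phase = 0) {
  forcefield(charges = c("*:*" = 0),
             lj = list(C = c(eps = 0.09, rmin = 3.9)),
             torsions = list(chi1 = data.frame(amplitude = amplitude,
                                               periodicity = periodicity,
                                               phase = phase)))
}

# Two-residue ARG/THR structure with the threonine OG1 placed at `distance`
# from the arginine NH1 along the CZ-NH1 direction (near-linear donor angle).
lock_structure <- function(distance = 2.9) {
  r <- build_ideal_helix(c("ARG"), start_index = 1)
  t <- build_ideal_helix(c("THR"), start_index = 2)
  nh1 <- atom_xyz(r, 1, "NH1")
  cz <- atom_xyz(r, 1, "CZ")
  dir <- (nh1 - cz) / sqrt(sum((nh1 - cz)^2))
  target <- nh1 + dir * distance
  og1 <- atom_xyz(t, 2, "OG1")
  shift <- target - og1
  t$x <- t$x + shift[1]; t$y <- t$y + shift[2]; t$z <- t$z + shift[3]
  s <- as_helix(dplyr::bind_rows(as.data.frame(r), as.data.frame(t)))
  list(structure = s,
       bw = assign_bw_numbers(s, anchors = c("3" = 1, "6" = 2)))
}

# Random rigid-body transform applied to an atom table.
random_rigid_motion <- function(h, seed = 1) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- helixcm:::rotation_matrix(ax, runif(1, 0, 360))
  t <- rnorm(3, sd = 10)
  xyz <- as.matrix(h[, c("x", "y", "z")]) %*% t(R)
  h$x <- xyz[, 1] + t[1]; h$y <- xyz[, 2] + t[2]; h$z <- xyz[, 3] + t[3]
  h
}

# Short annealing ladders for quick sampler runs.
quick_explore <- function() make_schedule(3000, 310, 6, mc_steps = 2000)
quick_biased <- function() make_schedule(749.4, 310, 4, mc_steps = 2000)
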