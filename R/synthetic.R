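# Seed-deterministic synthetic-structure generators.  Every generator
# records its ground truth (the transforms it applied) so downstream
# measurements can be tested without external data.

#' Build an ideal alpha-helix
#'
#' Backbone built from internal coordinates (default phi = -63, psi = -42,
#' omega = 180, the alpha-helical values used for transmembrane helices),
#' with side chains placed at the requested chi1 (default trans).
#'
#' @param sequence one-letter string, or character vector of one- or
#'   three-letter residue codes (length >= 1).
#' @param phi,psi,omega backbone dihedrals, degrees (recycled per residue).
#' @param tau N-CA-C bond angle, degrees (default the ideal 111).
#' @param chi1 optional chi1 angle(s), degrees, recycled over residues with
#'   side chains (default trans, 180).
#' @param chain chain identifier.
#' @param start_index residue index of the first residue (default 1).
#' @return a `helix`.
#' @export
build_ideal_helix <- function(sequence, phi = -63, psi = -42, omega = 180,
                              tau = IDEAL_GEOM$a_n_ca_c, chi1 = NULL,
                              chain = "A", start_index = 1) {
  seq3 <- as_seq3(sequence)
  n <- length(seq3)
  ic <- tibble::tibble(
    residue_index = seq.int(start_index, length.out = n),
    residue_name = seq3,
    phi = c(NA, rep_len(phi, n)[-1]),
    psi = c(rep_len(psi, n)[-n], NA),
    omega = c(NA, rep_len(omega, n)[-1]),
    tau = rep_len(tau, n))
  if (n == 1) {
    ic$phi <- NA_real_; ic$psi <- NA_real_; ic$omega <- NA_real_
  }
  if (!is.null(chi1)) ic$chi1 <- rep_len(chi1, n)
  build_from_internal(ic, chain = chain)
}

#' Build a kinked helix with known ground truth
#'
#' Starts from an ideal helix, then rigidly rotates the distal segment
#' (residues after the hinge) by `bend` degrees about an axis through the
#' hinge CA perpendicular to the helix axis, placed so that the distal axis
#' tilts toward azimuth `wobble` (measured from the hinge-CA reference
#' direction, right-handed about the proximal N->C axis); the distal segment
#' is then rotated `face_shift` degrees about its own (post-bend) axis.
#' Optional isotropic Gaussian noise is added last.  The recorded truth
#' values are exactly the applied transforms.
#'
#' @param sequence residue codes (as in [build_ideal_helix()]).
#' @param hinge hinge residue index (at least 6 residues from each
#'   terminus).
#' @param bend,wobble,face_shift applied kink angles, degrees.
#' @param noise_sigma standard deviation of per-coordinate Gaussian noise,
#'   Angstrom (default 0).
#' @param seed RNG seed for the noise (default 1).
#' @param ... passed to [build_ideal_helix()].
#' @return list with `helix` (the kinked structure) and `truth` (a one-row
#'   tibble of the applied bend/wobble/face_shift/noise_sigma/hinge).
#' @export
build_kinked_helix <- function(sequence, hinge, bend, wobble = 0,
                               face_shift = 0, noise_sigma = 0, seed = 1,
                               ...) {
  h <- build_ideal_helix(sequence, ...)
  res <- sort(unique(h$residue_index))
  if (hinge - min(res) < 6 || max(res) - hinge < 6) {
    abort("hinge must be at least 6 residues from each terminus")
  }
  clash_warning <- FALSE
  if (bend > 90) {
    warn("bend > 90 degrees is likely to produce steric clashes")
    clash_warning <- TRUE
  }
  pre <- fit_helix_axis(h, residues = res[res <= hinge])
  u <- pre$direction
  ca <- atom_xyz(h, hinge, "CA")
  r0 <- ca - pre$point
  r0 <- unitv(r0 - sum(r0 * u) * u)
  # rotation axis at azimuth (wobble + 90) so the distal axis projection
  # lands at azimuth `wobble` (tilting about w moves the axis toward w x u,
  # which sits 90 deg clockwise of w about u)
  w <- as.numeric(rotation_matrix(u, wobble + 90) %*% r0)
  distal <- which(h$residue_index > hinge)
  xyz <- as.matrix(h[, c("x", "y", "z")])
  foot <- pre$point + sum((ca - pre$point) * u) * u
  Rb <- rotation_matrix(w, bend)
  xyz[distal, ] <- sweep(sweep(xyz[distal, , drop = FALSE], 2, ca) %*% t(Rb),
                         2, ca, `+`)
  # distal axis line after the bend: point ca + Rb (foot - ca), direction Rb u
  d_dir <- as.numeric(Rb %*% u)
  d_pt <- ca + as.numeric(Rb %*% (foot - ca))
  xyz[distal, ] <- rotate_about_axis(xyz[distal, , drop = FALSE], d_pt,
                                     d_dir, face_shift)
  if (noise_sigma > 0) {
    set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise_sigma),
                        ncol = 3)
  }
  h$x <- xyz[, 1]; h$y <- xyz[, 2]; h$z <- xyz[, 3]
  list(helix = h,
       truth = tibble::tibble(hinge = hinge, bend = bend, wobble = wobble,
                              face_shift = face_shift,
                              noise_sigma = noise_sigma, seed = seed,
                              clash_warning = clash_warning))
}

#' Build a toy ligand-pocket complex with a closed-form expected table
#'
#' Places a single +1e ligand probe atom at the origin and `n` single-atom
#' pocket "residues" at recorded distances and directions, each carrying a
#' charge from `charge_pattern`.  The expected per-residue Coulomb and
#' van der Waals terms (distance-dependent dielectric eps(r) = 2r, the
#' stated cutoffs and shell rule) are computed by an independent direct-sum
#' double loop and returned with the fixture, together with a matching
#' force field.
#'
#' @param n number of pocket residues (>= 1).
#' @param charge_pattern charges (e) recycled over pocket residues
#'   (default -1).
#' @param seed RNG seed for placement.
#' @param distances optional explicit ligand-residue distances (Angstrom);
#'   default uniform in (2.8, 7).
#' @param directions optional n x 3 matrix of placement directions.
#' @param shell,cutoff_nb,cutoff_elec decomposition geometry (defaults 5, 8,
#'   20 Angstrom).
#' @param lj include Lennard-Jones parameters for the probe atoms
#'   (default TRUE; `FALSE` gives a pure-Coulomb fixture).
#' @return list with `complex` (atom tibble; ligand rows have
#'   `residue_name == "LIG"`), `params` (forcefield), `expected` (tibble
#'   `residue_index`, `coulomb`, `vdw`, `sum`, sorted ascending by sum) and
#'   `truth` (placement record).
#' @export
build_toy_complex <- function(n, charge_pattern = -1, seed = 1,
                              distances = NULL, directions = NULL,
                              shell = 5, cutoff_nb = 8, cutoff_elec = 20,
                              lj = TRUE) {
  if (n < 1) abort("need at least one pocket residue")
  set.seed(seed)
  if (is.null(distances)) distances <- runif(n, 2.8, 7)
  distances <- rep_len(distances, n)
  if (is.null(directions)) {
    directions <- matrix(stats::rnorm(3 * n), ncol = 3)
  }
  directions <- directions / sqrt(rowSums(directions^2))
  charges <- rep_len(charge_pattern, n)
  pocket_atoms <- paste0("P", seq_len(n))
  complex <- dplyr::bind_rows(
    tibble::tibble(residue_index = 1L, residue_name = "LIG", chain = "L",
                   atom = "L1", element = "C", x = 0, y = 0, z = 0),
    tibble::tibble(residue_index = seq_len(n) + 1L, residue_name = "PCK",
                   chain = "A", atom = pocket_atoms, element = "C",
                   x = directions[, 1] * distances,
                   y = directions[, 2] * distances,
                   z = directions[, 3] * distances))
  ljdef <- if (lj) list(C = c(eps = 0.09, rmin = 3.9)) else
    list(C = c(eps = 0, rmin = 3.9))
  params <- forcefield(
    charges = setNames(c(1, charges),
                       c("LIG:L1", paste0("PCK:", pocket_atoms))),
    lj = ljdef,
    dielectric = list(model = "distance", coefficient = 2))
  # independent direct-sum oracle (plain scalar arithmetic)
  rows <- list()
  for (k in seq_len(n)) {
    r <- distances[k]
    if (r > shell) next
    ecoul <- if (r <= cutoff_elec) 332.0636 * 1 * charges[k] / (2 * r * r) else 0
    evdw <- if (lj && r <= cutoff_nb) {
      s6 <- (3.9 / r)^6
      0.09 * (s6 * s6 - 2 * s6)
    } else 0
    rows[[length(rows) + 1]] <- tibble::tibble(
      residue_index = k + 1L, coulomb = ecoul, vdw = evdw,
      sum = ecoul + evdw)
  }
  expected <- dplyr::bind_rows(
    tibble::tibble(residue_index = integer(), coulomb = numeric(),
                   vdw = numeric(), sum = numeric()),
    rows)
  expected <- expected[order(expected$sum), ]
  list(complex = complex, params = params, expected = expected,
       truth = tibble::tibble(residue_index = seq_len(n) + 1L,
                              distance = distances, charge = charges,
                              seed = seed))
}
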