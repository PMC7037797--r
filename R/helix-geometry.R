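# Helix shape descriptors: axis fitting, bend/wobble/face-shift kink
# geometry about a hinge residue, and RMSD analyses.

#' Fit a helix axis
#'
#' Local helix centers are taken as means of four consecutive CA positions
#' (which cancels the ~3.6-residue helical periodicity); the axis is the
#' least-squares line through those centers, oriented N to C.
#'
#' @param x a `helix`, or an n x 3 matrix of consecutive CA coordinates
#'   (n >= 5).
#' @param residues optional residue indices to restrict a `helix` input.
#' @return a `helix_axis` list: `point` (a point on the axis), `direction`
#'   (unit vector, N->C), `residual` (RMS distance of centers from the line,
#'   Angstrom) and `degenerate` (TRUE, with a warning, when the CA trace is
#'   essentially collinear and the helical radius is unresolved).
#' @export
fit_helix_axis <- function(x, residues = NULL) {
  ca <- if (is.matrix(x)) x else helix_coords(x, atoms = "CA",
                                              residues = residues)
  n <- nrow(ca)
  if (n < 5) abort("axis fitting needs at least 5 consecutive CA positions")
  centers <- t(vapply(seq_len(n - 3), function(i) colMeans(ca[i:(i + 3), ]),
                      numeric(3)))
  # a 4-CA window does not fully cancel the ~100 deg/residue periodicity
  # (3.6 residues/turn); a second 3-point mean over the centers removes most
  # of the residual first harmonic when the segment is long enough
  if (nrow(centers) >= 4) {
    centers <- t(vapply(seq_len(nrow(centers) - 2), function(i) {
      colMeans(centers[i:(i + 2), ])
    }, numeric(3)))
  }
  cm <- colMeans(centers)
  rel <- sweep(centers, 2, cm)
  sv <- svd(rel)
  u <- sv$v[, 1]
  if (sum(u * (ca[n, ] - ca[1, ])) < 0) u <- -u
  proj <- as.numeric(rel %*% u)
  resid <- sqrt(mean(rowSums((rel - proj %o% u)^2)))
  radial <- sweep(ca, 2, cm)
  radial <- radial - as.numeric(radial %*% u) %o% u
  degenerate <- mean(sqrt(rowSums(radial^2))) < 0.5
  if (degenerate) {
    warn("CA trace is nearly collinear: helix axis is degenerate")
  }
  structure(list(point = cm, direction = u, residual = resid,
                 degenerate = degenerate), class = "helix_axis")
}

# Helical phase of CA positions about an axis, relative to reference
# direction `ref` (a vector perpendicular-projected internally); returns
# unwrapped phases in degrees.
helical_phases <- function(ca, axis_point, u, ref) {
  ph <- vapply(seq_len(nrow(ca)), function(i) {
    azimuth_about(u, ref, ca[i, ] - axis_point)
  }, numeric(1))
  # unwrap
  for (i in seq_along(ph)[-1]) {
    while (ph[i] - ph[i - 1] > 180) ph[i] <- ph[i] - 360
    while (ph[i] - ph[i - 1] < -180) ph[i] <- ph[i] + 360
  }
  ph
}

#' Kink geometry about a hinge residue
#'
#' Fits separate axes to the helix segments up to and after the hinge and
#' reports the ProKink-style descriptors: `bend` is the angle between the
#' two axes; `wobble` is the azimuth of the distal (post-hinge) axis about
#' the proximal axis, measured right-handedly (about the N->C proximal
#' direction) from the hinge-CA reference direction; `face_shift` is the mean
#' change in helical phase of the post-hinge residues relative to the phase
#' extrapolated from the pre-hinge segment, after transporting the phase
#' reference across the kink by the minimal rotation between the axes.
#'
#' Wobble is geometrically ill-conditioned as the bend vanishes; it is always
#' reported, with `wobble_reliable = FALSE` below `min_bend_for_wobble`.
#'
#' @param h a `helix`.
#' @param hinge absolute index of the hinge residue (>= 5 residues must lie
#'   on each side).
#' @param phase_per_residue ideal helical phase advance per residue used to
#'   extrapolate the pre-hinge face; `NULL` (default) estimates it from the
#'   pre-hinge segment itself, `100` fixes the canonical alpha-helical value.
#' @param min_bend_for_wobble bend threshold (degrees) below which the
#'   wobble azimuth is flagged unreliable (default 10).
#' @return a `kink_geometry` tibble: `bend`, `wobble`, `face_shift`
#'   (degrees), `wobble_reliable`.
#' @export
compute_kink <- function(h, hinge, phase_per_residue = NULL,
                         min_bend_for_wobble = 10) {
  h <- as_helix(h)
  res <- sort(unique(h$residue_index))
  pre_res <- res[res <= hinge]
  post_res <- res[res > hinge]
  if (length(pre_res) < 5 || length(post_res) < 5) {
    abort("hinge too close to a terminus: need >= 5 residues on each side")
  }
  pre <- fit_helix_axis(h, residues = pre_res)
  post <- fit_helix_axis(h, residues = post_res)
  u <- pre$direction
  d <- post$direction
  bend <- acos(max(-1, min(1, sum(u * d)))) / DEG

  ca_hinge <- atom_xyz(h, hinge, "CA")
  # reference direction: hinge CA offset from the proximal axis
  r0 <- ca_hinge - pre$point
  r0 <- r0 - sum(r0 * u) * u
  wobble <- azimuth_about(u, r0, d - sum(d * u) * u)

  # phases of the pre-hinge segment about the proximal axis
  ca_pre <- helix_coords(h, atoms = "CA", residues = pre_res)
  ph_pre <- helical_phases(ca_pre, pre$point, u, r0)
  off_pre <- pre_res - hinge
  fit <- stats::lm.fit(cbind(1, off_pre), ph_pre)
  slope <- if (is.null(phase_per_residue)) fit$coefficients[2] else {
    sign(fit$coefficients[2]) * phase_per_residue
  }
  intercept <- fit$coefficients[1]

  # transport the phase reference across the kink by the minimal rotation
  axis_w <- cross3(u, d)
  r0_post <- if (vnorm(axis_w) > 1e-8) {
    as.numeric(rotation_matrix(axis_w, bend) %*% r0)
  } else {
    r0
  }
  ca_post <- helix_coords(h, atoms = "CA", residues = post_res)
  ph_post <- helical_phases(ca_post, post$point, d, r0_post)
  pred <- intercept + slope * (post_res - hinge)
  dphase <- wrap_angle(ph_post - pred)
  face_shift <- wrap_angle(
    atan2(mean(sin(dphase * DEG)), mean(cos(dphase * DEG))) / DEG)

  out <- tibble::tibble(bend = bend, wobble = wobble,
                        face_shift = face_shift,
                        wobble_reliable = bend >= min_bend_for_wobble)
  class(out) <- c("kink_geometry", class(out))
  out
}

#' Per-frame RMSD of a trajectory against its first frame
#'
#' Each frame is superposed on the reference (frame 1) over the backbone of
#' the selected residues and the RMSD over that selection is reported;
#' frame 1 has RMSD 0 by construction.
#'
#' @param frames list of `helix` frames sharing a topology.
#' @param residues residue indices to include (default: all residues of the
#'   reference).
#' @param atoms backbone atom names used (default N, CA, C, O).
#' @param superpose superpose before measuring (default TRUE).
#' @return a tibble with columns `frame` and `rmsd` (Angstrom).
#' @export
trajectory_rmsd <- function(frames, residues = NULL,
                            atoms = c("N", "CA", "C", "O"),
                            superpose = TRUE) {
  if (is_helix(frames)) frames <- list(frames)
  ref <- as_helix(frames[[1]])
  if (is.null(residues)) residues <- unique(ref$residue_index)
  sel_ref <- helix_coords(ref, atoms = atoms, residues = residues)
  if (nrow(sel_ref) == 0) abort("empty atom selection for RMSD")
  tibble::tibble(
    frame = seq_along(frames),
    rmsd = vapply(frames, function(f) {
      sel <- helix_coords(as_helix(f), atoms = atoms, residues = residues)
      kabsch_rmsd(sel_ref, sel, superpose = superpose)
    }, numeric(1)))
}

#' Format a kink-geometry report table
#'
#' One row per analysed helix with the bend, wobble and face-shift angles at
#' one decimal place, written as TSV when `path` is given.
#'
#' @param rows a data frame with columns `helix`, `hinge` and either a
#'   `kink_geometry` list-column `kink` or plain `bend`, `wobble`,
#'   `face_shift` columns.
#' @param path optional output TSV path.
#' @return a tibble with character columns `Helix`, `Hinge Residue`, `Bend`,
#'   `Wobble`, `FaceShift`.
#' @export
format_kink_table <- function(rows, path = NULL) {
  rows <- tibble::as_tibble(rows)
  if ("kink" %in% names(rows)) {
    rows$bend <- vapply(rows$kink, function(k) k$bend, numeric(1))
    rows$wobble <- vapply(rows$kink, function(k) k$wobble, numeric(1))
    rows$face_shift <- vapply(rows$kink, function(k) k$face_shift, numeric(1))
  }
  out <- tibble::tibble(
    Helix = as.character(rows$helix),
    `Hinge Residue` = as.character(rows$hinge),
    Bend = sprintf("%.1f", rows$bend),
    Wobble = sprintf("%.1f", rows$wobble),
    FaceShift = sprintf("%.1f", rows$face_shift))
  if (nrow(rows) == 0) {
    out <- tibble::tibble(Helix = character(), `Hinge Residue` = character(),
                          Bend = character(), Wobble = character(),
                          FaceShift = character())
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
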