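# GPCR functional-state indicators: chi1 rotamers, the R3.50-T6.30 ionic
# lock, toggle-switch rotamer triads, sodium-pocket completeness,
# inter-helical contact audits and aromatic-stacking classes.

# Polar side-chain heavy atoms able to donate/accept hydrogen bonds.
POLAR_SIDECHAIN <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"), TRP = "NE1")

#' Classify chi1 rotamer states
#'
#' Standard staggered windows as used in the GPCR-modelling literature:
#' `g+` is centred near -60 deg (window `[-120, 0)`), `g-` near +60 deg
#' (`[0, 120)`), `trans` near 180 deg (the rest of the circle).  The three
#' windows partition the circle, so every angle maps to exactly one label.
#'
#' @param chi1 numeric vector of chi1 angles, degrees, in `(-180, 180]`.
#' @param windows list with elements `gplus` and `gminus`, each `c(lo, hi)`
#'   half-open windows; everything else is `trans`.
#' @return character vector of labels (`"g+"`, `"g-"`, `"trans"`).
#' @export
classify_chi1 <- function(chi1,
                          windows = list(gplus = c(-120, 0),
                                         gminus = c(0, 120))) {
  chi1 <- wrap_angle(chi1)
  out <- rep("trans", length(chi1))
  out[chi1 >= windows$gplus[1] & chi1 < windows$gplus[2]] <- "g+"
  out[chi1 >= windows$gminus[1] & chi1 < windows$gminus[2]] <- "g-"
  out
}

# chi1 of one residue measured from coordinates (NA when undefined).
residue_chi1 <- function(h, residue_index) {
  rn <- helix_sequence(h)[[as.character(residue_index)]]
  defs <- chi_definitions(rn)
  if (is.null(defs)) return(NA_real_)
  row <- defs[defs$dih == "chi1", ]
  if (nrow(row) == 0) return(NA_real_)
  pts <- list(atom_xyz(h, residue_index, row$ref_a),
              atom_xyz(h, residue_index, row$ref_b),
              atom_xyz(h, residue_index, row$ref_c),
              atom_xyz(h, residue_index, row$name))
  if (any(vapply(pts, is.null, logical(1)))) return(NA_real_)
  dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

resolve_bw <- function(h, bw, label) {
  i <- if (grepl("^[0-9]+$", label)) as.integer(label) else bw_index(bw, label)
  if (is.na(i) || !i %in% h$residue_index) return(NA_integer_)
  i
}

# Parent (antecedent) atom of a side-chain atom, from the template topology.
parent_atom <- function(residue_name, atom) {
  tmpl <- SIDECHAIN_TEMPLATES[[residue_name]]
  if (!is.null(tmpl)) {
    j <- match(atom, tmpl$name)
    if (!is.na(j)) return(tmpl$ref_c[j])
  }
  switch(atom, N = "CA", O = "C", CA = "N", C = "CA", NA_character_)
}

#' Detect the ionic lock
#'
#' The inactive-state interaction between the intracellular ends of TMH3 and
#' TMH6 (canonically residues 3.50 and 6.30; in GPR6 an arginine-threonine
#' hydrogen bond).  Formed when the minimum heavy-atom distance between the
#' donor's and acceptor's polar side-chain atoms is at most `max_distance`
#' and the angle at the donor atom (antecedent-donor-acceptor) is at least
#' `min_angle`; both bounds inclusive.
#'
#' @param h a `helix` (or full receptor atom table).
#' @param bw a `bw_map`.
#' @param donor,acceptor Ballesteros-Weinstein labels (default `"3.50"`,
#'   `"6.30"`).
#' @param max_distance donor-acceptor distance criterion, Angstrom
#'   (default 3.5).
#' @param min_angle donor-angle criterion, degrees (default 120).
#' @return a tibble: `status` (`"formed"`, `"broken"` or `"indeterminate"`),
#'   `distance`, `angle`, `donor_atom`, `acceptor_atom`, `donor`, `acceptor`.
#' @export
detect_ionic_lock <- function(h, bw, donor = "3.50", acceptor = "6.30",
                              max_distance = 3.5, min_angle = 120) {
  h <- as_helix(h)
  di <- resolve_bw(h, bw, donor)
  ai <- resolve_bw(h, bw, acceptor)
  if (is.na(di) || is.na(ai)) {
    abort(sprintf("residue %s not present in the structure/map",
                  if (is.na(di)) donor else acceptor))
  }
  seqs <- helix_sequence(h)
  datoms <- intersect(POLAR_SIDECHAIN[[seqs[[as.character(di)]]]] %||% character(),
                      h$atom[h$residue_index == di])
  aatoms <- intersect(POLAR_SIDECHAIN[[seqs[[as.character(ai)]]]] %||% character(),
                      h$atom[h$residue_index == ai])
  out <- function(status, dist = NA, ang = NA, da = NA, aa = NA) {
    tibble::tibble(status = status, distance = dist, angle = ang,
                   donor_atom = da, acceptor_atom = aa,
                   donor = donor, acceptor = acceptor)
  }
  if (!length(datoms) || !length(aatoms)) {
    warn("missing side-chain atoms: ionic lock status is indeterminate")
    return(out("indeterminate"))
  }
  grid <- expand.grid(da = datoms, aa = aatoms, stringsAsFactors = FALSE)
  grid$dist <- vapply(seq_len(nrow(grid)), function(k) {
    vnorm(atom_xyz(h, di, grid$da[k]) - atom_xyz(h, ai, grid$aa[k]))
  }, numeric(1))
  best <- grid[which.min(grid$dist), ]
  ante <- parent_atom(seqs[[as.character(di)]], best$da)
  ang <- NA_real_
  if (!is.na(ante) && !is.null(atom_xyz(h, di, ante))) {
    ang <- bond_angle(atom_xyz(h, di, ante), atom_xyz(h, di, best$da),
                      atom_xyz(h, ai, best$aa))
  }
  formed <- best$dist <= max_distance && (is.na(ang) || ang >= min_angle)
  out(if (formed) "formed" else "broken", best$dist, ang, best$da, best$aa)
}

# Extract an aromatic ring coordinate matrix from a residue.
ring_coords <- function(h, residue_index, ring = c("six", "five")) {
  rn <- helix_sequence(h)[[as.character(residue_index)]]
  rings <- AROMATIC_RINGS[[rn]]
  if (is.null(rings)) {
    abort(sprintf("residue %d (%s) carries no aromatic ring", residue_index, rn))
  }
  atoms <- if (rn == "TRP") rings[[match.arg(ring)]] else rings[[1]]
  m <- do.call(rbind, lapply(atoms, function(a) atom_xyz(h, residue_index, a)))
  if (is.null(m) || nrow(m) < 5) {
    abort(sprintf("ring atoms missing from residue %d", residue_index))
  }
  m
}

ring_plane <- function(xyz, planarity_tol) {
  cen <- colMeans(xyz)
  rel <- sweep(xyz, 2, cen)
  sv <- svd(rel)
  normal <- sv$v[, 3]
  dev <- max(abs(rel %*% normal))
  if (dev > planarity_tol) {
    abort(sprintf("ring is not planar: max out-of-plane deviation %.2f A", dev))
  }
  list(centroid = cen, normal = normal)
}

#' Classify an aromatic-aromatic contact
#'
#' Geometry-based classification of two (near-)planar rings: no contact
#' beyond `cutoff` between centroids; otherwise `parallel` stacking for
#' interplanar angles up to 30 deg, `tilted-T` for 30-60 deg and, for
#' near-perpendicular rings (60-90 deg), `T-stack` when the
#' centroid-centroid vector points along one ring's normal (within
#' `tstack_axis_tol`) or `edge-to-face` otherwise.  Angles are folded to
#' `[0, 90]`, so the classification is symmetric in its arguments.
#'
#' @param ring_a,ring_b n x 3 coordinate matrices (n >= 5) of ring heavy
#'   atoms; each must be planar to within `planarity_tol` (Angstrom).
#' @param cutoff centroid-centroid distance cutoff, Angstrom (default 7).
#' @param planarity_tol maximum out-of-plane deviation (default 0.3 A).
#' @param tstack_axis_tol angle (degrees) between the centroid vector and a
#'   ring normal below which a perpendicular pair counts as a T-stack
#'   (default 40).
#' @return an `aromatic_contact` tibble: `centroid_distance`,
#'   `interplanar_angle`, `class`.
#' @export
classify_aromatic <- function(ring_a, ring_b, cutoff = 7,
                              planarity_tol = 0.3, tstack_axis_tol = 40) {
  pa <- ring_plane(as.matrix(ring_a), planarity_tol)
  pb <- ring_plane(as.matrix(ring_b), planarity_tol)
  v <- pb$centroid - pa$centroid
  d <- vnorm(v)
  ang <- acos(min(1, abs(sum(pa$normal * pb$normal)))) / DEG
  cls <- if (d > cutoff) "none"
  else if (ang <= 30) "parallel"
  else if (ang <= 60) "tilted-T"
  else {
    axis_angle <- min(
      acos(min(1, abs(sum(unitv(v) * pa$normal)))) / DEG,
      acos(min(1, abs(sum(unitv(v) * pb$normal)))) / DEG)
    if (axis_angle <= tstack_axis_tol) "T-stack" else "edge-to-face"
  }
  out <- tibble::tibble(centroid_distance = d, interplanar_angle = ang,
                        class = cls)
  class(out) <- c("aromatic_contact", class(out))
  out
}

#' Audit expected inter-helical contacts
#'
#' Evaluates a list of expected interactions (hydrogen-bond networks,
#' aromatic stacks) against the structure.  Hydrogen bonds are satisfied
#' when the minimum polar side-chain heavy-atom distance is at most
#' `hbond_distance`; aromatic pairs when [classify_aromatic()] finds any
#' contact class.  Residues named by labels absent from the map or the
#' structure get status `"unresolvable"` rather than an error.
#'
#' @param h a `helix`/receptor atom table.
#' @param bw a `bw_map`.
#' @param expected data frame with columns `a`, `b` (Ballesteros-Weinstein
#'   labels, or absolute residue numbers as character) and optional `type`
#'   (`"hbond"`, default, or `"aromatic"`).
#' @param hbond_distance donor-acceptor criterion, Angstrom (default 3.5).
#' @return a tibble with one row per expected interaction: `a`, `b`, `type`,
#'   `status` (`"satisfied"`, `"unsatisfied"`, `"unresolvable"`),
#'   `satisfied`, `distance`; the counts are available via
#'   `attr(, "n_satisfied")` and `attr(, "n_total")`.
#' @export
contact_audit <- function(h, bw, expected, hbond_distance = 3.5) {
  h <- as_helix(h)
  expected <- tibble::as_tibble(expected)
  if (!"type" %in% names(expected)) expected$type <- "hbond"
  seqs <- helix_sequence(h)
  rows <- purrr::map_dfr(seq_len(nrow(expected)), function(k) {
    a <- resolve_bw(h, bw, expected$a[k])
    b <- resolve_bw(h, bw, expected$b[k])
    base <- tibble::tibble(a = expected$a[k], b = expected$b[k],
                           type = expected$type[k])
    if (is.na(a) || is.na(b)) {
      return(dplyr::mutate(base, status = "unresolvable", satisfied = NA,
                           distance = NA_real_))
    }
    if (expected$type[k] == "aromatic") {
      ok <- tryCatch({
        cc <- classify_aromatic(ring_coords(h, a), ring_coords(h, b))
        list(sat = cc$class != "none", d = cc$centroid_distance)
      }, error = function(e) NULL)
      if (is.null(ok)) {
        return(dplyr::mutate(base, status = "unresolvable", satisfied = NA,
                             distance = NA_real_))
      }
      return(dplyr::mutate(base,
                           status = ifelse(ok$sat, "satisfied", "unsatisfied"),
                           satisfied = ok$sat, distance = ok$d))
    }
    pa <- intersect(POLAR_SIDECHAIN[[seqs[[as.character(a)]]]] %||% character(),
                    h$atom[h$residue_index == a])
    pb <- intersect(POLAR_SIDECHAIN[[seqs[[as.character(b)]]]] %||% character(),
                    h$atom[h$residue_index == b])
    if (!length(pa) || !length(pb)) {
      return(dplyr::mutate(base, status = "unresolvable", satisfied = NA,
                           distance = NA_real_))
    }
    dmin <- min(vapply(pa, function(x) {
      min(vapply(pb, function(y) {
        vnorm(atom_xyz(h, a, x) - atom_xyz(h, b, y))
      }, numeric(1)))
    }, numeric(1)))
    sat <- dmin <= hbond_distance
    dplyr::mutate(base, status = ifelse(sat, "satisfied", "unsatisfied"),
                  satisfied = sat, distance = dmin)
  })
  attr(rows, "n_satisfied") <- sum(rows$satisfied %in% TRUE)
  attr(rows, "n_total") <- nrow(rows)
  rows
}

#' Audit the sodium-pocket residue set
#'
#' Checks that the polar residues lining the class A GPCR sodium site
#' (by default N1.50, D2.50, S3.39, N7.49 and Y7.53) are present in the map
#' and carry their polar side-chain atoms in the structure.
#'
#' @param h a `helix`/receptor atom table.
#' @param bw a `bw_map`.
#' @param residues Ballesteros-Weinstein labels of the pocket set.
#' @return a tibble: `label`, `residue_index`, `residue_name`, `present`.
#' @export
audit_sodium_pocket <- function(h, bw,
                                residues = c("1.50", "2.50", "3.39",
                                             "7.49", "7.53")) {
  h <- as_helix(h)
  seqs <- helix_sequence(h)
  purrr::map_dfr(residues, function(lbl) {
    i <- resolve_bw(h, bw, lbl)
    if (is.na(i)) {
      return(tibble::tibble(label = lbl, residue_index = NA_integer_,
                            residue_name = NA_character_, present = FALSE))
    }
    rn <- seqs[[as.character(i)]]
    polar <- POLAR_SIDECHAIN[[rn]] %||% character()
    tibble::tibble(label = lbl, residue_index = i, residue_name = rn,
                   present = length(intersect(polar,
                                              h$atom[h$residue_index == i])) > 0)
  })
}

#' Full microswitch state report
#'
#' Combines the ionic-lock detection, the toggle-switch chi1 rotamer states
#' (default triad F3.36, W6.48, F5.47), the sodium-pocket audit and an
#' optional contact audit into one report.
#'
#' @param h a `helix`/receptor atom table.
#' @param bw a `bw_map`.
#' @param toggle Ballesteros-Weinstein labels of the toggle-switch residues.
#' @param expected optional expected-contact table for [contact_audit()].
#' @param ... passed to [detect_ionic_lock()].
#' @return a `switch_report` list: `ionic_lock`, `toggle`, `sodium_pocket`,
#'   `contacts` (or `NULL`).
#' @export
switch_report <- function(h, bw, toggle = c("3.36", "6.48", "5.47"),
                          expected = NULL, ...) {
  h <- as_helix(h)
  seqs <- helix_sequence(h)
  tog <- purrr::map_dfr(toggle, function(lbl) {
    i <- resolve_bw(h, bw, lbl)
    if (is.na(i)) {
      return(tibble::tibble(label = lbl, residue_name = NA_character_,
                            chi1 = NA_real_, rotamer = NA_character_))
    }
    chi <- residue_chi1(h, i)
    tibble::tibble(label = lbl, residue_name = seqs[[as.character(i)]],
                   chi1 = chi,
                   rotamer = if (is.na(chi)) NA_character_ else classify_chi1(chi))
  })
  structure(list(
    ionic_lock = detect_ionic_lock(h, bw, ...),
    toggle = tog,
    sodium_pocket = audit_sodium_pocket(h, bw),
    contacts = if (!is.null(expected)) contact_audit(h, bw, expected)),
    class = "switch_report")
}

#' Write a switch report as JSON
#' @param report a `switch_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_switch_report <- function(report, path) {
  jsonlite::write_json(lapply(unclass(report), function(x) {
    if (is.null(x)) NULL else as.data.frame(x)
  }), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
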