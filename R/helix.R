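# A `helix` is a tibble of atom records (one row per heavy atom) with class
# c("helix", tibble classes).  Columns: residue_index, residue_name, chain,
# atom, element, x, y, z.  Internal coordinates are derived on demand with
# internal_coords() and structures are rebuilt with cartesian_from_internal().

new_helix <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("residue_index", "residue_name", "chain", "atom", "element",
              "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) {
    abort(paste0("atom table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  if (any(atoms$residue_index < 1)) abort("residue_index must be >= 1")
  class(atoms) <- c("helix", class(tibble::tibble()))
  atoms
}

#' Test for and coerce to helix atom tables
#' @param x object to coerce; a data frame of atom records.
#' @return `as_helix()` returns a `helix` tibble; `is_helix()` a logical.
#' @export
as_helix <- function(x) {
  if (inherits(x, "helix")) return(x)
  new_helix(x)
}

#' @rdname as_helix
#' @export
is_helix <- function(x) inherits(x, "helix")

#' @export
print.helix <- function(x, ...) {
  nres <- length(unique(x$residue_index))
  cat(sprintf("# A helix structure: %d residues, %d atoms\n", nres, nrow(x)))
  NextMethod()
}

#' Extract a coordinate matrix from a helix
#'
#' @param h a `helix` atom table.
#' @param atoms optional atom names to keep (e.g. `"CA"`).
#' @param residues optional residue indices to keep.
#' @return an n x 3 numeric matrix of coordinates (Angstrom).
#' @export
helix_coords <- function(h, atoms = NULL, residues = NULL) {
  keep <- rep(TRUE, nrow(h))
  if (!is.null(atoms)) keep <- keep & h$atom %in% atoms
  if (!is.null(residues)) keep <- keep & h$residue_index %in% residues
  as.matrix(h[keep, c("x", "y", "z")])
}

helix_sequence <- function(h) {
  u <- !duplicated(h$residue_index)
  setNames(h$residue_name[u], h$residue_index[u])
}

#' Coordinates of one named atom in one residue
#'
#' @param h a `helix` atom table.
#' @param residue_index absolute residue index.
#' @param atom atom name (e.g. `"CA"`).
#' @return a numeric 3-vector, or `NULL` if the atom is absent.
#' @export
atom_xyz <- function(h, residue_index, atom) {
  i <- which(h$residue_index == residue_index & h$atom == atom)
  if (!length(i)) return(NULL)
  as.numeric(h[i[1], c("x", "y", "z")])
}

# Atom (ref row dih == "chiK") defining each chi torsion of a residue type.
chi_definitions <- function(residue_name) {
  tmpl <- SIDECHAIN_TEMPLATES[[residue_name]]
  if (is.null(tmpl)) return(NULL)
  rows <- tmpl[grepl("^chi[0-9]$", tmpl$dih), , drop = FALSE]
  rows
}

#' Backbone and side-chain internal coordinates
#'
#' Measures per-residue backbone dihedrals (phi, psi, omega), the N-CA-C bond
#' angle (tau) and side-chain chi torsions from Cartesian coordinates.
#' `omega` is the torsion of the peptide bond preceding each residue
#' (CA(i-1)-C(i-1)-N(i)-CA(i)); terminal torsions that are undefined are `NA`.
#'
#' @param h a `helix` atom table.
#' @return a tibble with one row per residue: `residue_index`, `residue_name`,
#'   `phi`, `psi`, `omega`, `tau`, `chi1` ... `chi4` (degrees; `NA` where
#'   undefined).
#' @export
internal_coords <- function(h) {
  h <- as_helix(h)
  res <- sort(unique(h$residue_index))
  seq3 <- helix_sequence(h)
  out <- purrr::map_dfr(seq_along(res), function(k) {
    i <- res[k]
    Np <- atom_xyz(h, i, "N"); CAp <- atom_xyz(h, i, "CA")
    Cp <- atom_xyz(h, i, "C")
    phi <- psi <- omg <- tau <- NA_real_
    if (!is.null(Np) && !is.null(CAp) && !is.null(Cp)) {
      tau <- bond_angle(Np, CAp, Cp)
      if (k > 1) {
        Cm <- atom_xyz(h, res[k - 1], "C")
        CAm <- atom_xyz(h, res[k - 1], "CA")
        if (!is.null(Cm)) phi <- dihedral_angle(Cm, Np, CAp, Cp)
        if (!is.null(Cm) && !is.null(CAm)) omg <- dihedral_angle(CAm, Cm, Np, CAp)
      }
      if (k < length(res)) {
        Nn <- atom_xyz(h, res[k + 1], "N")
        if (!is.null(Nn)) psi <- dihedral_angle(Np, CAp, Cp, Nn)
      }
    }
    chi <- rep(NA_real_, 4)
    defs <- chi_definitions(seq3[[as.character(i)]])
    if (!is.null(defs) && nrow(defs)) {
      for (r in seq_len(nrow(defs))) {
        kk <- as.integer(substr(defs$dih[r], 4, 4))
        pts <- list(atom_xyz(h, i, defs$ref_a[r]), atom_xyz(h, i, defs$ref_b[r]),
                    atom_xyz(h, i, defs$ref_c[r]), atom_xyz(h, i, defs$name[r]))
        if (!any(vapply(pts, is.null, logical(1)))) {
          chi[kk] <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
        }
      }
    }
    tibble::tibble(residue_index = i, residue_name = seq3[[as.character(i)]],
                   phi = phi, psi = psi, omega = omg, tau = tau,
                   chi1 = chi[1], chi2 = chi[2], chi3 = chi[3], chi4 = chi[4])
  })
  out
}

# Build a structure in a canonical frame from an internal-coordinate table.
# `internal` needs residue_index, residue_name, phi, psi, omega, tau and
# optional chi1..chi4; missing taus fall back to the ideal value, missing
# chis to residue defaults.  Dihedrals missing for non-terminal residues are
# an error.
build_from_internal <- function(internal, chain = "A") {
  g <- IDEAL_GEOM
  n <- nrow(internal)
  if (n < 1) abort("internal table is empty")
  for (col in c("chi1", "chi2", "chi3", "chi4")) {
    if (is.null(internal[[col]])) internal[[col]] <- NA_real_
  }
  if (is.null(internal[["tau"]])) internal$tau <- NA_real_
  if (n > 1) {
    bad_phi <- which(is.na(internal$phi[-1])) + 1
    bad_psi <- which(is.na(internal$psi[-n]))
    bad_omg <- which(is.na(internal$omega[-1])) + 1
    if (length(bad_phi)) {
      abort(sprintf("phi missing for non-terminal residue %d",
                    internal$residue_index[bad_phi[1]]))
    }
    if (length(bad_psi)) {
      abort(sprintf("psi missing for non-terminal residue %d",
                    internal$residue_index[bad_psi[1]]))
    }
    if (length(bad_omg)) {
      abort(sprintf("omega missing for non-terminal residue %d",
                    internal$residue_index[bad_omg[1]]))
    }
  }
  rows <- vector("list", n)
  prev <- NULL  # list(N, CA, C)
  for (k in seq_len(n)) {
    rn <- internal$residue_name[k]
    ri <- internal$residue_index[k]
    tau <- internal$tau[k]
    if (is.na(tau)) tau <- g$a_n_ca_c
    if (k == 1) {
      N <- c(0, 0, 0)
      CA <- c(g$b_n_ca, 0, 0)
      th <- tau * DEG
      C <- CA + g$b_ca_c * c(-cos(th), sin(th), 0)
    } else {
      N <- place_atom(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n,
                      internal$psi[k - 1])
      CA <- place_atom(prev$CA, prev$C, N, g$b_n_ca, g$a_c_n_ca,
                       internal$omega[k])
      C <- place_atom(prev$C, N, CA, g$b_ca_c, tau, internal$phi[k])
    }
    psi_for_o <- internal$psi[k]
    if (is.na(psi_for_o)) psi_for_o <- 180
    O <- place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o, wrap_angle(psi_for_o + 180))
    placed <- list(N = N, CA = CA, C = C, O = O)
    tmpl <- SIDECHAIN_TEMPLATES[[rn]]
    if (is.null(tmpl) && !rn %in% names(SIDECHAIN_TEMPLATES)) {
      abort(sprintf("unknown residue code '%s' at position %d", rn, ri))
    }
    chi <- DEFAULT_CHI(rn)
    for (kk in 1:4) {
      v <- internal[[paste0("chi", kk)]][k]
      if (!is.na(v)) chi[paste0("chi", kk)] <- v
    }
    if (!is.null(tmpl)) {
      for (r in seq_len(nrow(tmpl))) {
        refs <- lapply(c(tmpl$ref_a[r], tmpl$ref_b[r], tmpl$ref_c[r]),
                       function(a) placed[[a]])
        placed[[tmpl$name[r]]] <- place_atom(refs[[1]], refs[[2]], refs[[3]],
                                             tmpl$bond[r], tmpl$angle[r],
                                             resolve_dih(tmpl$dih[r], chi))
      }
    }
    anames <- names(placed)
    xyz <- do.call(rbind, placed)
    rows[[k]] <- tibble::tibble(
      residue_index = ri, residue_name = rn, chain = chain,
      atom = anames, element = element_of(anames),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    prev <- placed[c("N", "CA", "C")]
  }
  new_helix(dplyr::bind_rows(rows))
}

#' Rebuild Cartesian coordinates from internal coordinates
#'
#' Measures the internal coordinates of `h` (backbone phi/psi/omega, the
#' N-CA-C bond angle and side-chain chi torsions), rebuilds the structure by
#' sequential extension from ideal covalent geometry, and superposes the
#' rebuilt copy onto the input frame.  For structures that were themselves
#' built from internal coordinates the round trip is the identity.
#'
#' @param h a `helix` atom table, or an internal-coordinate tibble as returned
#'   by [internal_coords()] (then `chain` names the output chain).
#' @param chain chain identifier for rebuilt atoms when `h` is an internal
#'   table.
#' @return a `helix` with rebuilt coordinates.
#' @export
cartesian_from_internal <- function(h, chain = "A") {
  if (!is_helix(h) && is.data.frame(h) && !is.null(h$phi)) {
    return(build_from_internal(tibble::as_tibble(h), chain = chain))
  }
  h <- as_helix(h)
  ic <- internal_coords(h)
  rebuilt <- build_from_internal(ic, chain = h$chain[1])
  # align onto the original frame using shared backbone atoms
  key <- function(x) paste(x$residue_index, x$atom)
  shared <- intersect(key(h), key(rebuilt))
  shared <- shared[match(shared, key(h)) > 0]
  a <- as.matrix(h[match(shared, key(h)), c("x", "y", "z")])
  b <- as.matrix(rebuilt[match(shared, key(rebuilt)), c("x", "y", "z")])
  if (nrow(a) >= 3) {
    fit <- kabsch_fit(a, b)
    xyz <- as.matrix(rebuilt[, c("x", "y", "z")])
    xyz <- sweep(sweep(xyz, 2, fit$center_b) %*% t(fit$rotation), 2,
                 fit$center_a, `+`)
    rebuilt$x <- xyz[, 1]; rebuilt$y <- xyz[, 2]; rebuilt$z <- xyz[, 3]
  }
  rebuilt
}

# Bond list (2-column matrix of atom row indices) from residue templates,
# backbone connectivity and ring closures.
helix_bonds <- function(h) {
  h <- as_helix(h)
  idx <- function(ri, an) which(h$residue_index == ri & h$atom == an)[1]
  res <- sort(unique(h$residue_index))
  seq3 <- helix_sequence(h)
  bonds <- list()
  add <- function(i, j) {
    if (!is.na(i) && !is.na(j)) bonds[[length(bonds) + 1]] <<- c(i, j)
  }
  for (k in seq_along(res)) {
    i <- res[k]
    add(idx(i, "N"), idx(i, "CA"))
    add(idx(i, "CA"), idx(i, "C"))
    add(idx(i, "C"), idx(i, "O"))
    if (k < length(res)) add(idx(i, "C"), idx(res[k + 1], "N"))
    rn <- seq3[[as.character(i)]]
    tmpl <- SIDECHAIN_TEMPLATES[[rn]]
    if (!is.null(tmpl)) {
      for (r in seq_len(nrow(tmpl))) add(idx(i, tmpl$ref_c[r]), idx(i, tmpl$name[r]))
    }
    for (cl in RING_CLOSURES[[rn]] %||% list()) add(idx(i, cl[1]), idx(i, cl[2]))
  }
  do.call(rbind, bonds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
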