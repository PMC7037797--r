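# Molecular-mechanics energy evaluation: Lennard-Jones 12-6 + Coulomb with
# configurable dielectric and cutoffs, plus cosine torsion series.

#' Cosine-series torsion energy
#'
#' `E(theta) = sum_k A_k * (1 + cos(n_k * theta - delta_k))`, the standard
#' molecular-mechanics dihedral form; periodic with period `360 / gcd(n_k)`.
#'
#' @param angle torsion angle(s), degrees.
#' @param terms data frame with columns `amplitude` (kcal/mol), `periodicity`
#'   (positive integer) and `phase` (degrees).
#' @return energy in kcal/mol, vectorised over `angle`.
#' @export
torsion_energy <- function(angle, terms) {
  if (is.null(terms) || nrow(terms) == 0) abort("torsion term list is empty")
  vapply(angle, function(th) {
    sum(terms$amplitude *
          (1 + cos((terms$periodicity * th - terms$phase) * DEG)))
  }, numeric(1))
}

# Pairs at bonded graph distance 1 (1-2) or 2 (1-3); returns a 2-column
# matrix of excluded atom index pairs (i < j).
bonded_exclusions <- function(bonds, n_atoms) {
  if (is.null(bonds) || nrow(bonds) == 0) return(matrix(0L, 0, 2))
  adj <- vector("list", n_atoms)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (i in seq_len(n_atoms)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one]))
    ex <- setdiff(union(one, two), i)
    ex <- ex[ex > i]
    if (length(ex)) out[[length(out) + 1]] <- cbind(i, ex)
  }
  m <- do.call(rbind, out)
  if (is.null(m)) matrix(0L, 0, 2) else m
}

# Nonbonded pair energies over explicit index pairs; returns per-pair coulomb
# and LJ vectors (cutoffs applied per term).
pair_energies <- function(xyz, q, eps, rmin, pairs, dielectric,
                          cutoff_nb, cutoff_elec) {
  if (nrow(pairs) == 0) {
    return(list(coulomb = numeric(0), lj = numeric(0), r = numeric(0)))
  }
  d <- xyz[pairs[, 1], , drop = FALSE] - xyz[pairs[, 2], , drop = FALSE]
  r2 <- rowSums(d * d)
  if (any(r2 < 1e-12)) {
    abort("zero interatomic distance between paired atoms (singularity)")
  }
  r <- sqrt(r2)
  qq <- q[pairs[, 1]] * q[pairs[, 2]]
  ecoul <- if (dielectric$model == "distance") {
    COULOMB_CONST * qq / (dielectric$coefficient * r2)
  } else {
    COULOMB_CONST * qq / (dielectric$coefficient * r)
  }
  ecoul[r > cutoff_elec] <- 0
  eij <- sqrt(eps[pairs[, 1]] * eps[pairs[, 2]])
  rm <- (rmin[pairs[, 1]] + rmin[pairs[, 2]]) / 2
  s6 <- (rm / r)^6
  elj <- eij * (s6 * s6 - 2 * s6)
  elj[r > cutoff_nb] <- 0
  list(coulomb = ecoul, lj = elj, r = r)
}

#' Evaluate molecular-mechanics energy
#'
#' Sums Coulomb (`332.0636 q_i q_j / (eps(r) r)`), Lennard-Jones 12-6 and
#' optional torsion-series terms.  In single-structure mode all nonbonded
#' pairs are evaluated with 1-2 and 1-3 bonded pairs excluded (1-4 pairs
#' included at `scale14`); in group-pair mode only pairs crossing the two
#' disjoint atom groups are counted.
#'
#' @param atoms a `helix`/atom tibble (columns `residue_name`, `atom`,
#'   `element`, `x`, `y`, `z`).
#' @param params a `forcefield` (default [default_forcefield()]).
#' @param group_a,group_b optional row-index (or logical) vectors selecting
#'   two disjoint atom groups; if given, only cross-group pairs count.
#' @param bonds optional 2-column matrix of bonded atom row pairs (defaults
#'   to the template-derived topology for helices).
#' @param torsions optional list of torsion assignments, each
#'   `list(atoms = <4 row indices>, class = <torsion class name>)`.
#' @param cutoff_nb,cutoff_elec Lennard-Jones and electrostatic cutoffs
#'   (Angstrom); pairs beyond a cutoff contribute zero to that term.
#' @param dielectric override the force field's dielectric model, e.g.
#'   `list(model = "distance", coefficient = 2)`.
#' @param scale14 multiplicative weight on 1-4 nonbonded pairs (default 1,
#'   i.e. full weight).
#' @return an `energy_breakdown`: one-row tibble with `torsional`,
#'   `lennard_jones`, `coulomb` and `total` (kcal/mol).
#' @export
evaluate_energy <- function(atoms, params = default_forcefield(),
                            group_a = NULL, group_b = NULL, bonds = NULL,
                            torsions = NULL,
                            cutoff_nb = 8, cutoff_elec = 20,
                            dielectric = NULL, scale14 = 1) {
  if (cutoff_nb <= 0 || cutoff_elec <= 0) abort("cutoffs must be positive")
  if (is.null(bonds) && is_helix(atoms)) bonds <- helix_bonds(atoms)
  atoms <- tibble::as_tibble(atoms)
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  q <- ff_charges(params, atoms$residue_name, atoms$atom)
  lj <- ff_lj(params, atoms$element, atoms$residue_name, atoms$atom)
  dielectric <- dielectric %||% params$dielectric

  if (!is.null(group_a) || !is.null(group_b)) {
    ia <- if (is.logical(group_a)) which(group_a) else as.integer(group_a)
    ib <- if (is.logical(group_b)) which(group_b) else as.integer(group_b)
    if (!length(ia) || !length(ib)) abort("atom groups must be non-empty")
    if (length(intersect(ia, ib))) abort("atom groups must be disjoint")
    pairs <- as.matrix(expand.grid(ia, ib))
    w <- rep(1, nrow(pairs))
  } else {
    if (n < 2) {
      pairs <- matrix(0L, 0, 2); w <- numeric(0)
    } else {
      pairs <- t(utils::combn(n, 2))
      excl <- bonded_exclusions(bonds, n)
      keep <- !(paste(pairs[, 1], pairs[, 2]) %in% paste(excl[, 1], excl[, 2]))
      pairs <- pairs[keep, , drop = FALSE]
      w <- rep(1, nrow(pairs))
      if (scale14 != 1 && !is.null(bonds) && nrow(bonds)) {
        g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
        dmat <- igraph::distances(g)
        is14 <- dmat[pairs] == 3
        w[is14] <- scale14
      }
    }
  }
  pe <- pair_energies(xyz, q, lj$eps, lj$rmin, pairs, dielectric,
                      cutoff_nb, cutoff_elec)
  etor <- 0
  for (t in torsions %||% list()) {
    terms <- params$torsions[[t$class]]
    if (is.null(terms)) abort(sprintf("no torsion class '%s' in force field", t$class))
    p <- xyz[t$atoms, ]
    etor <- etor + torsion_energy(
      dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]), terms)
  }
  breakdown <- tibble::tibble(
    torsional = etor,
    lennard_jones = sum(pe$lj * w),
    coulomb = sum(pe$coulomb * w),
    total = NA_real_)
  breakdown$total <- breakdown$torsional + breakdown$lennard_jones +
    breakdown$coulomb
  class(breakdown) <- c("energy_breakdown", class(breakdown))
  breakdown
}
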