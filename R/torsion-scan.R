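# Systematic torsion scans of small molecules and docked-vs-global-minimum
# conformational-cost accounting.

#' Construct a small molecule
#'
#' A molecule is an atom tibble plus an explicit bond list (torsion
#' definitions need the bond topology).  Atoms may carry a `charge` column;
#' missing charges default to zero.
#'
#' @param atoms tibble with columns `name`, `element`, `x`, `y`, `z` and
#'   optional `charge`.
#' @param bonds two-column matrix/data frame of bonded atom row indices.
#' @return a `molecule` tibble with the bond list as attribute `bonds`.
#' @export
molecule <- function(atoms, bonds) {
  atoms <- tibble::as_tibble(atoms)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  bonds <- as.matrix(bonds)
  if (ncol(bonds) != 2) abort("bonds must have two columns")
  if (any(bonds < 1) || any(bonds > nrow(atoms))) {
    abort("bond indices outside the atom table")
  }
  attr(atoms, "bonds") <- bonds
  class(atoms) <- c("molecule", class(atoms))
  atoms
}

mol_graph <- function(mol) {
  igraph::graph_from_edgelist(attr(mol, "bonds"), directed = FALSE)
}

# Atom indices on the d-side of the rotatable bond b-c (errors for ring
# bonds, which are not rotatable).
mol_moved_side <- function(mol, quad) {
  b <- quad[2]; c <- quad[3]
  g <- mol_graph(mol)
  g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(b, c)))
  comp <- igraph::components(g2)$membership
  if (comp[b] == comp[c]) {
    abort(sprintf("bond %d-%d lies in a ring and is not rotatable", b, c))
  }
  which(comp == comp[c])
}

mol_torsion <- function(mol, quad) {
  xyz <- as.matrix(mol[, c("x", "y", "z")])
  dihedral_angle(xyz[quad[1], ], xyz[quad[2], ], xyz[quad[3], ], xyz[quad[4], ])
}

mol_set_torsion <- function(mol, quad, target) {
  xyz <- as.matrix(mol[, c("x", "y", "z")])
  moved <- setdiff(mol_moved_side(mol, quad), quad[2:3])
  cur <- mol_torsion(mol, quad)
  b <- xyz[quad[2], ]; c <- xyz[quad[3], ]
  xyz[moved, ] <- rotate_about_axis(xyz[moved, , drop = FALSE], c, c - b,
                                    -(wrap_angle(target - cur)))
  mol$x <- xyz[, 1]; mol$y <- xyz[, 2]; mol$z <- xyz[, 3]
  mol
}

# Total molecular-mechanics energy: torsion terms of the declared rotatable
# bonds plus nonbonded pairs separated by more than three bonds.
mol_energy <- function(mol, rotatable, params,
                       cutoff_nb = 8, cutoff_elec = 20,
                       dielectric = NULL) {
  dielectric <- dielectric %||% params$dielectric
  e <- 0
  for (k in seq_len(nrow(rotatable))) {
    terms <- params$torsions[[rotatable$class[k]]]
    if (is.null(terms)) {
      abort(sprintf("no torsion class '%s' in force field", rotatable$class[k]))
    }
    quad <- as.integer(rotatable[k, c("a", "b", "c", "d")])
    e <- e + torsion_energy(mol_torsion(mol, quad), terms)
  }
  g <- mol_graph(mol)
  dmat <- igraph::distances(g)
  n <- nrow(mol)
  if (n >= 2) {
    pairs <- t(utils::combn(n, 2))
    pairs <- pairs[dmat[pairs] > 3, , drop = FALSE]
    if (nrow(pairs)) {
      lj <- ff_lj(params, mol$element)
      pe <- pair_energies(as.matrix(mol[, c("x", "y", "z")]), mol$charge,
                          lj$eps, lj$rmin, pairs, dielectric,
                          cutoff_nb, cutoff_elec)
      e <- e + sum(pe$lj) + sum(pe$coulomb)
    }
  }
  as.numeric(e)
}

# Energy as a function of the rotatable-torsion vector.
mol_energy_at <- function(theta, mol, rotatable, params, ...) {
  for (k in seq_len(nrow(rotatable))) {
    mol <- mol_set_torsion(mol, as.integer(rotatable[k, c("a", "b", "c", "d")]),
                           theta[k])
  }
  mol_energy(mol, rotatable, params, ...)
}

# Local minimisation on the torsional coordinates.  Each torsion is bounded
# to half the spacing of its fold-rotamer wells around the start, so a start
# relaxes into its own basin instead of hopping wells.
minimize_torsions <- function(mol, rotatable, params, grad_tol = 1e-4, ...) {
  theta0 <- vapply(seq_len(nrow(rotatable)), function(k) {
    mol_torsion(mol, as.integer(rotatable[k, c("a", "b", "c", "d")]))
  }, numeric(1))
  window <- 180 / rotatable$fold
  f <- function(th) mol_energy_at(th, mol, rotatable, params, ...)
  opt <- optim(theta0, f, method = "L-BFGS-B",
               lower = theta0 - window, upper = theta0 + window,
               control = list(factr = 10, pgtol = 1e-12, maxit = 500))
  # verify the gradient criterion by central differences
  h <- 1e-3
  g <- vapply(seq_along(opt$par), function(k) {
    tp <- opt$par; tm <- opt$par
    tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
  list(theta = wrap_angle(opt$par), energy = opt$value,
       grad_norm = max(abs(g)), converged = max(abs(g)) < grad_tol)
}

#' Enumerate torsional conformers and minimise each
#'
#' Generates the Cartesian product of fold-rotamer starting points for every
#' rotatable bond (120 deg increments for 3-fold bonds, 180 deg for 2-fold),
#' locally minimises each start on the torsional coordinates, removes
#' duplicates closer than `dedup_threshold` on every torsion, and sorts by
#' energy.
#'
#' @param mol a [molecule()].
#' @param rotatable data frame of rotatable bonds: columns `a`, `b`, `c`,
#'   `d` (atom row indices of the torsion quadruple), `fold` (2 or 3) and
#'   `class` (torsion class name in `params`).
#' @param params a `forcefield`.
#' @param dedup_threshold torsion-space distance (degrees, max over bonds)
#'   below which two conformers are duplicates (default 20).
#' @param ... passed to the energy evaluation (cutoffs, dielectric).
#' @return a `conformer_set`: list with `torsions` (matrix, one row per
#'   retained conformer), `energies`, `conformers` (list of molecules),
#'   `global_min_index` (always 1 after sorting) and `dedup_threshold`.
#' @export
enumerate_and_minimize <- function(mol, rotatable, params = default_forcefield(),
                                   dedup_threshold = 20, ...) {
  rotatable <- tibble::as_tibble(rotatable)
  if (nrow(rotatable) > 0 && !all(rotatable$fold %in% c(2, 3))) {
    abort("fold must be 2 or 3")
  }
  # validate rotatability up front (rings rejected here)
  for (k in seq_len(nrow(rotatable))) {
    mol_moved_side(mol, as.integer(rotatable[k, c("a", "b", "c", "d")]))
  }
  if (nrow(rotatable) == 0) {
    return(structure(list(torsions = matrix(numeric(0), 1, 0),
                          energies = mol_energy(mol, rotatable, params, ...),
                          conformers = list(mol), global_min_index = 1L,
                          dedup_threshold = dedup_threshold),
                     class = "conformer_set"))
  }
  theta0 <- vapply(seq_len(nrow(rotatable)), function(k) {
    mol_torsion(mol, as.integer(rotatable[k, c("a", "b", "c", "d")]))
  }, numeric(1))
  offsets <- lapply(rotatable$fold, function(f) {
    if (f == 3) c(0, 120, 240) else c(0, 180)
  })
  grid <- as.matrix(expand.grid(offsets))
  starts <- sweep(grid, 2, theta0, `+`)
  fits <- lapply(seq_len(nrow(starts)), function(s) {
    m <- mol
    for (k in seq_len(nrow(rotatable))) {
      m <- mol_set_torsion(m, as.integer(rotatable[k, c("a", "b", "c", "d")]),
                           starts[s, k])
    }
    minimize_torsions(m, rotatable, params, ...)
  })
  ord <- order(vapply(fits, `[[`, 0, "energy"))
  kept <- list()
  for (s in ord) {
    dup <- any(vapply(kept, function(k) {
      all(abs(wrap_angle(fits[[s]]$theta - k$theta)) < dedup_threshold)
    }, logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- fits[[s]]
  }
  torsions <- do.call(rbind, lapply(kept, `[[`, "theta"))
  energies <- vapply(kept, `[[`, 0, "energy")
  conformers <- lapply(kept, function(k) {
    m <- mol
    for (j in seq_len(nrow(rotatable))) {
      m <- mol_set_torsion(m, as.integer(rotatable[j, c("a", "b", "c", "d")]),
                           k$theta[j])
    }
    m
  })
  structure(list(torsions = torsions, energies = energies,
                 conformers = conformers, global_min_index = 1L,
                 dedup_threshold = dedup_threshold),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("# Conformer set: %d conformers, global minimum %.4f kcal/mol\n",
              length(x$energies), x$energies[x$global_min_index]))
  invisible(x)
}

#' Conformational cost of a docked pose
#'
#' The energy paid to adopt the bound conformation: the single-point energy
#' of the docked pose minus the energy of the global-minimum conformer after
#' relaxation on the torsional coordinates (to a gradient below 0.01
#' kcal/mol/deg).
#'
#' @param docked the docked-pose [molecule()].
#' @param global_min the global-minimum conformer (same topology), e.g.
#'   `conformer_set$conformers[[1]]`.
#' @param rotatable rotatable-bond table (see [enumerate_and_minimize()]).
#' @param params a `forcefield`.
#' @param ... passed to the energy evaluation.
#' @return cost in kcal/mol.
#' @export
conformational_cost <- function(docked, global_min, rotatable,
                                params = default_forcefield(), ...) {
  if (nrow(docked) != nrow(global_min) ||
      !identical(docked$name, global_min$name) ||
      !identical(attr(docked, "bonds"), attr(global_min, "bonds"))) {
    abort("docked pose and global minimum have mismatched topology")
  }
  rotatable <- tibble::as_tibble(rotatable)
  e_docked <- mol_energy(docked, rotatable, params, ...)
  e_min <- if (nrow(rotatable)) {
    minimize_torsions(global_min, rotatable, params, grad_tol = 0.01, ...)$energy
  } else {
    mol_energy(global_min, rotatable, params, ...)
  }
  e_docked - e_min
}
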