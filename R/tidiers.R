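# broom-style tidiers for the package's result objects.

#' Tidy a Conformational Memories run
#'
#' One row per output conformer with its energy.
#' @param x a `cm_run`.
#' @param ... unused.
#' @return a tibble with columns `frame`, `energy`.
#' @export
tidy.cm_run <- function(x, ...) x$energies

#' One-row summary of a Conformational Memories run
#'
#' @param x a `cm_run`.
#' @param ... unused.
#' @return a tibble: ensemble size, free dihedral count, energy range,
#'   final-temperature acceptance rate and seed.
#' @export
glance.cm_run <- function(x, ...) {
  fin <- x$acceptance[x$acceptance$phase == "biased", ]
  fin <- fin[nrow(fin), ]
  tibble::tibble(
    n_conformers = length(x$ensemble),
    n_free_dihedrals = nrow(x$spec$dihedrals),
    energy_min = min(x$energies$energy),
    energy_max = max(x$energies$energy),
    final_acceptance_rate = fin$accepted / fin$steps,
    seed = x$provenance$seed)
}

#' Tidy a conformer set
#'
#' @param x a `conformer_set`.
#' @param ... unused.
#' @return a tibble with one row per conformer: `conformer`, `energy` and
#'   one `torsion_k` column per rotatable bond.
#' @export
tidy.conformer_set <- function(x, ...) {
  out <- tibble::tibble(conformer = seq_along(x$energies),
                        energy = x$energies)
  tor <- x$torsions
  if (!is.null(tor) && ncol(tor) > 0) {
    colnames(tor) <- paste0("torsion_", seq_len(ncol(tor)))
    out <- dplyr::bind_cols(out, tibble::as_tibble(tor))
  }
  out
}

#' One-row summary of a conformer set
#' @param x a `conformer_set`.
#' @param ... unused.
#' @return a tibble: conformer count, global-minimum energy, energy spread.
#' @export
glance.conformer_set <- function(x, ...) {
  tibble::tibble(n_conformers = length(x$energies),
                 global_min_energy = x$energies[x$global_min_index],
                 energy_spread = diff(range(x$energies)))
}

#' Tidy an interaction table
#' @param x an `interaction_table`.
#' @param ... unused.
#' @return the per-residue tibble (already tidy), stripped of its class.
#' @export
tidy.interaction_table <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of an interaction table
#' @param x an `interaction_table`.
#' @param ... unused.
#' @return a tibble: residue count, total interaction energy, shell radius,
#'   flagged hydrogen-bond count.
#' @export
glance.interaction_table <- function(x, ...) {
  hb <- attr(x, "hbonds")
  tibble::tibble(n_residues = nrow(x),
                 total_interaction = attr(x, "total_interaction"),
                 shell_radius = attr(x, "shell_radius"),
                 n_hbond_flags = if (is.null(hb)) 0L else nrow(hb))
}
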