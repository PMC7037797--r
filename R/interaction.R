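# Per-residue decomposition of ligand-receptor interaction energies.

#' Per-residue ligand-receptor interaction energies
#'
#' Decomposes the nonbonded interaction of a bound ligand into per-residue
#' Coulombic and van der Waals terms.  Only residues with at least one atom
#' within `shell` of any ligand atom are tabulated; each residue's terms are
#' the group-pair energy of the ligand against that residue under the given
#' cutoffs and a distance-dependent dielectric of 2 (eps(r) = 2r) by
#' default.  Rows are sorted most stabilising first (ascending sum).
#' Ligand-residue heavy-atom pairs of nitrogen/oxygen within `hbond_cutoff`
#' are flagged as potential hydrogen bonds in the `hbonds` attribute (a
#' reporting criterion, not a separate energy term).
#'
#' @param complex atom tibble of the ligand-receptor complex.
#' @param ligand ligand selector: a logical vector over atoms, a chain
#'   identifier, or a residue name (e.g. `"LIG"`).
#' @param params a `forcefield`.
#' @param bw optional `bw_map` used to attach Ballesteros-Weinstein labels.
#' @param shell residue-inclusion radius around the ligand, Angstrom
#'   (default 5).
#' @param cutoff_nb,cutoff_elec van der Waals and electrostatic cutoffs
#'   (default 8 and 20 Angstrom).
#' @param dielectric dielectric model (default distance-dependent with
#'   coefficient 2).
#' @param hbond_cutoff distance below which polar pairs are flagged
#'   (default 4 Angstrom).
#' @return an `interaction_table` tibble: `residue_index`, `residue_name`,
#'   `label`, `coulomb`, `vdw`, `sum` (kcal/mol), with attributes
#'   `total_interaction`, `shell_radius` and `hbonds`.
#' @export
pairwise_interaction <- function(complex, ligand, params = default_forcefield(),
                                 bw = NULL, shell = 5,
                                 cutoff_nb = 8, cutoff_elec = 20,
                                 dielectric = list(model = "distance",
                                                   coefficient = 2),
                                 hbond_cutoff = 4) {
  complex <- tibble::as_tibble(complex)
  lig <- if (is.logical(ligand)) ligand
  else complex$residue_name %in% ligand | complex$chain %in% ligand
  if (!any(lig)) abort("ligand atom group is empty")
  if (all(lig)) abort("ligand selection leaves no receptor atoms")
  lxyz <- as.matrix(complex[lig, c("x", "y", "z")])
  rec <- which(!lig)
  rxyz <- as.matrix(complex[rec, c("x", "y", "z")])
  # minimum distance of each receptor atom to any ligand atom
  mind <- apply(rxyz, 1, function(p) {
    sqrt(min(rowSums(sweep(lxyz, 2, p)^2)))
  })
  rres <- complex$residue_index[rec]
  shell_res <- sort(unique(rres[mind <= shell]))
  empty_rows <- tibble::tibble(residue_index = integer(),
                               residue_name = character(),
                               label = character(), coulomb = numeric(),
                               vdw = numeric(), sum = numeric())
  rows <- purrr::map_dfr(shell_res, function(ri) {
    sel <- which(!lig & complex$residue_index == ri)
    e <- evaluate_energy(complex, params, group_a = which(lig), group_b = sel,
                         cutoff_nb = cutoff_nb, cutoff_elec = cutoff_elec,
                         dielectric = dielectric)
    tibble::tibble(residue_index = ri,
                   residue_name = complex$residue_name[sel[1]],
                   label = if (!is.null(bw)) bw_label(bw, ri) else
                     as.character(ri),
                   coulomb = e$coulomb, vdw = e$lennard_jones,
                   sum = e$coulomb + e$lennard_jones)
  })
  if (nrow(rows) == 0) rows <- empty_rows
  rows <- rows[order(rows$sum), ]
  # potential hydrogen bonds: polar heavy-atom pairs within hbond_cutoff
  lidx <- which(lig)
  polar_l <- lidx[complex$element[lidx] %in% c("N", "O")]
  polar_r <- rec[complex$element[rec] %in% c("N", "O") &
                   rres %in% shell_res]
  hb <- purrr::map_dfr(polar_l, function(i) {
    if (!length(polar_r)) return(NULL)
    p <- as.numeric(complex[i, c("x", "y", "z")])
    d <- sqrt(rowSums(sweep(as.matrix(complex[polar_r, c("x", "y", "z")]),
                            2, p)^2))
    keep <- which(d <= hbond_cutoff)
    if (!length(keep)) return(NULL)
    tibble::tibble(ligand_atom = complex$atom[i],
                   residue_index = complex$residue_index[polar_r[keep]],
                   receptor_atom = complex$atom[polar_r[keep]],
                   distance = d[keep])
  })
  attr(rows, "total_interaction") <- sum(rows$sum)
  attr(rows, "shell_radius") <- shell
  attr(rows, "hbonds") <- hb
  class(rows) <- c("interaction_table", class(rows))
  rows
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("# Ligand-receptor interaction table (%d residues in %.1f A shell)\n",
              nrow(x), attr(x, "shell_radius")))
  cat(sprintf("# total interaction energy: %.2f kcal/mol\n",
              attr(x, "total_interaction")))
  NextMethod()
}

#' Write an interaction table as TSV plus JSON summary
#'
#' @param table an `interaction_table`.
#' @param path output TSV path; a `.json` summary (total, shell radius,
#'   flagged hydrogen bonds) is written alongside.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(total_interaction = attr(table, "total_interaction"),
         shell_radius = attr(table, "shell_radius"),
         n_residues = nrow(table),
         hbonds = as.data.frame(attr(table, "hbonds"))),
    sub("\\.tsv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
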