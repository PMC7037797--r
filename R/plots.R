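# ggplot2 graphics for the package's result objects.

#' Plot the memory map of a Conformational Memories run
#'
#' Per-dihedral histograms of the exploratory-phase accepted states, with
#' retained bins highlighted.
#'
#' @param memory the `memory` tibble of a `cm_run` (or the run itself).
#' @return a ggplot object.
#' @export
plot_memory_map <- function(memory) {
  if (inherits(memory, "cm_run")) memory <- memory$memory
  memory$dihedral <- paste(memory$residue_index, memory$name, sep = ".")
  ggplot2::ggplot(memory,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                               y = .data$count, fill = .data$retained)) +
    ggplot2::geom_col(width = NA) +
    ggplot2::facet_wrap(~dihedral, scales = "free_y") +
    ggplot2::labs(x = "dihedral angle (deg)", y = "accepted states",
                  fill = "retained") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cm_run <- function(object, type = c("memory", "energy",
                                             "acceptance"), ...) {
  type <- match.arg(type)
  if (type == "memory") return(plot_memory_map(object))
  if (type == "energy") {
    return(ggplot2::ggplot(object$energies,
                           ggplot2::aes(.data$frame, .data$energy)) +
             ggplot2::geom_line() + ggplot2::geom_point(size = 0.6) +
             ggplot2::labs(x = "conformer", y = "energy (kcal/mol)") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(object$acceptance,
                  ggplot2::aes(.data$temperature, .data$accepted / .data$steps,
                               colour = .data$phase)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "temperature (K)", y = "acceptance rate") +
    ggplot2::theme_minimal()
}

#' Plot a trajectory RMSD trace
#'
#' @param rmsd a tibble from [trajectory_rmsd()].
#' @return a ggplot object.
#' @export
plot_rmsd <- function(rmsd) {
  ggplot2::ggplot(rmsd, ggplot2::aes(.data$frame, .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "RMSD (Å)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.interaction_table <- function(object, ...) {
  d <- tidy.interaction_table(object)
  d <- tidyr::pivot_longer(d, c("coulomb", "vdw"), names_to = "term",
                           values_to = "energy")
  d$label <- factor(d$label, levels = rev(unique(d$label)))
  ggplot2::ggplot(d, ggplot2::aes(.data$energy, .data$label,
                                  fill = .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "interaction energy (kcal/mol)", y = "residue",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
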