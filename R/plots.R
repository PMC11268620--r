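# ggplot2 views of the package's result types.

#' Dihedral map of conformation calls
#'
#' Scatter of the two DFG pseudo-dihedrals (the Y-axis torsion over DFG-2,
#' DFG-1, DFG-Asp, DFG-Phe against the X-axis torsion over DFG-Asp, DFG-Phe,
#' DFG-Gly, DFG+1), coloured by conformation label — the standard view of
#' DFG-motif movement across a model set.
#'
#' @param calls Call tibble from [classify_structures()].
#' @return A ggplot object.
#' @export
plot_dihedral_map <- function(calls) {
  calls <- calls[!calls$excluded & !is.na(calls$dihedral_x) &
                   !is.na(calls$dihedral_y), , drop = FALSE]
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$dihedral_x,
                                      y = .data$dihedral_y,
                                      colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    ggplot2::scale_y_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = "pseudo-dihedral X (DFG-Asp..DFG+1, deg)",
                  y = "pseudo-dihedral Y (DFG-2..DFG-Phe, deg)",
                  colour = "conformation") +
    ggplot2::theme_minimal()
}

#' Bar chart of a conformation distribution
#'
#' @param dist Tibble from [conformation_distribution()].
#' @param facet_by Optional stratification column to facet on.
#' @return A ggplot object.
#' @export
plot_conformation_distribution <- function(dist, facet_by = NULL) {
  p <- ggplot2::ggplot(dist, ggplot2::aes(x = .data$label,
                                          y = .data$fraction,
                                          fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "fraction of classified structures") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(facet_by)) {
    p <- p + ggplot2::facet_wrap(facet_by)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an enrichment curve
#'
#' Percent of known actives retrieved against the top percent of the ranked
#' database examined, with the diagonal random-retrieval line (AUC 50).
#'
#' @param object An `enrichment_result` from [enrichment_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$pct_db_examined,
                               y = .data$pct_actives_found)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "red") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "% of ranked database examined",
                  y = "% of known ligands identified",
                  title = sprintf("%s  (AUC = %.2f)",
                                  object$model_id %||% "", object$auc)) +
    ggplot2::theme_minimal()
}
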