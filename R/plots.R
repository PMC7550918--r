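#' Plot a residue correlation profile
#'
#' Horizontal bars of each residue's correlation with activity, coloured by
#' sign: negative (favourable-contribution residues, the cluster candidates)
#' versus positive.
#'
#' @param object A `residue_profile` from [residue_correlations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(residue_correlations(cox2_energies(), cox2_activities()))
#' @export
autoplot.residue_profile <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$defined)
  df$residue <- factor(df$residue, levels = rev(df$residue))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$residue,
                                   fill = .data$r < 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166AC", `FALSE` = "#B2182B")) +
    ggplot2::labs(x = "Pearson r with pIC50", y = NULL,
                  title = "Per-residue energy–activity correlation") +
    ggplot2::theme_minimal()
}

#' Plot a cluster calibration scatter
#'
#' Cumulative cluster energy versus activity per compound, with the
#' least-squares line. A tight, negatively sloped scatter is what a useful
#' cluster looks like: more favourable (more negative) cumulative energy for
#' more potent compounds.
#'
#' @param object A `cluster_cor` object.
#' @param label_compounds Annotate points with compound identifiers?
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(cluster_correlation(cox2_energies(), cox2_activities(),
#'                              cox2_cluster()))
#' @export
autoplot.cluster_cor <- function(object, label_compounds = TRUE, ...) {
  df <- object$energies
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$energy, y = .data$pic50)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey55", linewidth = 0.6) +
    ggplot2::geom_point(size = 2.4, colour = "#2166AC") +
    ggplot2::labs(
      x = "Cumulative cluster energy (kJ/mol)",
      y = "pIC50",
      title = sprintf("%d-residue cluster, r = %.2f", length(object$residues),
                      object$r),
      subtitle = paste(object$residues, collapse = ", ")
    ) +
    ggplot2::theme_minimal()
  if (label_compounds) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$compound),
                                vjust = -0.9, size = 2.8, colour = "grey30")
  }
  p
}
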