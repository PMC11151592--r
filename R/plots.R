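#' Forest plot of a pooled meta-analytic effect
#'
#' @param object A `meta_effect` from [pool_random_effects()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_effect <- function(object, ...) {
  d <- forest_data(object) |>
    mutate(label = factor(.data$label, levels = rev(.data$label)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$g, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight,
                                     shape = .data$type)) +
    ggplot2::scale_shape_manual(values = c(study = 15, pooled = 18)) +
    ggplot2::guides(size = "none", shape = "none") +
    ggplot2::labs(x = "Standardized mean difference (Hedges' g)", y = NULL,
                  subtitle = sprintf("tau2 = %.3f, I2 = %.1f%%",
                                     object$tau2, object$I2)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential-methylation statistics
#'
#' @param stats Output of [test_dml()].
#' @param min_delta,max_q Thresholds drawn as guides and used to colour
#'   the called DML.
#' @return A ggplot object.
#' @export
plot_volcano <- function(stats, min_delta = 0.20, max_q = 0.05) {
  d <- stats |>
    mutate(called = abs(.data$delta) > min_delta & .data$q < max_q)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta,
                                  y = -log10(pmax(.data$q, 1e-300)),
                                  colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-min_delta, min_delta),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(max_q), linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Methylation difference (tumor - normal)",
                  y = "-log10 q", colour = "DML") +
    ggplot2::theme_minimal()
}

#' Ordination scatter of a principal-coordinates result
#'
#' @param ord Result of [pcoa_ordination()].
#' @param groups Optional vector of group labels, in sample order.
#' @return A ggplot object.
#' @export
plot_ordination <- function(ord, groups = NULL) {
  d <- as_tibble(ord$coordinates, rownames = "sample_id")
  if (!is.null(groups)) d$group <- groups
  ve <- ord$var_explained
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PCo1, y = .data$PCo2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Heatmap of retained taxon-locus associations
#'
#' @param object An `assoc_screen` result.
#' @param ... Unused.
#' @return A ggplot object; an empty plot when nothing was retained.
#' @export
autoplot.assoc_screen <- function(object, ...) {
  d <- retained_associations(object)
  if (nrow(d) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "no retained association") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predictor_id, y = .data$locus_id,
                                  fill = .data$beta_debiased)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "Taxon", y = "CpG locus", fill = "Debiased beta") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
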