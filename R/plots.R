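#' @describeIn overlap_curve Plot the cumulative-overlap curve on the unit
#'   square with the no-enrichment diagonal.
#' @param object A `sigshift_overlap` object.
#' @export
autoplot.sigshift_overlap <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_path(colour = "#2166ac", linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Background genes passed (fraction)",
      y = "Signature genes recovered (fraction)",
      title = object$signature,
      subtitle = sprintf("AUC = %.3f, rank-sum p = %.2g", object$auc, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a signature enrichment ranking
#'
#' Dot plot of signed log10 p per signature (the ranking produced by
#' [rank_signatures()]), optionally restricted to the strongest `top`
#' signatures.
#'
#' @param object A `sigshift_enrichment` table.
#' @param top Number of top signatures to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sigshift_enrichment <- function(object, top = 25, ...) {
  d <- head(tibble::as_tibble(object), top)
  d$signature <- factor(d$signature, levels = rev(d$signature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signed_log10p, y = .data$signature)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2, colour = "#b2182b") +
    ggplot2::labs(x = "Signed log10 p (fold-change bias)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_moderated Volcano plot (log2 fold change against
#'   -log10 raw p) of the included genes.
#' @param object A `sigshift_de` object.
#' @export
autoplot.sigshift_de <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$included %in% TRUE, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = attr(object, "contrast")) +
    ggplot2::theme_minimal()
}

#' @describeIn run_qpcr Bar chart of group mean relative expression with
#'   standard-error bars and LSD letters, faceted by gene (and tissue
#'   when present).
#' @param object A `sigshift_qpcr` object.
#' @export
autoplot.sigshift_qpcr <- function(object, ...) {
  d <- object$summary
  facet <- if ("gene" %in% names(d)) "gene" else NULL
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean_relative)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_relative - .data$se,
                                        ymax = .data$mean_relative + .data$se),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean_relative + .data$se,
                                    label = .data$letter), vjust = -0.6) +
    ggplot2::labs(x = NULL, y = "Relative expression") +
    ggplot2::theme_minimal()
  if (!is.null(facet)) p <- p + ggplot2::facet_wrap(~gene, scales = "free_y")
  p
}
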