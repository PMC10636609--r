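#' Scatter of expression change versus degradation contribution
#'
#' The diagnostic view of a decomposition: each gene is placed by its total
#' expression log2 fold change (x) and the posterior-median fraction of
#' that change attributed to degradation (y), colored by its credible
#' classification. Stability-driven losses of expression sit in the upper
#' left, synthesis-driven gains in the lower right.
#'
#' @param object A [l2fc_decompose()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tl_decomposition <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object),
                      !is.na(.data$fracdeg_median))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$l2fc_n,
                                   y = .data$fracdeg_median,
                                   color = .data$class)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = sprintf("log2 fold change of expression (%s vs %s)",
                  attr(object, "perturbed") %||% "perturbed",
                  attr(object, "reference") %||% "reference"),
      y = "degradation contribution (frac_deg, posterior median)",
      color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Posterior fraction-new intervals per gene
#'
#' @param object A `tl_fit`.
#' @param interval Credible-interval mass.
#' @param max_genes Cap on the number of genes drawn (ordered by posterior
#'   median).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tl_fit <- function(object, interval = 0.8, max_genes = 50, ...) {
  s <- summarize_posterior(object, interval = interval) %>%
    filter(.data$parameter == "theta")
  keep <- s %>%
    group_by(.data$gene_id) %>%
    summarise(m = mean(.data$median)) %>%
    arrange(desc(.data$m)) %>%
    head(max_genes) %>%
    pull(.data$gene_id)
  df <- filter(s, .data$gene_id %in% keep) %>%
    mutate(gene_id = factor(.data$gene_id, levels = rev(keep)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median, y = .data$gene_id,
                                   color = .data$condition)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(0.5),
                             size = 0.2) +
    ggplot2::scale_x_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "fraction new (posterior median, interval)",
                  y = NULL, color = "condition") +
    ggplot2::theme_minimal()
}
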