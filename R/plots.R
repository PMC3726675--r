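#' Forest plot of a fixed-effects meta-analysis
#'
#' Per-study effects with 95% intervals and the pooled estimate.
#'
#' @param object An `fe_meta` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fe_meta <- function(object, ...) {
  d <- tidy(object) %>%
    mutate(lo = .data$beta - 1.96 * .data$se,
           hi = .data$beta + 1.96 * .data$se)
  pooled <- tibble(study = "Pooled (FE)", beta = object$beta,
                   lo = object$beta - 1.96 * object$se,
                   hi = object$beta + 1.96 * object$se)
  d <- bind_rows(select(d, "study", "beta", "lo", "hi"), pooled) %>%
    mutate(study = factor(.data$study, levels = rev(.data$study)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$study)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log-odds effect (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the combined evidence score against rank
#'
#' Score-vs-rank curve of the gene ranking, optionally highlighting a gene
#' set (e.g. the hypothesis genes).
#'
#' @param ranking Tibble with `rank` and `score`, e.g. from [rank_genes()].
#' @param highlight Optional character vector of gene ids to mark.
#' @return A ggplot object.
#' @export
plot_ranking <- function(ranking, highlight = NULL) {
  p <- ggplot2::ggplot(ranking,
                       ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "rank (1 = best)",
                  y = expression(Sigma ~ -log[10] ~ p ~ "over domains")) +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_point(
      data = filter(ranking, .data$gene_id %in% highlight),
      colour = "firebrick", size = 1.2)
  }
  p
}

#' Plot empirical enrichment p-values
#'
#' Dot plot of the plus-one empirical p-values per category and metric,
#' faceted by simulation filter, with the 0.05 reference line.
#'
#' @param object An `enrichment_report` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_report <- function(object, ...) {
  d <- mutate(object,
              filter = ifelse(.data$filter_K == "all", "unfiltered",
                              paste0("top ", .data$filter_K)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$empirical_p,
                                  colour = .data$category)) +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~filter) +
    ggplot2::labs(y = "empirical p (plus-one rule)", x = NULL) +
    ggplot2::theme_minimal()
}
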