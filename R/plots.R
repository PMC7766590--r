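# ggplot2 autoplot methods for the result objects.

#' Volcano plot of a differential expression result
#'
#' @param object A `cindr_de` tibble.
#' @param fdr Highlighting threshold on the q-value.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cindr_de
#' @export
autoplot.cindr_de <- function(object, fdr = 0.01, ...) {
  df <- tidy(object)
  df$status <- dplyr::case_when(
    df$q_value < fdr & df$log2_fold_change > 0 ~ "up",
    df$q_value < fdr & df$log2_fold_change < 0 ~ "down",
    TRUE ~ "ns"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2_fold_change,
    y = -log10(pmax(.data$p_value, 1e-300)),
    colour = .data$status
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d7301f", down = "#0570b0", ns = "grey70")
    ) +
    ggplot2::labs(
      x = "log2 fold change (treated vs control)",
      y = "-log10 p-value", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Tau waterfall plot of a connectivity result
#'
#' Perturbagens ordered by tau, reversal selection highlighted.
#'
#' @param object A `connectivity_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot connectivity_result
#' @export
autoplot.connectivity_result <- function(object, ...) {
  df <- tidy(object)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rank, y = .data$tau, fill = .data$selected
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#0570b0", `FALSE` = "grey70"),
      labels = c(`TRUE` = "selected (reversal)", `FALSE` = "other")
    ) +
    ggplot2::labs(
      x = "perturbagen rank by tau", y = "tau percentile", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of a pharmacovigilance screen
#'
#' Reporting odds ratios with 95% confidence intervals on a log scale,
#' protective signals highlighted.
#'
#' @param object A `ror_screen` tibble.
#' @param max_drugs Show at most this many drugs (smallest upper bounds
#'   first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ror_screen
#' @export
autoplot.ror_screen <- function(object, max_drugs = 30, ...) {
  df <- utils::head(tidy(object), max_drugs)
  df$drug <- factor(df$drug, levels = rev(df$drug))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$ror, y = .data$drug, colour = .data$protective
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#1a9850", `FALSE` = "grey40"),
      labels = c(`TRUE` = "protective (CI < 1)", `FALSE` = "not protective")
    ) +
    ggplot2::labs(x = "reporting odds ratio (95% CI)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dot plot of a gene-set enrichment table
#'
#' @param enrichment Tibble from [enrich_gene_sets()].
#' @param max_sets Show at most this many sets (smallest p first).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, max_sets = 20) {
  df <- utils::head(enrichment, max_sets)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$q_value, 1e-300)), y = .data$set_name,
    size = .data$overlap
  )) +
    ggplot2::geom_point(colour = "#0570b0") +
    ggplot2::labs(x = "-log10 q-value", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}
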