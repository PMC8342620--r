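#' Plot per-state SNP counts
#'
#' Horizontal bar chart of chromatin-state assignments, the usual summary of
#' where a SNP set sits in the 15-state segmentation.
#'
#' @param counts Tibble `state`, `n` from [state_overlap()].
#' @return A ggplot object.
#' @export
plot_state_counts <- function(counts) {
  assert_cols(counts, c("state", "n"))
  ggplot2::ggplot(counts, ggplot2::aes(
    x = .data$n, y = stats::reorder(.data$state, .data$n)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "SNPs", y = NULL, title = "Chromatin-state assignment") +
    ggplot2::theme_minimal()
}

#' Volcano-style view of association results
#'
#' Effect size against -log10 p, significant pairs (at `fdr_threshold` on q)
#' highlighted.
#'
#' @param associations Table from [map_eqtls()].
#' @param fdr_threshold Highlight threshold on `q` (default 0.05).
#' @return A ggplot object.
#' @export
plot_associations <- function(associations, fdr_threshold = 0.05) {
  assert_cols(associations, c("beta", "p", "q"))
  df <- mutate(associations, significant = .data$q < fdr_threshold)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$beta, y = -log10(.data$p), colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey55")) +
    ggplot2::labs(x = "allelic effect (SD)", y = expression(-log[10](p)),
                  colour = sprintf("q < %g", fdr_threshold)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.module_partition <- function(object, ...) {
  sizes <- count(object$membership, .data$module, name = "n")
  ggplot2::ggplot(sizes, ggplot2::aes(x = factor(.data$module), y = .data$n)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = "module", y = "proteins",
                  title = sprintf("Louvain modules (Q = %.3f)", object$modularity)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.tissue_comparison <- function(object, ...) {
  df <- tidy(object) |>
    count(.data$kind, .data$set, name = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$n, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "count", fill = NULL,
                  title = "Shared and tissue-specific eQTLs / eGenes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
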