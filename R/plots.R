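#' Histogram of per-individual allelic or paternal ratios
#'
#' The cohort-level view of skewing: allelic ratios cluster tightly just
#' left of 0.5 (reference bias), while paternal ratios spread widely, with
#' completely skewed individuals at 0 and 1.
#'
#' @param summaries Output of [summarize_individuals()].
#' @param ratio `"paternal"` or `"allelic"`; `"mean"` or `"median"` statistic.
#' @param stat Summary statistic to plot.
#' @param binwidth Histogram bin width.
#' @return A ggplot object.
#' @export
plot_ratio_distribution <- function(summaries,
                                    ratio = c("paternal", "allelic"),
                                    stat = c("mean", "median"),
                                    binwidth = 0.05) {
  ratio <- match.arg(ratio)
  stat <- match.arg(stat)
  col <- paste0(stat, "_", ratio, "_ratio")
  stopifnot(col %in% names(summaries))
  ggplot2::ggplot(summaries, ggplot2::aes(.data[[col]])) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      binwidth = binwidth, boundary = 0, fill = "grey70", colour = "grey30"
    ) +
    ggplot2::geom_density(colour = "black") +
    ggplot2::xlim(-0.025, 1.025) +
    ggplot2::labs(
      x = sprintf("%s %s ratio", stat, ratio),
      y = "density",
      title = sprintf("Distribution of %s %s ratios", stat, ratio)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of mother vs daughter median measure of balance
#'
#' @param pairs Tibble with `mother_balance` and `daughter_balance` columns
#'   (one row per pair), e.g. the `pairs` element of an `xi_result`.
#' @return A ggplot object.
#' @export
plot_mother_daughter <- function(pairs) {
  stopifnot(all(c("mother_balance", "daughter_balance") %in% names(pairs)))
  ggplot2::ggplot(
    pairs,
    ggplot2::aes(.data$mother_balance, .data$daughter_balance)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::coord_fixed(xlim = c(0, 0.5), ylim = c(0, 0.5)) +
    ggplot2::labs(
      x = "mother median measure of balance",
      y = "daughter median measure of balance",
      title = "Mother-daughter X-inactivation balance"
    ) +
    ggplot2::theme_minimal()
}

#' Skew-factor audit plot for one gene
#'
#' Side-by-side chromosome-wide (Sx) and gene (Sg) skew factors per skewed
#' individual: an escapee gene shows consistently smaller gene bars.
#'
#' @param screen An `escape_screen` (for its audit records) or the records
#'   tibble itself.
#' @param gene Gene identifier to plot.
#' @return A ggplot object.
#' @export
plot_gene_skew <- function(screen, gene) {
  recs <- if (inherits(screen, "escape_screen")) {
    attr(screen, "records")
  } else {
    screen
  }
  recs <- recs[recs$gene_id == gene, ]
  if (nrow(recs) == 0) stop("no records for gene ", gene, call. = FALSE)
  long <- tidyr::pivot_longer(
    recs[, c("sample_id", "Sx", "Sg")],
    cols = c("Sx", "Sg"),
    names_to = "scope", values_to = "skew_factor"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(.data$sample_id, .data$skew_factor, fill = .data$scope)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(Sx = "grey20", Sg = "grey70"),
      labels = c(Sx = "chromosome", Sg = gene)
    ) +
    ggplot2::labs(
      x = NULL, y = "skew factor |median ratio - 0.5|",
      title = sprintf("Skew factors: chromosome vs %s", gene)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)
    )
}
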