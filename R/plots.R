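#' Plot the distribution of percent overlap per replicate
#'
#' Mirrors the classic paired-replicate view: one density/histogram per
#' replicate of the percentage of its calls recovered in the other
#' replicate.  The unamplified (WGS) distribution typically sits higher
#' and narrower than the amplified (WGA) one.
#'
#' @param object An `overlap_summary` tibble from [pair_overlap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.overlap_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("sample_id", "pct_overlap_wgs", "pct_overlap_wga")],
    cols = c("pct_overlap_wgs", "pct_overlap_wga"),
    names_to = "replicate", values_to = "pct_overlap")
  long$replicate <- ifelse(long$replicate == "pct_overlap_wgs", "WGS", "WGA")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$pct_overlap, fill = .data$replicate)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.55, bins = 20,
                            na.rm = TRUE) +
    ggplot2::labs(x = "% of replicate's calls found in the other replicate",
                  y = "pairs", fill = "replicate") +
    ggplot2::theme_minimal()
}

#' Plot per-filter effects across a cohort
#'
#' Boxplots, per filter, of either the percent of the replicate overlap
#' removed, the difference-over-overlap removal ratio, or the relative
#' Jaccard change.
#'
#' @param object A `filter_effect` tibble (one row per sample x filter),
#'   e.g. the `effects` element of a `concordance_report`.
#' @param metric One of `"pct_overlap_removed"`,
#'   `"diff_over_overlap_ratio"`, `"pct_jaccard_change"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.filter_effect <- function(object,
                                   metric = c("pct_overlap_removed",
                                              "diff_over_overlap_ratio",
                                              "pct_jaccard_change"),
                                   ...) {
  metric <- match.arg(metric)
  df <- as_tibble(object)
  df <- df[df$filter_name != "combined", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$filter_name,
                                   y = .data[[metric]])) +
    ggplot2::geom_boxplot(na.rm = TRUE) +
    ggplot2::labs(x = "filter", y = metric) +
    ggplot2::theme_minimal()
}

#' Scatter plot of WGS versus WGA call counts
#'
#' One point per patient with the identity line; points below the line
#' have more calls in the amplified replicate.
#'
#' @param overlaps An `overlap_summary` tibble.
#' @return A ggplot object.
#' @export
plot_pair_counts <- function(overlaps) {
  ggplot2::ggplot(as_tibble(overlaps),
                  ggplot2::aes(x = .data$n_wga, y = .data$n_wgs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "putative SNVs (WGA)", y = "putative SNVs (WGS)") +
    ggplot2::theme_minimal()
}

#' Plot LOH/VAQ complementarity against overlap size
#'
#' Percent of the overlap removed by each of the LOH and VAQ filters as a
#' function of the overlap size, with their union coverage.
#'
#' @param comp The `complementarity` tibble of a `concordance_report`.
#' @param overlaps The matching `overlap_summary` tibble.
#' @return A ggplot object.
#' @export
plot_complementarity <- function(comp, overlaps) {
  df <- inner_join(as_tibble(comp),
                   as_tibble(overlaps)[, c("sample_id", "n_overlap")],
                   by = "sample_id")
  long <- tidyr::pivot_longer(
    df, cols = c("pct_overlap_removed_loh", "pct_overlap_removed_vaq",
                 "union_pct"),
    names_to = "measure", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_overlap, y = .data$pct,
                                     colour = .data$measure)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "overlap size (calls in both replicates)",
                  y = "% of overlap removed") +
    ggplot2::theme_minimal()
}
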