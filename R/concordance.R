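#' Overlap statistics for paired technical replicates
#'
#' For each patient the two replicate call sets (labelled WGS and WGA) are
#' compared as sets of SNV keys.  Reported per pair: the two set sizes, the
#' overlap (keys called in both), the percent overlap from each side
#' (`100 * |WGS n WGA| / |WGS|` and `100 * |WGS n WGA| / |WGA|`) and the
#' Jaccard similarity `|WGS n WGA| / |WGS u WGA|`.  A replicate with zero
#' calls makes its percent overlap undefined (`NA`); when both are empty
#' the Jaccard is also `NA`.
#'
#' @param calls An [snv_calls()] tibble holding both replicates for one or
#'   more samples (rows distinguished by `sample_id` and `replicate`).
#' @return A tibble of class `overlap_summary`, one row per sample, with
#'   columns `sample_id`, `n_wgs`, `n_wga`, `n_overlap`,
#'   `pct_overlap_wgs`, `pct_overlap_wga`, `jaccard`.
#' @examples
#' calls <- snv_calls(tibble::tibble(
#'   sample_id = "p1",
#'   replicate = rep(c("WGS", "WGA"), c(2, 3)),
#'   chrom = "chr1", pos = c(1L, 2L, 2L, 3L, 4L), ref = "A", alt = "G"))
#' pair_overlap(calls)
#' @export
pair_overlap <- function(calls) {
  stopifnot(is.data.frame(calls))
  samples <- unique(calls$sample_id)
  rows <- lapply(samples, function(s) {
    wgs <- snv_key(calls[calls$sample_id == s & calls$replicate == "WGS", ])
    wga <- snv_key(calls[calls$sample_id == s & calls$replicate == "WGA", ])
    overlap_row(s, wgs, wga)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(sample_id = character(), n_wgs = integer(),
                  n_wga = integer(), n_overlap = integer(),
                  pct_overlap_wgs = double(), pct_overlap_wga = double(),
                  jaccard = double())
  }
  structure(out, class = unique(c("overlap_summary", class(out))))
}

overlap_row <- function(sample_id, wgs_keys, wga_keys) {
  n_wgs <- length(wgs_keys)
  n_wga <- length(wga_keys)
  o <- length(intersect(wgs_keys, wga_keys))
  u <- n_wgs + n_wga - o
  if (n_wgs == 0 || n_wga == 0) {
    inform(paste0("sample ", sample_id,
                  ": a replicate has zero calls; percent overlap undefined"))
  }
  tibble(sample_id = sample_id, n_wgs = n_wgs, n_wga = n_wga, n_overlap = o,
         pct_overlap_wgs = if (n_wgs > 0) 100 * o / n_wgs else NA_real_,
         pct_overlap_wga = if (n_wga > 0) 100 * o / n_wga else NA_real_,
         jaccard = if (u > 0) o / u else NA_real_)
}

#' Effect of one filter on the overlap and difference of a replicate pair
#'
#' Given the same named filter applied independently to each replicate,
#' measures where its removals fall: in the overlap (keys called in both
#' replicates) or in the symmetric difference (keys called in exactly one).
#' A key in the overlap counts as removed if the filter removed it from
#' *either* replicate — once gone from one kept set it has left the
#' overlap.  A key in the difference counts if removed from the replicate
#' containing it.  The Jaccard is recomputed on the two kept sets, and the
#' relative change `100 * (after - before) / before` reported.
#'
#' Undefined ratios are `NA`, never sentinel numbers: the percent of
#' overlap removed when the overlap is empty, and the
#' difference-over-overlap removal ratio when nothing was removed from the
#' overlap.
#'
#' @param wgs_result,wga_result `snv_filter_result` objects from the same
#'   filter applied to the WGS and WGA call sets of one sample.
#' @param sample_id Sample identifier for the output row (defaults to the
#'   one carried by the WGS calls).
#' @return One-row tibble of class `filter_effect` with columns
#'   `sample_id`, `filter_name`, `n_removed_wgs`, `n_removed_wga`,
#'   `n_removed_overlap`, `n_removed_difference`, `pct_overlap_removed`,
#'   `diff_over_overlap_ratio`, `jaccard_before`, `jaccard_after`,
#'   `pct_jaccard_change`.
#' @export
filter_effect <- function(wgs_result, wga_result, sample_id = NULL) {
  name_wgs <- attr(wgs_result, "filter_name")
  name_wga <- attr(wga_result, "filter_name")
  if (!identical(name_wgs, name_wga)) {
    abort(paste0("filter results disagree on the filter applied: ",
                 name_wgs, " vs ", name_wga))
  }
  sample_id <- sample_id %||% first_non_na(wgs_result$sample_id) %||%
    NA_character_
  wgs <- filter_keys(wgs_result)
  wga <- filter_keys(wga_result)
  effect_from_keys(sample_id, name_wgs,
                   wgs_all = snv_key(wgs_result), wga_all = snv_key(wga_result),
                   wgs_removed = wgs$removed, wga_removed = wga$removed)
}

first_non_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NULL else x[1]
}

effect_from_keys <- function(sample_id, filter_name, wgs_all, wga_all,
                             wgs_removed, wga_removed) {
  overlap <- intersect(wgs_all, wga_all)
  difference <- c(setdiff(wgs_all, wga_all), setdiff(wga_all, wgs_all))
  removed_any <- union(wgs_removed, wga_removed)
  n_removed_overlap <- length(intersect(overlap, removed_any))
  n_removed_difference <- length(intersect(setdiff(wgs_all, wga_all), wgs_removed)) +
    length(intersect(setdiff(wga_all, wgs_all), wga_removed))

  jac <- function(a, b) {
    u <- length(a) + length(b) - length(intersect(a, b))
    if (u > 0) length(intersect(a, b)) / u else NA_real_
  }
  j_before <- jac(wgs_all, wga_all)
  j_after <- jac(setdiff(wgs_all, wgs_removed), setdiff(wga_all, wga_removed))

  out <- tibble(
    sample_id = sample_id, filter_name = filter_name,
    n_removed_wgs = length(wgs_removed), n_removed_wga = length(wga_removed),
    n_removed_overlap = n_removed_overlap,
    n_removed_difference = n_removed_difference,
    pct_overlap_removed = if (length(overlap) > 0) {
      100 * n_removed_overlap / length(overlap)
    } else NA_real_,
    diff_over_overlap_ratio = if (n_removed_overlap > 0) {
      n_removed_difference / n_removed_overlap
    } else NA_real_,
    jaccard_before = j_before, jaccard_after = j_after,
    pct_jaccard_change = if (!is.na(j_before) && j_before > 0 &&
                             !is.na(j_after)) {
      100 * (j_after - j_before) / j_before
    } else NA_real_)
  structure(out, class = unique(c("filter_effect", class(out))))
}

#' Spearman rank correlation with the reporting style of replicate-cohort
#' studies
#'
#' Ranks use average ranks for ties; `rho` is the Pearson correlation of
#' the two rank vectors; `s_stat` is the sum of squared rank differences
#' (the classic S statistic); the two-sided p-value uses the large-sample
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom.
#'
#' @param xs,ys Numeric vectors of equal length, `n >= 3`.
#' @return Object of class `spearman_cor` with fields `rho`, `s_stat`,
#'   `n`, `p_value`; supports [tidy()] and [glance()].
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_cor <- function(xs, ys) {
  if (length(xs) != length(ys)) abort("xs and ys must have equal length")
  ok <- !is.na(xs) & !is.na(ys)
  xs <- xs[ok]; ys <- ys[ok]
  n <- length(xs)
  if (n < 3) abort("need at least 3 complete pairs")
  rx <- rank(xs)
  ry <- rank(ys)
  s_stat <- sum((rx - ry)^2)
  rho <- if (sd(rx) == 0 || sd(ry) == 0) NA_real_ else cor(rx, ry)
  p <- if (is.na(rho) || abs(rho) == 1) {
    if (is.na(rho)) NA_real_ else 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  structure(list(rho = rho, s_stat = s_stat, n = n, p_value = p),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4g, S = %.6g, n = %d, P = %.4g\n",
              x$rho, x$s_stat, x$n, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.spearman_cor <- function(x, ...) {
  tibble(estimate = x$rho, statistic = x$s_stat, p.value = x$p_value,
         method = "Spearman rank correlation (t approximation)")
}

#' @exportS3Method generics::glance
glance.spearman_cor <- function(x, ...) {
  tibble(rho = x$rho, s_stat = x$s_stat, n = x$n, p_value = x$p_value)
}

#' LOH + VAQ complementarity of overlap removal
#'
#' The raw sum of the percent of the overlap removed by the LOH filter and
#' by the VAQ filter.  A sum near 100 with little double-removal means the
#' two filters remove nearly disjoint halves of the overlap.  Note the raw
#' sum cannot detect double-removal (two filters removing the *same* half
#' also sum to 100); [evaluate_filters()] therefore also reports the
#' union-based coverage of the overlap where the underlying key sets are
#' available.
#'
#' @param loh_effect,vaq_effect One-row [filter_effect()] tibbles for the
#'   LOH and VAQ filters on the same sample.
#' @return The sum of the two `pct_overlap_removed` values (`NA` if either
#'   is undefined).
#' @export
complementarity <- function(loh_effect, vaq_effect) {
  if (!identical(loh_effect$sample_id, vaq_effect$sample_id)) {
    abort("complementarity requires effects from the same sample")
  }
  loh_effect$pct_overlap_removed + vaq_effect$pct_overlap_removed
}

#' Cohort-level summary statistics
#'
#' Mean, standard deviation, minimum and maximum across samples for call
#' counts, overlap sizes, percent overlaps and Jaccard, plus the mutation
#' frequency per Mbp for each replicate, and (when filter effects are
#' given) per-filter removal counts per sample and percent of the overlap
#' removed.
#'
#' @param overlaps An [pair_overlap()] result (one row per sample).
#' @param effects Optional combined [filter_effect()] rows (one per sample
#'   x filter).
#' @param genome_size_mbp Denominator for mutation frequency, in megabases
#'   (default 30, exome scale).
#' @return Tibble with columns `metric`, `mean`, `stdev`, `min`, `max`,
#'   `n`.
#' @export
cohort_summary <- function(overlaps, effects = NULL, genome_size_mbp = 30) {
  if (nrow(overlaps) == 0) abort("no pairs analyzed")
  stopifnot(genome_size_mbp > 0)
  stat_row <- function(metric, v) {
    v_ok <- v[!is.na(v)]
    tibble(metric = metric,
           mean = mean(v_ok), stdev = if (length(v_ok) > 1) sd(v_ok) else 0,
           min = min(v_ok), max = max(v_ok), n = length(v_ok))
  }
  rows <- list(
    stat_row("n_wgs", overlaps$n_wgs),
    stat_row("n_wga", overlaps$n_wga),
    stat_row("n_overlap", overlaps$n_overlap),
    stat_row("pct_overlap_wgs", overlaps$pct_overlap_wgs),
    stat_row("pct_overlap_wga", overlaps$pct_overlap_wga),
    stat_row("jaccard", overlaps$jaccard),
    stat_row("mut_per_mbp_wgs", overlaps$n_wgs / genome_size_mbp),
    stat_row("mut_per_mbp_wga", overlaps$n_wga / genome_size_mbp))
  if (!is.null(effects) && nrow(effects) > 0) {
    for (f in unique(effects$filter_name)) {
      e <- effects[effects$filter_name == f, ]
      # removals averaged over replicate samples (each pair contributes two)
      rows <- c(rows, list(
        stat_row(paste0("n_removed[", f, "]"),
                 c(e$n_removed_wgs, e$n_removed_wga)),
        stat_row(paste0("pct_overlap_removed[", f, "]"),
                 e$pct_overlap_removed)))
    }
  }
  bind_rows(rows)
}

#' Rank correlations across a cohort
#'
#' The three correlations typically inspected in replicate-concordance
#' cohorts: WGS vs WGA call counts across samples; call count vs mean
#' coverage; call count vs percent mapped reads (the latter two only when
#' a metadata table is supplied).
#'
#' @param overlaps A [pair_overlap()] result.
#' @param metadata Optional tibble with columns `sample_id`, `replicate`,
#'   `coverage`, `pct_mapped`.
#' @return Tibble with one row per correlation: `comparison`, `rho`,
#'   `s_stat`, `n`, `p_value`.
#' @export
cohort_correlations <- function(overlaps, metadata = NULL) {
  out <- list()
  if (nrow(overlaps) >= 3) {
    sc <- spearman_cor(overlaps$n_wgs, overlaps$n_wga)
    out[[1]] <- tibble(comparison = "n_wgs_vs_n_wga", !!!glance(sc))
    sc2 <- spearman_cor(overlaps$n_wga, overlaps$pct_overlap_wga)
    out[[2]] <- tibble(comparison = "n_wga_vs_pct_overlap_wga", !!!glance(sc2))
  }
  if (!is.null(metadata)) {
    counts <- tidyr::pivot_longer(
      overlaps[, c("sample_id", "n_wgs", "n_wga")],
      cols = c("n_wgs", "n_wga"), names_to = "replicate",
      values_to = "n_calls")
    counts$replicate <- ifelse(counts$replicate == "n_wgs", "WGS", "WGA")
    m <- inner_join(counts, metadata, by = c("sample_id", "replicate"))
    for (cov in intersect(c("coverage", "pct_mapped"), names(m))) {
      if (sum(!is.na(m[[cov]])) >= 3) {
        sc <- spearman_cor(m$n_calls, m[[cov]])
        out[[length(out) + 1L]] <-
          tibble(comparison = paste0("n_calls_vs_", cov), !!!glance(sc))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(comparison = character(), rho = double(),
                  s_stat = double(), n = integer(), p_value = double()))
  }
  bind_rows(out)
}
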