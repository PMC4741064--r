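#' SNV filters
#'
#' Each filter partitions one call set into `removed` and `kept` keys.
#' Filters are pure and independent: every filter judges the *original*
#' unfiltered call set, so applying several filters via [apply_filters()]
#' is order-free and their removals combine by set union.
#'
#' Boundary semantics, used consistently everywhere: score thresholds
#' remove values *strictly below* the threshold (a value exactly at 40 is
#' kept); the proximity window is *inclusive* (distance <= window removes);
#' the alternate-allele fraction filter removes fractions *strictly below*
#' the minimum (exactly 10% is kept).
#'
#' Missing-field policy: with `missing = "keep"` (the default) a call whose
#' required field is absent is kept and counted in `n_missing_field`; with
#' `missing = "error"` it raises an error naming the call and field.
#'
#' @param calls An [snv_calls()] tibble (one call set).
#' @param field Which score the threshold filter reads: `"qual"`, `"ssc"`
#'   or `"vaq"`.
#' @param min_value Threshold; calls with the score strictly below are
#'   removed.
#' @param missing `"keep"` or `"error"` (see above).
#' @param window_bp Inclusive proximity window in base pairs.
#' @param indels An [indel_records()] tibble.
#' @param sites A [site_keys()] tibble.
#' @param mode dbSNP matching: `"position+alt"` removes a call only when the
#'   site's alternate allele is a wildcard or equals the call's;
#'   `"position-only"` matches on `(chrom, pos)` alone.
#' @param min_fraction Minimum alternate-allele fraction in `[0, 1]`.
#' @return An object of class `snv_filter_result`: the input tibble plus
#'   logical columns `removed` and `missing_field`, with the filter's name
#'   attached.  Use [glance()] for one-row counts or [filter_keys()] for
#'   the removed/kept key sets.
#' @name snv_filters
NULL

new_filter_result <- function(calls, removed, missing_field, filter_name) {
  calls$removed <- removed
  calls$missing_field <- missing_field
  structure(calls,
            class = unique(c("snv_filter_result", class(calls))),
            filter_name = filter_name)
}

#' @export
print.snv_filter_result <- function(x, ...) {
  cat("<snv_filter_result> filter:", attr(x, "filter_name"),
      "| removed", sum(x$removed), "of", nrow(x), "calls",
      sprintf("(%d with missing field)\n", sum(x$missing_field)))
  NextMethod()
}

#' @exportS3Method generics::glance
glance.snv_filter_result <- function(x, ...) {
  tibble(filter_name = attr(x, "filter_name"),
         n_input = nrow(x),
         n_removed = sum(x$removed),
         n_kept = sum(!x$removed),
         n_missing_field = sum(x$missing_field))
}

#' @exportS3Method generics::tidy
tidy.snv_filter_result <- function(x, ...) {
  tibble(filter_name = attr(x, "filter_name"),
         key = snv_key(x), removed = x$removed,
         missing_field = x$missing_field)
}

#' Removed and kept key sets of a filter result
#'
#' @param result An `snv_filter_result`.
#' @return List with character vectors `removed` and `kept`.
#' @export
filter_keys <- function(result) {
  keys <- snv_key(result)
  list(removed = keys[result$removed], kept = keys[!result$removed])
}

missing_or_error <- function(calls, is_missing, field, missing) {
  if (missing == "error" && any(is_missing)) {
    i <- which(is_missing)[1]
    abort(paste0("call ", snv_key(calls)[i], " has missing field ", field))
  }
  is_missing
}

#' @rdname snv_filters
#' @export
threshold_filter <- function(calls, field = c("qual", "ssc", "vaq"),
                             min_value = 40, missing = c("keep", "error")) {
  field <- match.arg(field)
  missing <- match.arg(missing)
  stopifnot(min_value >= 0)
  v <- calls[[field]]
  is_missing <- missing_or_error(calls, is.na(v), field, missing)
  removed <- !is_missing & v < min_value
  name <- c(qual = "GATK", ssc = "SS", vaq = "VAQ")[[field]]
  new_filter_result(calls, removed, is_missing, name)
}

#' @rdname snv_filters
#' @export
loh_filter <- function(calls, missing = c("keep", "error")) {
  missing <- match.arg(missing)
  is_missing <- missing_or_error(calls, is.na(calls$status), "status", missing)
  removed <- !is_missing & calls$status == "LOH"
  new_filter_result(calls, removed, is_missing, "LOH")
}

#' @rdname snv_filters
#' @export
snv_proximity_filter <- function(calls, window_bp = 10) {
  stopifnot(window_bp >= 0)
  removed <- rep(FALSE, nrow(calls))
  if (nrow(calls) >= 2) {
    gr <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos, width = 1))
    # findOverlaps gap semantics differ from position distance by one;
    # take a superset of candidate pairs, then apply |pos1 - pos2| <= window
    hits <- GenomicRanges::findOverlaps(gr, maxgap = window_bp,
                                        drop.self = TRUE,
                                        drop.redundant = FALSE)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    close <- abs(calls$pos[q] - calls$pos[s]) <= window_bp
    removed[unique(q[close])] <- TRUE
  }
  new_filter_result(calls, removed, rep(FALSE, nrow(calls)), "10bp-SNV")
}

#' @rdname snv_filters
#' @export
indel_proximity_filter <- function(calls, indels, window_bp = 10) {
  stopifnot(window_bp >= 0)
  removed <- rep(FALSE, nrow(calls))
  if (nrow(calls) > 0 && nrow(indels) > 0) {
    gr <- GenomicRanges::GRanges(calls$chrom,
                                 IRanges::IRanges(calls$pos, width = 1))
    gi <- GenomicRanges::GRanges(indels$chrom,
                                 IRanges::IRanges(indels$start, indels$end))
    # disjoint chromosome sets between calls and indels are legitimate input
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, gi, maxgap = window_bp))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    gap <- indel_gap_distance(calls$pos[q], indels$start[s], indels$end[s])
    removed[unique(q[gap <= window_bp])] <- TRUE
  }
  new_filter_result(calls, removed, rep(FALSE, nrow(calls)), "10bp-INDEL")
}

# 0 inside the span, otherwise distance to the nearest affected base
indel_gap_distance <- function(pos, start, end) {
  ifelse(pos >= start & pos <= end, 0L,
         pmin(abs(pos - start), abs(pos - end)))
}

#' @rdname snv_filters
#' @export
dbsnp_filter <- function(calls, sites,
                         mode = c("position+alt", "position-only")) {
  mode <- match.arg(mode)
  removed <- rep(FALSE, nrow(calls))
  if (nrow(calls) > 0 && nrow(sites) > 0) {
    pos_key <- paste(calls$chrom, calls$pos, sep = "\r")
    site_pos <- paste(sites$chrom, sites$pos, sep = "\r")
    if (mode == "position-only") {
      removed <- pos_key %in% site_pos
    } else {
      wildcard <- pos_key %in% site_pos[is.na(sites$alt)]
      allele_key <- paste(pos_key, calls$alt, sep = "\r")
      site_allele <- paste(site_pos[!is.na(sites$alt)],
                           sites$alt[!is.na(sites$alt)], sep = "\r")
      removed <- wildcard | allele_key %in% site_allele
    }
  }
  new_filter_result(calls, removed, rep(FALSE, nrow(calls)), "dbSNP")
}

#' @rdname snv_filters
#' @export
alt_fraction_filter <- function(calls, min_fraction = 0.10) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  no_depth <- is.na(calls$depth_total) | is.na(calls$depth_alt) |
    calls$depth_total == 0L
  frac <- ifelse(no_depth, NA_real_, calls$depth_alt / calls$depth_total)
  removed <- !no_depth & frac < min_fraction
  if (any(no_depth)) {
    inform(paste0(sum(no_depth),
                  " call(s) without usable depth kept by the lt10pct filter"))
  }
  new_filter_result(calls, removed, no_depth, "lt10pct")
}

#' Apply a set of filters independently to one call set
#'
#' Every enabled filter sees the full, unfiltered input (single-pass
#' semantics); the combined removal is the union of the per-filter removed
#' key sets.  Because each filter is evaluated on the original set, the
#' result is invariant to the order of `enabled_filters`.
#'
#' @param calls An [snv_calls()] tibble (one call set).
#' @param config A [filter_config()].
#' @param sites Optional [site_keys()] tibble for the dbSNP filter (empty
#'   set if omitted).
#' @param indels Optional [indel_records()] tibble for the 10bp-INDEL
#'   filter.
#' @return List of class `snv_filter_set` with elements `results` (named
#'   list of `snv_filter_result`, one per enabled filter),
#'   `combined_removed` (character vector of keys removed by at least one
#'   filter) and `n_input`.
#' @export
apply_filters <- function(calls, config = filter_config(), sites = NULL,
                          indels = NULL) {
  stopifnot(inherits(config, "filter_config"))
  if (length(config$enabled_filters) == 0) abort("no filters enabled")
  unknown <- setdiff(config$enabled_filters, FILTER_NAMES)
  if (length(unknown) > 0) {
    abort(paste0("unknown filter name(s): ", paste(unknown, collapse = ", ")))
  }
  sites <- sites %||% site_keys(tibble(chrom = character(), pos = integer()))
  indels <- indels %||% indel_records(tibble(chrom = character(),
                                             start = integer(),
                                             end = integer()))
  run_one <- function(name) {
    switch(name,
      "GATK" = threshold_filter(calls, "qual", config$min_qual, config$missing),
      "SS" = threshold_filter(calls, "ssc", config$min_ssc, config$missing),
      "VAQ" = threshold_filter(calls, "vaq", config$min_vaq, config$missing),
      "LOH" = loh_filter(calls, config$missing),
      "10bp-SNV" = snv_proximity_filter(calls, config$proximity_window_bp),
      "10bp-INDEL" = indel_proximity_filter(calls, indels,
                                            config$proximity_window_bp),
      "dbSNP" = dbsnp_filter(calls, sites, config$dbsnp_match_mode),
      "lt10pct" = alt_fraction_filter(calls, config$min_alt_fraction))
  }
  results <- lapply(config$enabled_filters, run_one)
  names(results) <- config$enabled_filters
  combined <- unique(unlist(lapply(results, function(r) filter_keys(r)$removed),
                            use.names = FALSE))
  structure(list(results = results,
                 combined_removed = combined %||% character(),
                 n_input = nrow(calls)),
            class = "snv_filter_set")
}

#' @export
print.snv_filter_set <- function(x, ...) {
  cat("<snv_filter_set>", length(x$results), "filters on", x$n_input,
      "calls;", length(x$combined_removed), "keys removed by >= 1 filter\n")
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.snv_filter_set <- function(x, ...) {
  bind_rows(lapply(x$results, glance))
}
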