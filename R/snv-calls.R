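#' Construct and validate a table of somatic SNV calls
#'
#' A call table is an ordinary tibble with one row per putative somatic SNV.
#' The identity of a call (its *key*) is the quadruple
#' `(chrom, pos, ref, alt)`: two calls are the same mutation if and only if
#' all four agree.  Keys must be unique within one `(sample_id, replicate)`
#' call set.  Chromosome names are compared as exact strings; no "chr"
#' prefix normalization happens here (see [vcf_dialect()] for an explicit
#' switch at parse time).
#'
#' Numeric quality fields (`qual`, `ssc`, `vaq`) and depths may be `NA`;
#' missingness is explicit and never encoded as 0.  Filters decide how
#' missing values are treated; the model layer never imputes.
#'
#' @param x A data frame with columns `chrom` (character), `pos` (integer,
#'   1-based), `ref`, `alt` (single bases A/C/G/T), and optionally
#'   `sample_id`, `replicate` ("WGS"/"WGA"), `qual`, `ssc`, `vaq`
#'   (non-negative scores), `status` (one of SOMATIC/GERMLINE/LOH/UNKNOWN),
#'   `depth_total`, `depth_alt`.  Missing optional columns are added as `NA`.
#' @return A validated tibble of class `snv_calls`.
#' @examples
#' snv_calls(data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G"))
#' @export
snv_calls <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as_tibble(x)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("call table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  optional <- list(sample_id = NA_character_, replicate = NA_character_,
                   qual = NA_real_, ssc = NA_real_, vaq = NA_real_,
                   status = NA_character_,
                   depth_total = NA_integer_, depth_alt = NA_integer_)
  for (nm in names(optional)) {
    if (!nm %in% names(x)) x[[nm]] <- optional[[nm]]
  }
  x <- x[, c("sample_id", "replicate", required,
             setdiff(names(optional), c("sample_id", "replicate")))]
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$depth_total <- as.integer(x$depth_total)
  x$depth_alt <- as.integer(x$depth_alt)

  validate_snv_calls(x)
  class(x) <- unique(c("snv_calls", class(x)))
  x
}

validate_snv_calls <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$pos < 1, na.rm = TRUE)) abort("pos must be >= 1")
  bases <- c("A", "C", "G", "T")
  if (!all(x$ref %in% bases)) abort("ref must be a single base A/C/G/T")
  if (!all(x$alt %in% bases)) abort("alt must be a single base A/C/G/T")
  if (any(x$ref == x$alt)) abort("ref and alt must differ")
  bad_status <- !is.na(x$status) & !x$status %in% STATUS_LEVELS
  if (any(bad_status)) {
    abort(paste0("unknown somatic status: ",
                 paste(unique(x$status[bad_status]), collapse = ", ")))
  }
  for (f in c("qual", "ssc", "vaq")) {
    if (any(x[[f]] < 0, na.rm = TRUE)) abort(paste0(f, " must be non-negative"))
  }
  if (any(x$depth_alt > x$depth_total, na.rm = TRUE)) {
    abort("depth_alt must not exceed depth_total")
  }
  bad_rep <- !is.na(x$replicate) & !x$replicate %in% c("WGS", "WGA")
  if (any(bad_rep)) abort("replicate must be \"WGS\" or \"WGA\"")
  assert_unique_keys(x)
  invisible(x)
}

# Duplicate keys within one (sample, replicate) call set are a data error:
# the same mutation listed twice would double-count in every set statistic.
assert_unique_keys <- function(x) {
  grp <- paste(x$sample_id, x$replicate, sep = "\r")
  key <- paste(grp, snv_key(x), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    abort(paste0("duplicate SNV key within one call set: ",
                 snv_key(x)[dup][1]))
  }
  invisible(x)
}

#' SNV key strings
#'
#' Collapses the identity fields of each call into a single
#' `chrom:pos:ref:alt` string, the unit of comparison for all overlap and
#' filter statistics.
#'
#' @param x A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of keys, one per row.
#' @export
snv_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Set of keys identified by a call collection
#'
#' @param calls A call table (see [snv_calls()]).  Keys must be unique;
#'   a duplicated key raises an error naming it.
#' @return Character vector of unique `chrom:pos:ref:alt` keys, one per call.
#' @export
snv_key_set <- function(calls) {
  keys <- snv_key(calls)
  dup <- duplicated(keys)
  if (any(dup)) {
    abort(paste0("duplicate SNV key in input: ", keys[dup][1]))
  }
  keys
}

#' Construct a table of indel records
#'
#' An indel occupies a closed 1-based span `[start, end]` of reference
#' bases; for a VCF record with reference allele of length L at position p
#' the span is `[p, p + L - 1]`.
#'
#' @param x Data frame with columns `chrom`, `start`, `end`.
#' @return Tibble with validated spans.
#' @export
indel_records <- function(x) {
  x <- as_tibble(x)[, c("chrom", "start", "end")]
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  if (any(x$start < 1)) abort("indel start must be >= 1")
  if (any(x$end < x$start)) abort("indel end must be >= start")
  x
}

#' Construct a table of site keys (dbSNP-style site lists)
#'
#' A site is `(chrom, pos, alt)`; `alt = NA` is the wildcard marker meaning
#' "any alternate allele at this position" (as produced by BED input, which
#' carries no allele information).
#'
#' @param x Data frame with columns `chrom`, `pos` and optionally `alt`.
#' @return De-duplicated tibble of sites.
#' @export
site_keys <- function(x) {
  x <- as_tibble(x)
  if (!"alt" %in% names(x)) x$alt <- NA_character_
  x <- x[, c("chrom", "pos", "alt")]
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$alt <- as.character(x$alt)
  if (nrow(x) > 0 && any(x$pos < 1)) abort("site pos must be >= 1")
  distinct(x)
}

#' Filter configuration
#'
#' Thresholds and switches for the eight SNV filters.  Defaults follow
#' common somatic-calling practice: quality-score thresholds at 40
#' (values strictly below are removed), a 10 bp proximity window
#' (inclusive: distance <= window removes), and a 10% minimum
#' alternate-allele fraction (strictly below removes).
#'
#' @param min_qual,min_ssc,min_vaq Thresholds for the GATK-quality,
#'   SomaticScore and Variant Allele Quality filters.
#' @param proximity_window_bp Window (bp) used by both proximity filters.
#' @param min_alt_fraction Minimum alternate-allele fraction, in `[0, 1]`.
#' @param dbsnp_match_mode `"position+alt"` (default) or `"position-only"`.
#' @param enabled_filters Character vector of filter names to apply, from
#'   `GATK, SS, VAQ, LOH, 10bp-SNV, 10bp-INDEL, dbSNP, lt10pct`.
#' @param missing `"keep"` (lenient; calls with a missing required field are
#'   kept and counted) or `"error"` (strict).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_qual = 40, min_ssc = 40, min_vaq = 40,
                          proximity_window_bp = 10, min_alt_fraction = 0.10,
                          dbsnp_match_mode = c("position+alt", "position-only"),
                          enabled_filters = FILTER_NAMES,
                          missing = c("keep", "error")) {
  dbsnp_match_mode <- match.arg(dbsnp_match_mode)
  missing <- match.arg(missing)
  stopifnot(min_qual >= 0, min_ssc >= 0, min_vaq >= 0,
            proximity_window_bp >= 0,
            min_alt_fraction >= 0, min_alt_fraction <= 1)
  unknown <- setdiff(enabled_filters, FILTER_NAMES)
  if (length(unknown) > 0) {
    abort(paste0("unknown filter name(s): ", paste(unknown, collapse = ", "),
                 "; known filters: ", paste(FILTER_NAMES, collapse = ", ")))
  }
  structure(list(min_qual = min_qual, min_ssc = min_ssc, min_vaq = min_vaq,
                 proximity_window_bp = proximity_window_bp,
                 min_alt_fraction = min_alt_fraction,
                 dbsnp_match_mode = dbsnp_match_mode,
                 enabled_filters = enabled_filters,
                 missing = missing),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat("  thresholds: qual >=", x$min_qual, " ssc >=", x$min_ssc,
      " vaq >=", x$min_vaq, "\n")
  cat("  proximity window:", x$proximity_window_bp, "bp (inclusive)\n")
  cat("  min alt fraction:", x$min_alt_fraction, "\n")
  cat("  dbSNP matching:", x$dbsnp_match_mode, "\n")
  cat("  enabled:", paste(x$enabled_filters, collapse = ", "), "\n")
  invisible(x)
}
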