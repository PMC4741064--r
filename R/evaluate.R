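#' Run the full concordance analysis on in-memory call sets
#'
#' For every sample: computes the pair overlap; applies each enabled
#' filter independently to each replicate and derives its [filter_effect()]
#' row; adds a `combined` pseudo-filter whose removal set is the union of
#' all enabled filters (the "run everything" analysis); and, when both the
#' LOH and VAQ filters are enabled, a complementarity table carrying the
#' raw sum of their percent-overlap removals and the union-based coverage
#' `100 * |(removed_LOH u removed_VAQ) n overlap| / |overlap|` (the raw
#' sum cannot see double-removal; the union coverage can).
#'
#' @param calls An [snv_calls()] tibble with both replicates for one or
#'   more samples.
#' @param config A [filter_config()].
#' @param sites Optional [site_keys()] tibble (dbSNP filter input).
#' @param indels Optional [indel_records()] tibble (10bp-INDEL input).
#' @return A list of class `concordance_report` with tibbles `overlap`,
#'   `effects`, `complementarity`, `correlations`, and the `config`.
#' @export
concordance_analysis <- function(calls, config = filter_config(),
                                 sites = NULL, indels = NULL) {
  stopifnot(is.data.frame(calls))
  if (nrow(calls) == 0) abort("no pairs analyzed")
  overlap <- pair_overlap(calls)
  samples <- overlap$sample_id

  effects <- list()
  comp <- list()
  for (s in samples) {
    wgs <- calls[calls$sample_id == s & calls$replicate == "WGS", ]
    wga <- calls[calls$sample_id == s & calls$replicate == "WGA", ]
    fs_wgs <- apply_filters(wgs, config, sites, indels)
    fs_wga <- apply_filters(wga, config, sites, indels)
    for (f in config$enabled_filters) {
      effects[[length(effects) + 1L]] <-
        filter_effect(fs_wgs$results[[f]], fs_wga$results[[f]], sample_id = s)
    }
    effects[[length(effects) + 1L]] <- effect_from_keys(
      s, "combined",
      wgs_all = snv_key(wgs), wga_all = snv_key(wga),
      wgs_removed = fs_wgs$combined_removed,
      wga_removed = fs_wga$combined_removed)

    if (all(c("LOH", "VAQ") %in% config$enabled_filters)) {
      comp[[length(comp) + 1L]] <-
        complementarity_row(s, wgs, wga, fs_wgs, fs_wga)
    }
  }
  effects <- bind_rows(effects)
  effects <- structure(effects,
                       class = unique(c("filter_effect", class(effects))))
  comp <- if (length(comp) > 0) bind_rows(comp) else NULL
  structure(list(overlap = overlap, effects = effects,
                 complementarity = comp,
                 correlations = cohort_correlations(overlap),
                 config = config),
            class = "concordance_report")
}

complementarity_row <- function(sample_id, wgs, wga, fs_wgs, fs_wga) {
  overlap_keys <- intersect(snv_key(wgs), snv_key(wga))
  removed_in_overlap <- function(f) {
    intersect(overlap_keys,
              union(filter_keys(fs_wgs$results[[f]])$removed,
                    filter_keys(fs_wga$results[[f]])$removed))
  }
  loh <- removed_in_overlap("LOH")
  vaq <- removed_in_overlap("VAQ")
  n_o <- length(overlap_keys)
  tibble(sample_id = sample_id,
         pct_overlap_removed_loh = if (n_o > 0) 100 * length(loh) / n_o else NA_real_,
         pct_overlap_removed_vaq = if (n_o > 0) 100 * length(vaq) / n_o else NA_real_,
         sum_pct = if (n_o > 0) 100 * (length(loh) + length(vaq)) / n_o else NA_real_,
         union_pct = if (n_o > 0) 100 * length(union(loh, vaq)) / n_o else NA_real_)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>", nrow(x$overlap), "pairs,",
      length(unique(x$effects$filter_name)), "filters\n\n")
  print(as_tibble(x$overlap))
  invisible(x)
}

#' Evaluate filters across a cohort of paired VCFs
#'
#' Reads every pair named in the manifest, runs [concordance_analysis()]
#' and optionally writes the tidy report tables.  Any unreadable input is
#' an error naming the failing pair, unless `continue_on_error = TRUE`, in
#' which case the pair is skipped with a warning.
#'
#' @param manifest A pairs manifest: either a tibble with columns
#'   `sample_id`, `wgs_vcf`, `wga_vcf`, or a path to such a TSV (relative
#'   VCF paths resolved against its directory).
#' @param config A [filter_config()].
#' @param dbsnp Optional path to a dbSNP site list (VCF/BED) or a
#'   [site_keys()] tibble.
#' @param indels Optional path to an indel list (BED/VCF) or an
#'   [indel_records()] tibble.  Indels parsed out of each replicate's own
#'   VCF are always included for that replicate's 10bp-INDEL filter.
#' @param dialect A [vcf_dialect()].
#' @param out_dir When given, report tables and a JSON run manifest are
#'   written there via [write_report_tables()].
#' @param genome_size_mbp Passed to [cohort_summary()].
#' @param continue_on_error Skip unreadable pairs instead of failing.
#' @return A `concordance_report` (invisibly when `out_dir` is given).
#' @export
evaluate_filters <- function(manifest, config = filter_config(),
                             dbsnp = NULL, indels = NULL,
                             dialect = vcf_dialect(), out_dir = NULL,
                             genome_size_mbp = 30,
                             continue_on_error = FALSE) {
  if (is.character(manifest)) manifest <- read_pairs_manifest(manifest)
  if (nrow(manifest) == 0) abort("no pairs analyzed")
  sites <- if (is.character(dbsnp)) read_site_list(dbsnp) else dbsnp
  extra_indels <- if (is.character(indels)) read_indel_list(indels) else indels

  all_calls <- list()
  all_indels <- list(extra_indels)
  for (i in seq_len(nrow(manifest))) {
    s <- manifest$sample_id[i]
    parsed <- tryCatch({
      wgs <- read_somatic_vcf(manifest$wgs_vcf[i], dialect, s, "WGS")
      wga <- read_somatic_vcf(manifest$wga_vcf[i], dialect, s, "WGA")
      list(wgs = wgs, wga = wga)
    }, error = function(e) {
      msg <- paste0("pair ", s, ": ", conditionMessage(e))
      if (continue_on_error) {
        warn(msg)
        NULL
      } else {
        abort(msg)
      }
    })
    if (is.null(parsed)) next
    all_calls[[length(all_calls) + 1L]] <- parsed$wgs$calls
    all_calls[[length(all_calls) + 1L]] <- parsed$wga$calls
    all_indels <- c(all_indels, list(parsed$wgs$indels, parsed$wga$indels))
  }
  if (length(all_calls) == 0) abort("no pairs analyzed")
  calls <- bind_rows(all_calls)
  indel_tbl <- distinct(bind_rows(all_indels))

  report <- concordance_analysis(snv_calls(calls), config,
                                 sites = sites, indels = indel_tbl)
  if (!is.null(out_dir)) {
    write_report_tables(report, out_dir, genome_size_mbp = genome_size_mbp)
    return(invisible(report))
  }
  report
}

#' Write the tidy report tables of a concordance analysis
#'
#' Emits three tab-separated tables with stable column order and fixed
#' 6-significant-digit float formatting (so re-runs on identical input are
#' byte-identical): `overlap_summary.tsv` (one row per pair),
#' `filter_effects.tsv` (one row per pair x filter, including the
#' `combined` pseudo-filter), and `cohort_summary.tsv` (mean/stdev/min/max
#' per metric).  When available, `complementarity.tsv` and
#' `correlations.tsv` are written too, plus a JSON run manifest.
#'
#' @param report A `concordance_report` from [concordance_analysis()] or
#'   [evaluate_filters()].
#' @param out_dir Output directory (created if needed).
#' @param genome_size_mbp Passed to [cohort_summary()].
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(report, out_dir, genome_size_mbp = 30) {
  stopifnot(inherits(report, "concordance_report"))
  if (nrow(report$overlap) == 0) abort("no pairs analyzed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  per_filter <- report$effects[report$effects$filter_name != "combined", ]
  summary_tbl <- cohort_summary(report$overlap, per_filter,
                                genome_size_mbp = genome_size_mbp)
  paths <- c(
    write_fixed_tsv(report$overlap, file.path(out_dir, "overlap_summary.tsv")),
    write_fixed_tsv(report$effects, file.path(out_dir, "filter_effects.tsv")),
    write_fixed_tsv(summary_tbl, file.path(out_dir, "cohort_summary.tsv")))
  if (!is.null(report$complementarity)) {
    paths <- c(paths, write_fixed_tsv(
      report$complementarity, file.path(out_dir, "complementarity.tsv")))
  }
  if (nrow(report$correlations) > 0) {
    paths <- c(paths, write_fixed_tsv(
      report$correlations, file.path(out_dir, "correlations.tsv")))
  }
  run_manifest <- list(
    tool = "snvconcord::write_report_tables",
    config = unclass(report$config),
    genome_size_mbp = genome_size_mbp,
    n_pairs = nrow(report$overlap),
    files = lapply(setNames(basename(paths), basename(paths)), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }))
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, file.path(out_dir, "run_manifest.json")))
}

# TSV with doubles rendered at 6 significant digits; byte-stable across runs
write_fixed_tsv <- function(x, path) {
  x <- as_tibble(x)
  for (nm in names(x)) {
    if (is.double(x[[nm]])) {
      x[[nm]] <- ifelse(is.na(x[[nm]]), "NA", sprintf("%.6g", x[[nm]]))
    }
  }
  readr::write_tsv(x, path, progress = FALSE)
  path
}
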