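#' Parameters of the paired-replicate simulator
#'
#' The generator emulates the statistical structure of paired
#' technical-replicate somatic call sets: a patient carries a set of true
#' fixed mutations, each detected independently in each replicate with
#' probability `detect_prob`; on top of those, each replicate accrues its
#' own false calls, with the amplified (WGA) replicate receiving more than
#' the unamplified (WGS) one; per-patient mutation burden varies over
#' orders of magnitude (log-uniform); a fraction of calls carries LOH
#' status irrespective of truth; and error calls are planted on dbSNP
#' sites, near indels, or clustered near other errors so that the
#' corresponding filters have signal to find.  Quality scores for true
#' calls are drawn from a higher-mean distribution than for false calls,
#' with overlap; depths are Poisson with beta-distributed alternate-allele
#' fractions centered near 0.45 (true) and 0.15 (false).
#'
#' @param n_patients Cohort size.
#' @param n_true_range Two-element range; the per-patient count of true
#'   fixed mutations is drawn log-uniformly over it.
#' @param detect_prob Probability that a true mutation is called in one
#'   replicate (independent across replicates).
#' @param n_err_wgs,n_err_wga Expected replicate-specific false calls per
#'   patient (Poisson means); the WGA default is higher, modelling
#'   amplification error.
#' @param frac_loh Fraction of calls assigned LOH status, truth-blind.
#' @param frac_dbsnp_artifact Fraction of false calls placed on dbSNP
#'   sites.
#' @param frac_clustered Fraction of false calls planted within the
#'   proximity window of an indel or of another false call (split evenly
#'   between the two placements).
#' @param qual_true_mean,qual_true_sd,qual_false_mean,qual_false_sd
#'   Normal parameters for the quality-score model (applied to qual, ssc
#'   and vaq independently; draws are floored at 0).
#' @param mean_coverage Poisson mean of the per-site total depth.
#' @param alt_shape_true,alt_shape_false Beta shape pairs for the
#'   alternate-allele fraction of true and false calls.
#' @param n_chroms,chrom_length_bp Synthetic genome model.
#' @param n_dbsnp_sites,n_indels Size of the generated dbSNP site list and
#'   indel list.
#' @param proximity_window_bp Window used when planting clustered and
#'   near-indel errors.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_patients = 10,
                       n_true_range = c(100, 5000),
                       detect_prob = 0.66,
                       n_err_wgs = 400, n_err_wga = 1100,
                       frac_loh = 0.35,
                       frac_dbsnp_artifact = 0.05,
                       frac_clustered = 0.08,
                       qual_true_mean = 120, qual_true_sd = 25,
                       qual_false_mean = 45, qual_false_sd = 20,
                       mean_coverage = 30,
                       alt_shape_true = c(9, 11),
                       alt_shape_false = c(3, 17),
                       n_chroms = 3, chrom_length_bp = 1e7,
                       n_dbsnp_sites = 5000, n_indels = 100,
                       proximity_window_bp = 10,
                       seed = 1L) {
  stopifnot(n_patients >= 1,
            length(n_true_range) == 2, all(n_true_range > 0),
            n_true_range[2] >= n_true_range[1],
            detect_prob >= 0, detect_prob <= 1,
            n_err_wgs >= 0, n_err_wga >= 0,
            frac_loh >= 0, frac_loh <= 1,
            frac_dbsnp_artifact >= 0, frac_dbsnp_artifact <= 1,
            frac_clustered >= 0, frac_clustered <= 1,
            frac_dbsnp_artifact + frac_clustered <= 1,
            mean_coverage > 0, n_chroms >= 1, chrom_length_bp >= 1000,
            n_dbsnp_sites >= 0, n_indels >= 0, proximity_window_bp >= 0)
  p <- as.list(environment())
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat("  patients:", x$n_patients,
      "| true mutations: log-uniform", x$n_true_range[1], "-",
      x$n_true_range[2], "\n")
  cat("  detect_prob:", x$detect_prob,
      "| false calls (Poisson mean): WGS", x$n_err_wgs, ", WGA",
      x$n_err_wga, "\n")
  cat("  frac_loh:", x$frac_loh, "| dbSNP artifacts:", x$frac_dbsnp_artifact,
      "| clustered/near-indel:", x$frac_clustered, "\n")
  cat("  genome:", x$n_chroms, "x", format(x$chrom_length_bp, scientific = FALSE),
      "bp | seed:", x$seed, "\n")
  invisible(x)
}

BASES <- c("A", "C", "G", "T")

sim_chrom_names <- function(params) paste0("chr", seq_len(params$n_chroms))

# uniform draw of n (chrom, pos) genome positions
sample_genome_positions <- function(n, params) {
  tibble(chrom = sample(sim_chrom_names(params), n, replace = TRUE),
         pos = sample.int(as.integer(params$chrom_length_bp), n,
                          replace = TRUE))
}

random_alleles <- function(n) {
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  tibble(ref = ref, alt = unname(alt))
}

#' Generate a shared dbSNP site list and indel list
#'
#' @param params A [sim_params()].
#' @return List with `sites` (a [site_keys()] tibble with explicit
#'   alternate alleles) and `indels` (an [indel_records()] tibble of spans
#'   of 1-3 bp).
#' @keywords internal
simulate_site_lists <- function(params) {
  sp <- sample_genome_positions(params$n_dbsnp_sites, params)
  sites <- site_keys(tibble(chrom = sp$chrom, pos = sp$pos,
                            alt = sample(BASES, nrow(sp), replace = TRUE)))
  ip <- sample_genome_positions(params$n_indels, params)
  len <- sample.int(3L, nrow(ip), replace = TRUE)
  indels <- indel_records(tibble(chrom = ip$chrom, start = ip$pos,
                                 end = pmin(ip$pos + len - 1L,
                                            as.integer(params$chrom_length_bp))))
  list(sites = sites, indels = indels)
}

#' Simulate one patient's paired replicate call sets with ground truth
#'
#' True mutations are sampled once per patient at distinct genome
#' positions, then detected in each replicate independently with
#' probability `detect_prob`.  False calls are drawn per replicate with
#' Poisson counts (`n_err_wgs` / `n_err_wga` means) and placed uniformly,
#' except for the planted fractions: `frac_dbsnp_artifact` on dbSNP sites,
#' and `frac_clustered` split between positions near an indel and
#' positions near another false call.  Every emitted call gets one truth
#' row (`TRUE_FIXED` or `ERROR` with an error class).
#'
#' @param params A [sim_params()].
#' @param sample_id Patient identifier.
#' @param seed Integer seed for this patient's stream.
#' @param sites,indels Optional shared site/indel lists (generated from
#'   this patient's stream when omitted).
#' @return List with `calls` (both replicates, an [snv_calls()] tibble),
#'   `truth` (per-call truth table), `sites`, `indels`.
#' @export
simulate_pair <- function(params, sample_id = "patient1",
                          seed = params$seed, sites = NULL, indels = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(as.integer(seed))
  if (is.null(sites) || is.null(indels)) {
    sl <- simulate_site_lists(params)
    sites <- sites %||% sl$sites
    indels <- indels %||% sl$indels
  }

  genome_bp <- params$n_chroms * params$chrom_length_bp
  lo <- log(params$n_true_range[1]); hi <- log(params$n_true_range[2])
  n_true <- as.integer(round(exp(runif(1, lo, hi))))
  if (n_true > genome_bp / 100) {
    abort("n_true_range exceeds the synthetic genome's capacity")
  }

  true_pos <- distinct(sample_genome_positions(n_true, params),
                       .data$chrom, .data$pos)
  true_calls <- dplyr::bind_cols(true_pos, random_alleles(nrow(true_pos)))

  one_replicate <- function(replicate, n_err_mean) {
    detected <- runif(nrow(true_calls)) < params$detect_prob
    truths <- true_calls[detected, ]
    truths$truth <- "TRUE_FIXED"
    truths$error_class <- NA_character_

    n_err <- rpois(1, n_err_mean)
    errs <- simulate_error_calls(n_err, params, sites, indels)
    both <- bind_rows(truths, errs)
    both <- both[!duplicated(paste(both$chrom, both$pos, both$ref, both$alt)), ]
    n <- nrow(both)
    is_true <- both$truth == "TRUE_FIXED"

    score <- function() {
      pmax(0, ifelse(is_true,
                     rnorm(n, params$qual_true_mean, params$qual_true_sd),
                     rnorm(n, params$qual_false_mean, params$qual_false_sd)))
    }
    both$qual <- round(score(), 2)
    both$ssc <- round(score(), 2)
    both$vaq <- round(score(), 2)
    is_loh <- runif(n) < params$frac_loh
    both$status <- ifelse(is_loh, "LOH", "SOMATIC")
    both$error_class[!is_true & is_loh &
                       both$error_class == "GENERIC"] <- "LOH_ARTIFACT"
    both$depth_total <- rpois(n, params$mean_coverage)
    p_alt <- ifelse(is_true,
                    rbeta(n, params$alt_shape_true[1], params$alt_shape_true[2]),
                    rbeta(n, params$alt_shape_false[1], params$alt_shape_false[2]))
    both$depth_alt <- rbinom(n, both$depth_total, p_alt)
    both$sample_id <- sample_id
    both$replicate <- replicate
    both
  }

  wgs <- one_replicate("WGS", params$n_err_wgs)
  wga <- one_replicate("WGA", params$n_err_wga)
  all_calls <- bind_rows(wgs, wga)
  truth <- all_calls[, c("sample_id", "replicate", "chrom", "pos", "ref",
                         "alt", "truth", "error_class")]
  calls <- snv_calls(all_calls[, c("sample_id", "replicate", "chrom", "pos",
                                   "ref", "alt", "qual", "ssc", "vaq",
                                   "status", "depth_total", "depth_alt")])
  list(calls = calls, truth = truth, sites = sites, indels = indels,
       n_true = nrow(true_calls))
}

# place n_err false calls: dbSNP-coincident, near-indel, clustered, generic
simulate_error_calls <- function(n_err, params, sites, indels) {
  if (n_err == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), truth = character(),
                  error_class = character()))
  }
  probs <- c(DBSNP_SITE = params$frac_dbsnp_artifact,
             NEAR_INDEL = params$frac_clustered / 2,
             CLUSTERED = params$frac_clustered / 2)
  probs <- c(probs, GENERIC = 1 - sum(probs))
  cls <- sample(names(probs), n_err, replace = TRUE, prob = probs)
  if (nrow(sites) == 0) cls[cls == "DBSNP_SITE"] <- "GENERIC"
  if (nrow(indels) == 0) cls[cls == "NEAR_INDEL"] <- "GENERIC"

  n_generic <- sum(cls == "GENERIC")
  generic <- dplyr::bind_cols(sample_genome_positions(n_generic, params),
                              random_alleles(n_generic))
  generic$error_class <- "GENERIC"

  n_db <- sum(cls == "DBSNP_SITE")
  db <- if (n_db > 0) {
    picked <- sites[sample.int(nrow(sites), n_db, replace = TRUE), ]
    ref <- vapply(picked$alt, function(a) sample(setdiff(BASES, a), 1),
                  character(1))
    tibble(chrom = picked$chrom, pos = picked$pos, ref = unname(ref),
           alt = picked$alt, error_class = "DBSNP_SITE")
  }

  n_ni <- sum(cls == "NEAR_INDEL")
  ni <- if (n_ni > 0) {
    picked <- indels[sample.int(nrow(indels), n_ni, replace = TRUE), ]
    w <- params$proximity_window_bp
    pos <- pmax(1L, picked$start +
                  sample.int(2L * w + 1L, n_ni, replace = TRUE) - w - 1L)
    dplyr::bind_cols(tibble(chrom = picked$chrom, pos = as.integer(pos)),
                     random_alleles(n_ni)) |>
      mutate(error_class = "NEAR_INDEL")
  }

  # clustered errors come in pairs within the proximity window of each other
  n_cl <- sum(cls == "CLUSTERED")
  cl <- if (n_cl > 0) {
    n_anchor <- ceiling(n_cl / 2)
    anchors <- sample_genome_positions(n_anchor, params)
    w <- max(1L, params$proximity_window_bp)
    partner_pos <- pmax(1L, anchors$pos[seq_len(n_cl - n_anchor)] +
                          sample.int(w, n_cl - n_anchor, replace = TRUE))
    pos_tbl <- tibble(
      chrom = c(anchors$chrom, anchors$chrom[seq_len(n_cl - n_anchor)]),
      pos = as.integer(c(anchors$pos, partner_pos)))
    dplyr::bind_cols(pos_tbl, random_alleles(n_cl)) |>
      mutate(error_class = "CLUSTERED")
  }

  out <- bind_rows(generic, db, ni, cl)
  out$truth <- "ERROR"
  out[, c("chrom", "pos", "ref", "alt", "truth", "error_class")]
}

#' Expected percent overlap under the generator's assumptions
#'
#' Closed-form oracle for parameter-recovery tests: with `n_true` true
#' mutations detected independently in each replicate with probability
#' `detect_prob` and `n_err` expected false calls per replicate, the
#' expected fraction of one replicate's calls also present in the other is
#' `n_true * detect_prob^2 / (n_true * detect_prob + n_err)`.
#'
#' @param n_true Count of true fixed mutations.
#' @param detect_prob Per-replicate detection probability.
#' @param n_err Expected false calls in the replicate whose denominator is
#'   used.
#' @return Expected percent overlap (0-100).
#' @examples
#' expected_overlap_fraction(1000, 0.7, 300) # 49
#' @export
expected_overlap_fraction <- function(n_true, detect_prob, n_err) {
  denom <- n_true * detect_prob + n_err
  if (any(denom <= 0)) abort("degenerate denominator: no expected calls")
  100 * (n_true * detect_prob^2) / denom
}

#' Simulate a cohort and write it to disk
#'
#' Writes per-patient WGS/WGA VCFs, one shared dbSNP VCF, one indel BED,
#' a per-call truth table, a pairs manifest consumable by
#' [evaluate_filters()], and a JSON run manifest echoing the parameters,
#' the seed and md5 checksums of every written file.  One integer seed
#' derives all per-patient streams, so repeated runs are byte-identical.
#'
#' @param params A [sim_params()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (tibble), `truth`, `sites`,
#'   `indels`, and the file paths.
#' @export
simulate_cohort <- function(params, out_dir) {
  stopifnot(inherits(params, "sim_params"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create directory: ", out_dir))

  set.seed(as.integer(params$seed))
  shared <- simulate_site_lists(params)
  patient_seeds <- sample.int(2147483646L, params$n_patients)

  sample_ids <- sprintf("patient%02d", seq_len(params$n_patients))
  truth_all <- list()
  n_true <- integer(params$n_patients)
  manifest <- tibble(sample_id = sample_ids,
                     wgs_vcf = paste0(sample_ids, "_wgs.vcf"),
                     wga_vcf = paste0(sample_ids, "_wga.vcf"))
  for (i in seq_len(params$n_patients)) {
    sim <- simulate_pair(params, sample_ids[i], seed = patient_seeds[i],
                         sites = shared$sites, indels = shared$indels)
    for (rep_label in c("WGS", "WGA")) {
      calls <- sim$calls[sim$calls$replicate == rep_label, ]
      calls <- arrange(calls, .data$chrom, .data$pos, .data$alt)
      path <- file.path(out_dir, if (rep_label == "WGS") {
        manifest$wgs_vcf[i]
      } else {
        manifest$wga_vcf[i]
      })
      write_somatic_vcf(calls, path)
    }
    truth_all[[i]] <- sim$truth
    n_true[i] <- sim$n_true
  }
  truth <- bind_rows(truth_all)
  patients <- tibble(sample_id = sample_ids, seed = patient_seeds,
                     n_true = n_true)

  dbsnp_path <- file.path(out_dir, "dbsnp_synthetic.vcf")
  write_site_vcf(shared$sites, dbsnp_path)
  indel_path <- file.path(out_dir, "indels_synthetic.bed")
  writeLines(paste(shared$indels$chrom, shared$indels$start - 1L,
                   shared$indels$end, sep = "\t"), indel_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(truth, truth_path, progress = FALSE)
  manifest_path <- file.path(out_dir, "pairs_manifest.tsv")
  readr::write_tsv(manifest, manifest_path, progress = FALSE)
  patients_path <- file.path(out_dir, "patients.tsv")
  readr::write_tsv(patients, patients_path, progress = FALSE)

  files <- c(manifest$wgs_vcf, manifest$wga_vcf, basename(dbsnp_path),
             basename(indel_path), basename(truth_path),
             basename(manifest_path), basename(patients_path))
  run_manifest <- list(
    tool = "snvconcord::simulate_cohort",
    seed = params$seed,
    params = params[setdiff(names(params), "seed")],
    files = lapply(setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    }))
  jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(manifest = manifest, truth = truth, patients = patients,
                 sites = shared$sites, indels = shared$indels,
                 out_dir = out_dir, manifest_path = manifest_path,
                 dbsnp_path = dbsnp_path, indel_path = indel_path,
                 truth_path = truth_path, patients_path = patients_path))
}

# minimal sites-only VCF (CHROM/POS/REF/ALT; REF arbitrary valid base)
write_site_vcf <- function(sites, path) {
  sites <- arrange(sites, .data$chrom, .data$pos, .data$alt)
  ref <- vapply(sites$alt, function(a) {
    if (is.na(a)) "A" else setdiff(BASES, a)[1]
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##source=snvconcord-synthetic-sites",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  lines <- paste(sites$chrom, sites$pos, ".", unname(ref),
                 ifelse(is.na(sites$alt), "N", sites$alt), ".", ".", ".",
                 sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}
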