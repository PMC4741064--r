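#' VCF dialect: where each call field lives in a somatic VCF
#'
#' Somatic callers differ in which record or per-sample fields carry the
#' quality scores, somatic status and depths.  A dialect names those fields
#' once so [read_somatic_vcf()] stays caller-agnostic.  The defaults match
#' SomaticSniper-style output: record-level `QUAL`, per-sample `SSC`
#' (SomaticScore), `VAQ` (Variant Allele Quality) and `SS` (somatic status,
#' coded 1 = GERMLINE, 2 = SOMATIC, 3 = LOH, 4 = UNKNOWN), with depths from
#' `DP` plus an allele-depth vector `AD`, and the tumor genotype in the
#' last sample column.
#'
#' @param qual_source `"QUAL"` to take the record-level quality column, or
#'   the name of a per-sample FORMAT field.
#' @param ssc_field,vaq_field,status_field Per-sample FORMAT field names.
#' @param depth_mode `"AD"`: `depth_alt` is the allele-depth entry of the
#'   alternate allele and `depth_total` comes from `dp_field`;
#'   `"DP4"`: a strand-split quartet (ref-fwd, ref-rev, alt-fwd, alt-rev)
#'   whose last two entries sum to `depth_alt` and whose total is
#'   `depth_total`.
#' @param ad_field,dp_field,dp4_field FORMAT field names for the two depth
#'   modes.
#' @param tumor_sample Which sample column is the tumor: `"last"`
#'   (default), `"first"`, or an explicit sample name.
#' @param chrom_normalization `"off"` (default; names compared as written),
#'   `"strip-chr"`, or `"add-chr"`.
#' @param strict If `TRUE` (default) a FORMAT field named by the dialect but
#'   absent from the file header is an error; if `FALSE` the field is
#'   recorded as missing with one warning per field per file.
#' @return A list of class `vcf_dialect`.
#' @export
vcf_dialect <- function(qual_source = "QUAL",
                        ssc_field = "SSC", vaq_field = "VAQ",
                        status_field = "SS",
                        depth_mode = c("AD", "DP4"),
                        ad_field = "AD", dp_field = "DP", dp4_field = "DP4",
                        tumor_sample = "last",
                        chrom_normalization = c("off", "strip-chr", "add-chr"),
                        strict = TRUE) {
  depth_mode <- match.arg(depth_mode)
  chrom_normalization <- match.arg(chrom_normalization)
  fields <- c(ssc_field, vaq_field, status_field)
  if (any(!nzchar(fields))) abort("dialect field names must be non-empty")
  structure(list(qual_source = qual_source,
                 ssc_field = ssc_field, vaq_field = vaq_field,
                 status_field = status_field,
                 depth_mode = depth_mode, ad_field = ad_field,
                 dp_field = dp_field, dp4_field = dp4_field,
                 tumor_sample = tumor_sample,
                 chrom_normalization = chrom_normalization,
                 strict = strict),
            class = "vcf_dialect")
}

SS_CODE_MAP <- c("1" = "GERMLINE", "2" = "SOMATIC", "3" = "LOH", "4" = "UNKNOWN")

normalize_chrom <- function(chrom, mode) {
  switch(mode,
         "off" = chrom,
         "strip-chr" = sub("^chr", "", chrom),
         "add-chr" = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)))
}

#' Read a somatic VCF into a call table and an indel table
#'
#' Every record whose REF and ALT are single bases yields one SNV call;
#' multi-allelic records are decomposed into one call per alternate allele.
#' Records where REF or ALT spans more than one base are returned as indel
#' records covering the closed span `[pos, pos + nchar(ref) - 1]`.
#'
#' @param path Path to a VCF 4.x file (plain or gz-compressed).
#' @param dialect A [vcf_dialect()]; defaults to SomaticSniper conventions.
#' @param sample_id Patient identifier stamped on every call.
#' @param replicate Replicate label, `"WGS"` or `"WGA"`.
#' @return A list with `calls` (an [snv_calls()] tibble, file order) and
#'   `indels` (an [indel_records()] tibble).
#' @export
read_somatic_vcf <- function(path, dialect = vcf_dialect(),
                             sample_id = NA_character_,
                             replicate = NA_character_) {
  if (!file.exists(path)) abort(paste0("cannot read VCF: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))

  empty <- list(
    calls = snv_calls(tibble(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             sample_id = character(), replicate = character())),
    indels = indel_records(tibble(chrom = character(), start = integer(),
                                  end = integer())))
  if (nrow(fix) == 0) return(empty)

  fmt_fields <- declared_format_fields(vcf)
  need <- c(dialect$ssc_field, dialect$vaq_field, dialect$status_field)
  need <- c(need, switch(dialect$depth_mode,
                         AD = c(dialect$ad_field, dialect$dp_field),
                         DP4 = dialect$dp4_field))
  if (!identical(dialect$qual_source, "QUAL")) need <- c(need, dialect$qual_source)
  absent <- setdiff(need, fmt_fields)
  if (length(absent) > 0) {
    if (dialect$strict) {
      abort(paste0("VCF header of ", path,
                   " does not declare FORMAT field(s): ",
                   paste(absent, collapse = ", ")))
    }
    for (f in absent) {
      warn(paste0("FORMAT field ", f, " not declared in ", path,
                  "; recorded as missing"))
    }
  }

  tumor <- tumor_column(vcf, dialect$tumor_sample)
  get_field <- function(field, numeric = TRUE) {
    if (field %in% absent) {
      return(rep(if (numeric) NA_real_ else NA_character_, nrow(fix)))
    }
    m <- vcfR::extract.gt(vcf, element = field, as.numeric = numeric)
    unname(m[, tumor])
  }

  chrom <- normalize_chrom(unname(fix[, "CHROM"]), dialect$chrom_normalization)
  pos <- as.integer(unname(fix[, "POS"]))
  ref <- unname(fix[, "REF"])
  alt_raw <- unname(fix[, "ALT"])

  qual <- if (identical(dialect$qual_source, "QUAL")) {
    suppressWarnings(as.numeric(unname(fix[, "QUAL"])))
  } else {
    get_field(dialect$qual_source)
  }
  ssc <- get_field(dialect$ssc_field)
  vaq <- get_field(dialect$vaq_field)
  ss_code <- get_field(dialect$status_field)
  status <- unname(SS_CODE_MAP[as.character(ss_code)])

  if (dialect$depth_mode == "AD") {
    ad <- get_field(dialect$ad_field, numeric = FALSE)
    depth_total <- as.integer(round(get_field(dialect$dp_field)))
  } else {
    dp4 <- get_field(dialect$dp4_field, numeric = FALSE)
    dp4_mat <- vapply(strsplit(ifelse(is.na(dp4), "", dp4), ","),
                      function(v) {
                        v <- suppressWarnings(as.integer(v))
                        if (length(v) != 4 || anyNA(v)) rep(NA_integer_, 2)
                        else c(sum(v), v[3] + v[4])
                      }, integer(2))
    depth_total <- dp4_mat[1, ]
    depth_alt_rec <- dp4_mat[2, ]
  }

  # decompose multi-allelic records: one expanded row per alternate allele
  alts <- strsplit(alt_raw, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_along(alts), n_alt)
  alt_j <- sequence(n_alt)
  alt_vec <- unlist(alts, use.names = FALSE)
  is_snv <- nchar(ref[idx]) == 1L & nchar(alt_vec) == 1L

  si <- idx[is_snv]
  depth_alt_v <- if (dialect$depth_mode == "AD") {
    if (dialect$ad_field %in% absent) {
      rep(NA_integer_, length(si))
    } else {
      ad_split <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
      entry <- alt_j[is_snv] + 1L
      vapply(seq_along(si), function(k) {
        v <- suppressWarnings(as.integer(ad_split[[si[k]]]))
        if (length(v) < entry[k]) NA_integer_ else v[entry[k]]
      }, integer(1))
    }
  } else {
    depth_alt_rec[si]
  }

  calls <- tibble(
    sample_id = sample_id, replicate = replicate,
    chrom = chrom[si], pos = pos[si], ref = ref[si], alt = alt_vec[is_snv],
    qual = qual[si], ssc = ssc[si], vaq = vaq[si], status = status[si],
    depth_total = depth_total[si], depth_alt = depth_alt_v)
  # a decomposed multi-allelic alt can carry less depth than DP, never more
  both <- !is.na(calls$depth_alt) & !is.na(calls$depth_total)
  calls$depth_alt[both] <- pmin(calls$depth_alt[both], calls$depth_total[both])

  keys <- snv_key(calls)
  dup <- duplicated(keys)
  if (any(dup)) {
    abort(paste0("duplicate SNV key in ", path, ": ", keys[dup][1]))
  }
  indels <- if (any(!is_snv)) {
    ii <- idx[!is_snv]
    indel_records(distinct(tibble(chrom = chrom[ii], start = pos[ii],
                                  end = pos[ii] + nchar(ref[ii]) - 1L)))
  } else {
    empty$indels
  }
  list(calls = snv_calls(calls), indels = indels)
}

declared_format_fields <- function(vcf) {
  meta <- vcf@meta
  ids <- regmatches(meta, regexpr("##FORMAT=<ID=[^,>]+", meta))
  sub("##FORMAT=<ID=", "", ids)
}

tumor_column <- function(vcf, selector) {
  samples <- colnames(vcf@gt)[-1]
  if (length(samples) == 0) abort("VCF has no sample columns")
  if (identical(selector, "last")) return(samples[length(samples)])
  if (identical(selector, "first")) return(samples[1])
  if (!selector %in% samples) {
    abort(paste0("tumor sample \"", selector, "\" not among VCF samples: ",
                 paste(samples, collapse = ", ")))
  }
  selector
}

#' Read a site list (dbSNP-style) from VCF or BED
#'
#' VCF input takes sites from CHROM/POS/ALT (multi-allelic records yield one
#' site per alternate allele).  BED3 input uses the half-open 0-based BED
#' convention: a line `chrom 99 101` covers 1-based positions 100 and 101,
#' and every covered position becomes a site with a wildcard (NA) alternate
#' allele.
#'
#' @param path Path ending in `.vcf`, `.vcf.gz`, or `.bed`.
#' @return A de-duplicated [site_keys()] tibble.
#' @export
read_site_list <- function(path) {
  if (!grepl("\\.(vcf(\\.gz)?|bed)$", path)) {
    abort(paste0("unrecognized site-list format: ", path,
                 " (accepted: .vcf, .vcf.gz, .bed)"))
  }
  if (!file.exists(path)) abort(paste0("cannot read site list: ", path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    if (nrow(fix) == 0) {
      return(site_keys(tibble(chrom = character(), pos = integer())))
    }
    alts <- strsplit(unname(fix[, "ALT"]), ",", fixed = TRUE)
    n_alt <- lengths(alts)
    site_keys(tibble(chrom = rep(unname(fix[, "CHROM"]), n_alt),
                     pos = rep(as.integer(unname(fix[, "POS"])), n_alt),
                     alt = unlist(alts, use.names = FALSE)))
  } else if (grepl("\\.bed$", path)) {
    bed <- read_bed3(path)
    if (nrow(bed) == 0) {
      return(site_keys(tibble(chrom = character(), pos = integer())))
    }
    pos <- purrr::map2(bed$start, bed$end, function(s, e) seq.int(s + 1L, e))
    site_keys(tibble(chrom = rep(bed$chrom, lengths(pos)),
                     pos = as.integer(unlist(pos))))
  }
}

#' Read an indel position list from BED or VCF
#'
#' BED spans (0-based half-open) become 1-based closed spans; VCF records
#' use `[pos, pos + nchar(ref) - 1]`.
#'
#' @param path Path ending in `.bed`, `.vcf` or `.vcf.gz`.
#' @return An [indel_records()] tibble.
#' @export
read_indel_list <- function(path) {
  if (!grepl("\\.(vcf(\\.gz)?|bed)$", path)) {
    abort(paste0("unrecognized indel-list format: ", path,
                 " (accepted: .bed, .vcf, .vcf.gz)"))
  }
  if (!file.exists(path)) abort(paste0("cannot read indel list: ", path))
  if (grepl("\\.bed$", path)) {
    bed <- read_bed3(path)
    indel_records(tibble(chrom = bed$chrom, start = bed$start + 1L,
                         end = bed$end))
  } else if (grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    if (nrow(fix) == 0) {
      return(indel_records(tibble(chrom = character(), start = integer(),
                                  end = integer())))
    }
    pos <- as.integer(unname(fix[, "POS"]))
    indel_records(tibble(chrom = unname(fix[, "CHROM"]), start = pos,
                         end = pos + nchar(unname(fix[, "REF"])) - 1L))
  }
}

read_bed3 <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", comment = "#", progress = FALSE)
  if (nrow(bed) > 0 && (anyNA(bed$start) || anyNA(bed$end))) {
    abort(paste0("malformed BED3 file: ", path))
  }
  bed
}

#' Write a call table as a somatic VCF
#'
#' Emits valid VCF 4.2 with two sample columns (NORMAL, TUMOR) using the
#' SomaticSniper-style FORMAT fields `DP:AD:SSC:VAQ:SS` that
#' [read_somatic_vcf()] parses back with the default dialect.  Numeric
#' values use a canonical shortest decimal form, so writing is
#' deterministic and read-write-read is a fixed point.
#'
#' @param calls An [snv_calls()] tibble (a single sample/replicate).
#' @param path Output path (plain text).
#' @param removed_keys Character vector of `chrom:pos:ref:alt` keys to drop
#'   or flag.
#' @param mode `"drop"` omits removed calls; `"flag"` writes every call with
#'   `filter_name` in the FILTER column for removed calls and `PASS`
#'   otherwise.
#' @param filter_name Label written in the FILTER column in flag mode.
#' @return Invisibly, the path.
#' @export
write_somatic_vcf <- function(calls, path, removed_keys = character(),
                              mode = c("drop", "flag"),
                              filter_name = "filtered") {
  mode <- match.arg(mode)
  keys <- snv_key(calls)
  removed <- keys %in% removed_keys
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snvconcord",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=SSC,Number=1,Type=Float,Description=\"Somatic score\">",
    "##FORMAT=<ID=VAQ,Number=1,Type=Float,Description=\"Variant allele quality\">",
    "##FORMAT=<ID=SS,Number=1,Type=Integer,Description=\"Somatic status: 1=germline,2=somatic,3=LOH,4=unknown\">",
    if (mode == "flag") {
      paste0("##FILTER=<ID=", filter_name, ",Description=\"Removed by the ",
             filter_name, " filter\">")
    },
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NORMAL", "TUMOR", sep = "\t"))

  keep <- if (mode == "drop") !removed else rep(TRUE, nrow(calls))
  x <- calls[keep, , drop = FALSE]
  filt <- if (mode == "flag") {
    ifelse(removed[keep], filter_name, "PASS")
  } else {
    rep(".", nrow(x))
  }
  ss_inv <- setNames(names(SS_CODE_MAP), SS_CODE_MAP)
  ss <- ifelse(is.na(x$status), ".", unname(ss_inv[x$status]))
  ad <- ifelse(is.na(x$depth_total) | is.na(x$depth_alt), ".",
               paste0(x$depth_total - x$depth_alt, ",", x$depth_alt))
  fmt <- paste(num_or_dot(x$depth_total), ad, num_or_dot(x$ssc),
               num_or_dot(x$vaq), ss, sep = ":")
  lines <- paste(x$chrom, x$pos, ".", x$ref, x$alt, num_or_dot(x$qual),
                 filt, ".", "DP:AD:SSC:VAQ:SS", ".:.:.:.:.", fmt, sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

# canonical shortest-decimal rendering; "." for NA (VCF missing marker)
num_or_dot <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.15g", as.numeric(x)))
}

#' Read a pairs manifest
#'
#' A pairs manifest is a TSV with columns `sample_id`, `wgs_vcf`,
#' `wga_vcf`; relative VCF paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest path.
#' @return Tibble with absolute VCF paths.
#' @export
read_pairs_manifest <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  need <- c("sample_id", "wgs_vcf", "wga_vcf")
  if (!all(need %in% names(m))) {
    abort(paste0("pairs manifest must have columns: ",
                 paste(need, collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  m$wgs_vcf <- resolve(m$wgs_vcf)
  m$wga_vcf <- resolve(m$wga_vcf)
  m
}
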