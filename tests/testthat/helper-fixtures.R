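# Fixture builders and independent brute-force oracles shared across tests.

# quick call-table builder; scalar arguments recycle across positions
make_calls <- function(pos, chrom = "chr1", ref = "A", alt = "G",
                       sample_id = "p1", replicate = "WGS",
                       qual = NA_real_, ssc = NA_real_, vaq = NA_real_,
                       status = NA_character_,
                       depth_total = NA_integer_, depth_alt = NA_integer_) {
  snv_calls(tibble::tibble(
    sample_id = sample_id, replicate = replicate, chrom = chrom,
    pos = as.integer(pos), ref = ref, alt = alt, qual = qual, ssc = ssc,
    vaq = vaq, status = status, depth_total = as.integer(depth_total),
    depth_alt = as.integer(depth_alt)))
}

# random call set on a small genome; distinct keys guaranteed
random_calls <- function(n, max_pos = 1000, n_chroms = 2,
                         replicate = "WGS", sample_id = "p1") {
  keys <- unique(tibble::tibble(
    chrom = sample(paste0("chr", seq_len(n_chroms)), n, replace = TRUE),
    pos = sample.int(max_pos, n, replace = TRUE),
    ref = "A",
    alt = sample(c("C", "G", "T"), n, replace = TRUE)))
  make_calls(keys$pos, chrom = keys$chrom, ref = keys$ref, alt = keys$alt,
             replicate = replicate, sample_id = sample_id)
}

# O(n^2) all-pairs oracle for the SNV proximity filter: every pair (i, j),
# i != j, is checked for same chromosome and |pos_i - pos_j| <= window
bf_snv_proximity <- function(calls, window_bp) {
  n <- nrow(calls)
  if (n < 2) return(logical(n))
  same_chrom <- outer(calls$chrom, calls$chrom, `==`)
  close <- abs(outer(calls$pos, calls$pos, `-`)) <= window_bp
  pair <- same_chrom & close
  diag(pair) <- FALSE
  rowSums(pair) > 0
}

# brute-force oracle for the indel proximity filter
bf_indel_proximity <- function(calls, indels, window_bp) {
  vapply(seq_len(nrow(calls)), function(i) {
    any(vapply(seq_len(nrow(indels)), function(j) {
      if (calls$chrom[i] != indels$chrom[j]) return(FALSE)
      p <- calls$pos[i]
      gap <- if (p >= indels$start[j] && p <= indels$end[j]) 0 else
        min(abs(p - indels$start[j]), abs(p - indels$end[j]))
      gap <= window_bp
    }, logical(1)))
  }, logical(1))
}

# explicit rank-then-Pearson Spearman oracle
bf_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# write a small SomaticSniper-style VCF fixture and return its path
write_fixture_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "fixture.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=SSC,Number=1,Type=Float,Description=\"Somatic score\">",
    "##FORMAT=<ID=VAQ,Number=1,Type=Float,Description=\"Variant allele quality\">",
    "##FORMAT=<ID=SS,Number=1,Type=Integer,Description=\"Somatic status\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "NORMAL", "TUMOR", sep = "\t"))
  writeLines(c(header, lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, qual = 50,
                     tumor = "28:20,8:77:60:2") {
  paste(chrom, pos, ".", ref, alt, qual, ".", ".", "DP:AD:SSC:VAQ:SS",
        "30:30,0:.:.:1", tumor, sep = "\t")
}
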