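# Boundary semantics under test throughout: thresholds remove strictly-below
# values; the proximity window is inclusive; the alt-fraction filter removes
# strictly-below fractions.

test_that("threshold filters remove values strictly below the threshold", {
  calls <- make_calls(1:5 * 10, vaq = c(10, 39, 40, 41, 100))
  res <- threshold_filter(calls, "vaq", 40)
  expect_equal(res$removed, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  k <- filter_keys(res)
  expect_setequal(k$removed, snv_key(calls)[1:2])
  expect_setequal(k$kept, snv_key(calls)[3:5])
  expect_equal(attr(res, "filter_name"), "VAQ")
  # same semantics for the qual (GATK) and ssc (SS) fields
  expect_equal(threshold_filter(make_calls(1:2, qual = c(39.999, 40)),
                                "qual", 40)$removed, c(TRUE, FALSE))
  expect_equal(attr(threshold_filter(calls, "ssc", 40), "filter_name"), "SS")
})

test_that("threshold filter handles empty input and the all-pass case", {
  empty <- threshold_filter(make_calls(integer(0)), "vaq", 40)
  expect_equal(nrow(empty), 0)
  allpass <- threshold_filter(make_calls(1:3, vaq = c(40, 50, 60)), "vaq", 40)
  expect_false(any(allpass$removed))
})

test_that("missing fields are kept and counted, or raise in strict mode", {
  calls <- make_calls(1:3, vaq = c(10, NA, 50))
  res <- threshold_filter(calls, "vaq", 40)
  expect_equal(res$removed, c(TRUE, FALSE, FALSE))
  expect_equal(glance(res)$n_missing_field, 1)
  expect_error(threshold_filter(calls, "vaq", 40, missing = "error"),
               "chr1:2:A:G")
})

test_that("LOH filter removes exactly the LOH-status calls", {
  expect_false(any(loh_filter(make_calls(1:3, status = "SOMATIC"))$removed))
  mixed <- make_calls(1:7, status = rep(c("SOMATIC", "LOH"), c(4, 3)))
  res <- loh_filter(mixed)
  expect_equal(sum(res$removed), 3)
  # GERMLINE is not targeted by this filter
  res2 <- loh_filter(make_calls(1:2, status = c("GERMLINE", "LOH")))
  expect_equal(res2$removed, c(FALSE, TRUE))
})

test_that("SNV proximity boundary: distance 10 removes, 11 keeps", {
  single <- snv_proximity_filter(make_calls(100), 10)
  expect_false(any(single$removed))
  near <- snv_proximity_filter(make_calls(c(100, 110)), 10)
  expect_true(all(near$removed))
  far <- snv_proximity_filter(make_calls(c(100, 111)), 10)
  expect_false(any(far$removed))
  # different chromosomes never count as close
  cross <- snv_proximity_filter(make_calls(c(100, 105),
                                           chrom = c("chr1", "chr2")), 10)
  expect_false(any(cross$removed))
})

test_that("proximity chains remove every member with a close neighbor", {
  chain <- snv_proximity_filter(make_calls(c(100, 108, 116)), 10)
  expect_true(all(chain$removed))
  # two distinct substitutions at one position are distance 0 apart
  same_pos <- make_calls(c(50, 50), alt = c("G", "T"))
  expect_true(all(snv_proximity_filter(same_pos, 10)$removed))
})

test_that("proximity filter judges neighbors on the original set (single pass)", {
  # 118's only close neighbor (108) is itself removed; a second pass on the
  # kept set would find nothing, which is exactly the single-pass semantics
  calls <- make_calls(c(100, 108, 118, 300))
  res <- snv_proximity_filter(calls, 10)
  expect_equal(res$removed, c(TRUE, TRUE, TRUE, FALSE))
  second <- snv_proximity_filter(res[!res$removed, ], 10)
  expect_false(any(second$removed))
})

test_that("interval-based proximity matches the all-pairs brute force", {
  set.seed(2024)
  for (i in 1:30) {
    calls <- random_calls(sample.int(120, 1), max_pos = 500)
    w <- sample(c(0, 1, 5, 10, 25), 1)
    expect_identical(snv_proximity_filter(calls, w)$removed,
                     bf_snv_proximity(calls, w),
                     info = paste("case", i, "window", w))
  }
})

test_that("indel proximity uses gap distance to the affected span", {
  ind <- indel_records(tibble::tibble(chrom = "chr1", start = 110L, end = 112L))
  no_indels <- indel_proximity_filter(
    make_calls(105), indel_records(tibble::tibble(chrom = character(),
                                                  start = integer(),
                                                  end = integer())), 10)
  expect_false(any(no_indels$removed))
  expect_true(indel_proximity_filter(make_calls(105), ind, 10)$removed)  # gap 5
  expect_true(indel_proximity_filter(make_calls(111), ind, 10)$removed)  # inside
  expect_true(indel_proximity_filter(make_calls(100), ind, 10)$removed)  # gap 10
  expect_false(indel_proximity_filter(make_calls(99), ind, 10)$removed)  # gap 11
  expect_false(indel_proximity_filter(make_calls(111, chrom = "chr2"),
                                      ind, 10)$removed)
})

test_that("indel proximity matches its brute-force oracle on random inputs", {
  set.seed(77)
  for (i in 1:20) {
    calls <- random_calls(sample.int(80, 1), max_pos = 400)
    starts <- sample.int(400, 10)
    ind <- indel_records(tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 10, replace = TRUE),
      start = starts, end = starts + sample(0:4, 10, replace = TRUE)))
    expect_identical(indel_proximity_filter(calls, ind, 10)$removed,
                     bf_indel_proximity(calls, ind, 10))
  }
})

test_that("dbSNP matching is allele-aware in position+alt mode", {
  sites <- site_keys(tibble::tibble(chrom = "chr1", pos = 100L, alt = "G"))
  none <- dbsnp_filter(make_calls(100), site_keys(tibble::tibble(
    chrom = character(), pos = integer())))
  expect_false(any(none$removed))

  hit <- make_calls(100, ref = "A", alt = "G")
  expect_true(dbsnp_filter(hit, sites, "position+alt")$removed)
  expect_true(dbsnp_filter(hit, sites, "position-only")$removed)

  other_allele <- make_calls(100, ref = "A", alt = "T")
  expect_false(dbsnp_filter(other_allele, sites, "position+alt")$removed)
  expect_true(dbsnp_filter(other_allele, sites, "position-only")$removed)

  # wildcard sites (BED-derived) match any allele in both modes
  wild <- site_keys(tibble::tibble(chrom = "chr1", pos = 100L,
                                   alt = NA_character_))
  expect_true(dbsnp_filter(other_allele, wild, "position+alt")$removed)
})

test_that("alt-fraction boundary: 5% removed, exactly 10% kept", {
  calls <- make_calls(1:2, depth_total = c(20, 20), depth_alt = c(1, 2))
  res <- alt_fraction_filter(calls, 0.10)
  expect_equal(res$removed, c(TRUE, FALSE))
  # zero or missing depth: kept and counted as missing
  degenerate <- make_calls(1:2, depth_total = c(0, NA), depth_alt = c(0, NA))
  res2 <- suppressMessages(alt_fraction_filter(degenerate, 0.10))
  expect_false(any(res2$removed))
  expect_equal(glance(res2)$n_missing_field, 2)
})

test_that("every filter partitions its input keys", {
  set.seed(11)
  calls <- random_calls(150, max_pos = 2000)
  calls$qual <- runif(150, 0, 80)
  calls$ssc <- runif(150, 0, 80)
  calls$vaq <- runif(150, 0, 80)
  calls$status <- sample(c("SOMATIC", "LOH"), 150, replace = TRUE)
  calls$depth_total <- rpois(150, 30L)
  calls$depth_alt <- pmin(calls$depth_total, rpois(150, 4L))
  sites <- site_keys(calls[sample.int(150, 20), c("chrom", "pos", "alt")])
  ind <- indel_records(tibble::tibble(chrom = "chr1", start = c(100L, 900L),
                                      end = c(102L, 900L)))
  fs <- apply_filters(calls, filter_config(), sites, ind)
  all_keys <- snv_key(calls)
  for (res in fs$results) {
    k <- filter_keys(res)
    expect_length(intersect(k$removed, k$kept), 0)
    expect_setequal(c(k$removed, k$kept), all_keys)
  }
})

test_that("filters other than SNV-proximity are idempotent on their kept set", {
  set.seed(12)
  calls <- random_calls(100, max_pos = 1500)
  calls$vaq <- runif(100, 0, 80)
  calls$status <- sample(c("SOMATIC", "LOH"), 100, replace = TRUE)
  for (build in list(function(x) threshold_filter(x, "vaq", 40),
                     loh_filter)) {
    first <- build(calls)
    again <- build(first[!first$removed, ])
    expect_false(any(again$removed))
  }
})

test_that("raising a threshold never shrinks the removed set", {
  set.seed(13)
  calls <- make_calls(seq_len(60) * 100, vaq = runif(60, 0, 100))
  prev <- character(0)
  for (thr in c(0, 10, 20, 40, 60, 80, 100, 120)) {
    removed <- filter_keys(threshold_filter(calls, "vaq", thr))$removed
    expect_true(all(prev %in% removed))
    prev <- removed
  }
})

test_that("apply_filters unions removals and ignores filter order", {
  calls <- make_calls(1:10 * 100, vaq = c(rep(10, 3), rep(90, 7)),
                      status = c(rep("SOMATIC", 6), rep("LOH", 4)))
  cfg <- filter_config(enabled_filters = c("VAQ", "LOH"))
  fs <- apply_filters(calls, cfg)
  # VAQ removes 3, LOH removes 4, disjoint by construction
  expect_length(fs$combined_removed, 7)

  cfg_rev <- filter_config(enabled_filters = c("LOH", "VAQ"))
  fs_rev <- apply_filters(calls, cfg_rev)
  expect_setequal(fs$combined_removed, fs_rev$combined_removed)

  single <- apply_filters(calls, filter_config(enabled_filters = "VAQ"))
  expect_setequal(single$combined_removed,
                  filter_keys(threshold_filter(calls, "vaq", 40))$removed)

  noop <- apply_filters(calls, filter_config(enabled_filters = "dbSNP"))
  expect_length(noop$combined_removed, 0)

  expect_error(apply_filters(calls, structure(list(enabled_filters = character()),
                                              class = "filter_config")),
               "no filters enabled")
})

test_that("proximity filters see the whole original set, not PASS calls only", {
  # the low-VAQ call at 108 still condemns its neighbor at 100
  calls <- make_calls(c(100, 108, 400), vaq = c(90, 10, 90))
  fs <- apply_filters(calls, filter_config(enabled_filters = c("VAQ", "10bp-SNV")))
  prox <- filter_keys(fs$results[["10bp-SNV"]])$removed
  expect_setequal(prox, snv_key(calls)[1:2])
})
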