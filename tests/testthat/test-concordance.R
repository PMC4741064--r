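pair_calls <- function(wgs_pos, wga_pos, sample_id = "p1") {
  dplyr::bind_rows(
    make_calls(wgs_pos, replicate = "WGS", sample_id = sample_id),
    make_calls(wga_pos, replicate = "WGA", sample_id = sample_id))
}

test_that("identical and disjoint replicates bound the overlap statistics", {
  same <- pair_overlap(pair_calls(1:5, 1:5))
  expect_equal(same$pct_overlap_wgs, 100)
  expect_equal(same$pct_overlap_wga, 100)
  expect_equal(same$jaccard, 1)

  disjoint <- pair_overlap(pair_calls(1:4, 11:14))
  expect_equal(disjoint$n_overlap, 0)
  expect_equal(disjoint$jaccard, 0)
})

test_that("overlap statistics match set arithmetic on a constructed pair", {
  # |WGS| = 4, |WGA| = 6, overlap {1, 2}
  res <- pair_overlap(pair_calls(1:4, c(1, 2, 11:14)))
  expect_equal(res$n_wgs, 4)
  expect_equal(res$n_wga, 6)
  expect_equal(res$n_overlap, 2)
  expect_equal(res$pct_overlap_wgs, 50)
  expect_equal(res$pct_overlap_wga, 100 * 2 / 6)
  expect_equal(res$jaccard, 0.25)
})

test_that("empty replicates give explicit undefined markers", {
  res <- suppressMessages(pair_overlap(make_calls(1:3, replicate = "WGS")))
  expect_equal(res$n_wga, 0)
  expect_true(is.na(res$pct_overlap_wga))
  expect_equal(res$pct_overlap_wgs, 0)
  expect_equal(res$jaccard, 0)
})

test_that("overlap invariants hold on 500 random pairs", {
  set.seed(500)
  for (i in 1:500) {
    a <- sample.int(40, sample.int(12, 1))
    b <- sample.int(40, sample.int(12, 1))
    res <- pair_overlap(pair_calls(a, b))
    expect_equal(res$jaccard,
                 res$n_overlap / (res$n_wgs + res$n_wga - res$n_overlap))
    expect_lte(res$n_overlap, min(res$n_wgs, res$n_wga))
    expect_gte(res$jaccard, 0)
    expect_lte(res$jaccard, 1)
    expect_lte(res$jaccard,
               min(res$pct_overlap_wgs, res$pct_overlap_wga) / 100)
    if (res$n_wga >= res$n_wgs) {
      expect_gte(res$pct_overlap_wgs, res$pct_overlap_wga)
    }
  }
})

# build filter results that remove exactly the requested keys, via dbSNP
remove_exactly <- function(calls, victims) {
  sites <- if (length(victims) > 0) {
    parts <- strsplit(victims, ":", fixed = TRUE)
    site_keys(tibble::tibble(chrom = vapply(parts, `[[`, "", 1),
                             pos = as.integer(vapply(parts, `[[`, "", 2)),
                             alt = vapply(parts, `[[`, "", 4)))
  } else {
    site_keys(tibble::tibble(chrom = character(), pos = integer()))
  }
  dbsnp_filter(calls, sites, "position+alt")
}

test_that("filter_effect separates overlap and difference removals", {
  # overlap {m1, m2} at pos 1:2; WGS-only {d1, d2, d3} at 11:13
  calls <- pair_calls(c(1, 2, 11, 12, 13), c(1, 2))
  wgs <- calls[calls$replicate == "WGS", ]
  wga <- calls[calls$replicate == "WGA", ]
  keys <- snv_key(wgs)
  # remove m1 from both replicates and d1, d2 from WGS
  wgs_res <- remove_exactly(wgs, keys[c(1, 3, 4)])
  wga_res <- remove_exactly(wga, keys[1])
  eff <- filter_effect(wgs_res, wga_res)
  expect_equal(eff$n_removed_overlap, 1)
  expect_equal(eff$n_removed_difference, 2)
  expect_equal(eff$pct_overlap_removed, 50)
  expect_equal(eff$diff_over_overlap_ratio, 2.0)
  # jaccard on kept sets: kept WGS {m2, d3}, kept WGA {m2} -> 1/2
  expect_equal(eff$jaccard_after, 0.5)
  expect_equal(eff$jaccard_before, 2 / 5)
})

test_that("a no-op filter leaves every effect statistic at its identity", {
  calls <- pair_calls(1:4, 2:6)
  wgs <- calls[calls$replicate == "WGS", ]
  wga <- calls[calls$replicate == "WGA", ]
  eff <- filter_effect(remove_exactly(wgs, character(0)),
                       remove_exactly(wga, character(0)))
  expect_equal(eff$pct_overlap_removed, 0)
  expect_equal(eff$jaccard_after, eff$jaccard_before)
  expect_equal(eff$pct_jaccard_change, 0)
  expect_true(is.na(eff$diff_over_overlap_ratio))
})

test_that("undefined ratios are NA markers, never sentinel numbers", {
  disjoint <- pair_calls(1:3, 11:13)
  wgs <- disjoint[disjoint$replicate == "WGS", ]
  wga <- disjoint[disjoint$replicate == "WGA", ]
  eff <- filter_effect(remove_exactly(wgs, snv_key(wgs)[1]),
                       remove_exactly(wga, character(0)))
  expect_true(is.na(eff$pct_overlap_removed))  # empty overlap
  expect_true(is.na(eff$diff_over_overlap_ratio))  # nothing removed from it
  expect_false(any(is.infinite(unlist(eff[sapply(eff, is.numeric)]))))
})

test_that("removing an overlap key never raises Jaccard; a difference key never lowers it", {
  set.seed(900)
  for (i in 1:100) {
    a <- sample.int(30, sample(3:10, 1))
    b <- sample.int(30, sample(3:10, 1))
    calls <- pair_calls(a, b)
    wgs <- calls[calls$replicate == "WGS", ]
    wga <- calls[calls$replicate == "WGA", ]
    before <- pair_overlap(calls)$jaccard
    for (key in snv_key(wgs)) {
      in_overlap <- key %in% snv_key(wga)
      eff <- filter_effect(remove_exactly(wgs, key),
                           remove_exactly(wga, key))
      if (in_overlap) {
        expect_lte(eff$jaccard_after, before)
      } else {
        expect_gte(eff$jaccard_after, before)
      }
    }
  }
})

test_that("removals confined to the overlap strictly decrease Jaccard", {
  # 6-key union: overlap {1, 2}, WGS-only {11, 12}, WGA-only {21, 22}
  calls <- pair_calls(c(1, 2, 11, 12), c(1, 2, 21, 22))
  wgs <- calls[calls$replicate == "WGS", ]
  wga <- calls[calls$replicate == "WGA", ]
  overlap_keys <- intersect(snv_key(wgs), snv_key(wga))
  for (key in overlap_keys) {
    eff <- filter_effect(remove_exactly(wgs, key), remove_exactly(wga, key))
    expect_lt(eff$pct_jaccard_change, 0)
  }
})

test_that("jaccard_after agrees with recomputing the overlap on kept sets", {
  set.seed(901)
  calls <- pair_calls(sample.int(30, 12), sample.int(30, 15))
  wgs <- calls[calls$replicate == "WGS", ]
  wga <- calls[calls$replicate == "WGA", ]
  victims_wgs <- sample(snv_key(wgs), 5)
  victims_wga <- sample(snv_key(wga), 6)
  eff <- filter_effect(remove_exactly(wgs, victims_wgs),
                       remove_exactly(wga, victims_wga))
  kept <- dplyr::bind_rows(
    wgs[!snv_key(wgs) %in% victims_wgs, ],
    wga[!snv_key(wga) %in% victims_wga, ])
  expect_equal(eff$jaccard_after, pair_overlap(kept)$jaccard)
})

test_that("spearman matches the closed form on the worked example", {
  res <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(res$s_stat, 4)
  expect_equal(res$rho, 1 - 6 * 4 / (5 * 24))
  expect_equal(res$rho, 0.8)
  expect_equal(res$n, 5)
})

test_that("spearman hits the monotone limits and rejects bad input", {
  up <- spearman_cor(1:6, (1:6)^2)
  expect_equal(up$rho, 1)
  expect_equal(up$s_stat, 0)
  expect_equal(spearman_cor(1:6, -(1:6))$rho, -1)
  expect_error(spearman_cor(1:4, 1:5), "equal length")
  expect_true(is.na(spearman_cor(1:5, rep(1, 5))$rho))
})

test_that("spearman equals explicit rank-then-Pearson on random vectors", {
  set.seed(321)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- sample.int(20, n, replace = TRUE)  # ties likely
    y <- x + rnorm(n, sd = 3)
    res <- spearman_cor(x, y)
    expect_lt(abs(res$rho - bf_spearman_rho(x, y)), 1e-12)
    expect_equal(res$s_stat, sum((rank(x) - rank(y))^2))
  }
})

test_that("spearman agrees with the asymptotic stats::cor.test on tie-free data", {
  set.seed(42)
  x <- rnorm(30)
  y <- x + rnorm(30)
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  res <- spearman_cor(x, y)
  expect_equal(res$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$s_stat, unname(ct$statistic), tolerance = 1e-9)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-9)
})

test_that("complementarity sums the two percent-overlap removals", {
  calls <- pair_calls(1:4, 1:4)  # overlap of 4 keys
  wgs <- calls[calls$replicate == "WGS", ]
  wga <- calls[calls$replicate == "WGA", ]
  keys <- snv_key(wgs)
  eff_of <- function(victims) {
    filter_effect(remove_exactly(wgs, victims), remove_exactly(wga, victims))
  }
  # LOH removes all, VAQ nothing
  expect_equal(complementarity(eff_of(keys), eff_of(character(0))), 100)
  # disjoint halves
  expect_equal(complementarity(eff_of(keys[1:2]), eff_of(keys[3:4])), 100)
  # the SAME half twice still sums to 100: the raw sum is blind to
  # double-removal (the union-based coverage in evaluate_filters is not)
  expect_equal(complementarity(eff_of(keys[1:2]), eff_of(keys[1:2])), 100)
})

test_that("cohort_summary reduces to the sample stats", {
  one <- pair_overlap(pair_calls(1:4, c(1, 2, 11, 12)))
  s1 <- cohort_summary(one)
  row <- s1[s1$metric == "n_wgs", ]
  expect_equal(row$mean, row$min)
  expect_equal(row$mean, row$max)
  expect_equal(row$stdev, 0)

  two <- dplyr::bind_rows(
    pair_overlap(pair_calls(1:100, 1:50, sample_id = "a")),
    pair_overlap(pair_calls(1:300, 1:50, sample_id = "b")))
  s2 <- cohort_summary(two)
  row <- s2[s2$metric == "n_wgs", ]
  expect_equal(c(row$mean, row$min, row$max), c(200, 100, 300))

  # 90 calls over 30 Mbp = 3 mutations per Mbp
  f <- pair_overlap(pair_calls(1:90, 1:90))
  s3 <- cohort_summary(f, genome_size_mbp = 30)
  expect_equal(s3$mean[s3$metric == "mut_per_mbp_wgs"], 3)

  expect_error(cohort_summary(one[0, ]), "no pairs")
})
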