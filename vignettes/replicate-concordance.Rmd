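---
title: "Measuring SNV-calling concordance between technical replicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring SNV-calling concordance between technical replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvconcord)
```

## The model

A tumor specimen sequenced twice gives two somatic call sets for the same
underlying mutations. The package's working model is simple set algebra on
call identities: a call is the quadruple `(chrom, pos, ref, alt)`, two
calls are the same mutation iff all four fields agree, and the pair of
replicates is summarized by the overlap `|A ∩ B|`, the per-side percent
overlaps `100·|A ∩ B|/|A|`, and the Jaccard coefficient
`J = |A ∩ B|/|A ∪ B|`. The interpretive assumption is that a fixed somatic
mutation is expected in both replicates, while sequencing, amplification
and alignment errors are replicate-specific; the overlap is therefore
enriched for true positives and the symmetric difference for false ones.
The assumption is imperfect — subclonal (polymorphic) mutations can
legitimately appear in only one replicate, and a degraded specimen can put
the *same* artifact in both — so concordance is a confidence measure, not
a validation.

Two design choices follow from the identity definition. First, matching is
allele-aware: `chr1:100 A>G` and `chr1:100 A>T` are different mutations,
and no position-only comparison mode is offered for replicate overlap
(position-only matching exists only for dbSNP lookup, where site lists
often carry no allele). Second, chromosome names are compared as exact
strings; an explicit `chrom_normalization` switch in `vcf_dialect()`
strips or adds the `chr` prefix at parse time, because silently renaming
contigs corrupts overlap counts.

## Filters and their boundary semantics

Each of the eight filters is a pure partition of one call set into
`removed` and `kept`. They run *independently*: every filter judges the
original, unfiltered call set (single-pass semantics), so the combined
removal is the union of per-filter removals and the result does not depend
on filter order. One consequence worth stating: the SNV-proximity filter
counts neighbors among *all* putative calls, including calls another
filter would remove, and it is deliberately not idempotent — re-running it
on its own kept set can remove more, because a survivor's only close
neighbor may itself have been removed. The implementation therefore always
works single-pass, and a test pins its output to an all-pairs brute-force
oracle.

Boundary conventions are the most drift-prone part of such filters, so
they are fixed once, package-wide:

* score thresholds (`GATK` on the calling quality, `SS` on the
  SomaticScore, `VAQ` on the Variant Allele Quality; default 40 each)
  remove values **strictly below** the threshold — exactly 40 is kept;
* the proximity window (default 10 bp) is **inclusive** — distance 10
  removes, 11 keeps; the indel distance is 0 inside the affected span
  `[pos, pos + nchar(ref) − 1]` and otherwise the distance to the nearest
  span end (span, not anchor position, because the bases an indel disturbs
  are the whole reference stretch it rewrites);
* the alternate-allele fraction filter (default 10%) removes fractions
  **strictly below** the minimum — exactly 10% is kept.

Missing fields are never imputed: by default a call whose required field
is absent is kept and counted (`n_missing_field`), with a strict mode that
errors instead. Dropping on missingness would conflate data hygiene with
filter action. Calls with zero or missing depth are likewise kept by the
fraction filter and counted.

The quality-score filters are exposed as ordinary filters even though in
practice they are often applied upstream by the caller's command line;
exposing them lets their individual action be studied with the same
machinery as every other filter.

## Pair and filter statistics

`filter_effect()` asks where a filter's removals fall. A key in the
overlap counts as "removed from the overlap" if the filter removed it in
*either* replicate — once absent from one kept set it has left the
overlap. This reading makes the reported `jaccard_after` identical to
recomputing the overlap on the two kept sets (a cross-checked invariant).
Undefined ratios are explicit `NA`s, never sentinel values: percent of
overlap removed is undefined when the overlap is empty, and the
difference-over-overlap ratio is undefined when nothing was removed from
the overlap (typical for the alternate-allele-fraction filter, which
removes very little).

Two useful monotonicity facts follow from `J = o/(a + b − o)` and are
asserted property-style in the tests: removing a key present in both
replicates never increases the Jaccard, and removing a key present in
exactly one never decreases it.

The LOH/VAQ complementarity table reports both the raw sum of the two
filters' percent-overlap removals *and* the union-based coverage
`100·|(removed_LOH ∪ removed_VAQ) ∩ overlap|/|overlap|`. The raw sum is
the classic presentation but is blind to double-removal (two filters
removing the same half of the overlap also sum to 100%); the union
coverage disambiguates.

`spearman_cor()` reports ρ as the Pearson correlation of average ranks,
the S statistic as the literal sum of squared rank differences, and a
two-sided p-value from the large-sample t approximation
`t = ρ√((n−2)/(1−ρ²))`. At cohort sizes of tens of pairs the t
approximation is standard; with ties, S = Σd² differs slightly from the
value `stats::cor.test()` back-derives from ρ, and the literal Σd² is
reported because that is how such cohorts conventionally quote it. A test
verifies exact agreement with `cor.test(exact = FALSE)` on tie-free data
and with an explicit rank-then-Pearson oracle everywhere.

## The synthetic cohort generator

`simulate_pair()`/`simulate_cohort()` emulate the statistical structure
the analysis assumes, with per-call ground truth that real cohorts lack:

* per-patient true mutation count drawn log-uniformly over 100–5000,
  reproducing order-of-magnitude burden variation across tumors;
* each true mutation detected independently per replicate with probability
  `detect_prob = 0.66` (detection below 1 stands in for subclonal loss and
  coverage fluctuations; `detect_prob = 1` recovers the idealized
  fixed-mutation model);
* replicate-specific false calls with Poisson counts, mean 400 (WGS) vs
  1100 (WGA) — the amplified replicate's error excess;
* planted artifact classes among false calls: 5% on generated dbSNP sites,
  8% split between clusters near another false call and positions within
  the proximity window of an indel — so the dbSNP and proximity filters
  have true signal to find by construction;
* LOH status assigned truth-blind at rate `frac_loh = 0.35`, reflecting
  that LOH labels in this setting are not error-specific, without
  asserting a mechanism;
* quality scores for true calls from N(120, 25) and false calls from
  N(45, 20), floored at 0; depths Poisson(30) with beta alternate-allele
  fractions centered near 0.45 (true) and 0.15 (false);
* a synthetic genome of 3 chromosomes × 10 Mbp, 5000 dbSNP sites and 100
  indels per cohort (sizes chosen once as a desk-scale stand-in for a
  genome-wide site list: dense enough that planted classes are non-empty
  at the default error rates, sparse enough that chance coincidence stays
  negligible).

All randomness flows from one integer seed; per-patient streams are
derived from it, and cohorts are written with canonical number formatting,
so identical seeds give byte-identical VCFs, truth tables and report
tables. Everything the generator writes is labelled synthetic in its
filename.

The closed form
`expected_overlap_fraction(n, d, e) = 100·n·d²/(n·d + e)` gives the
expected percent overlap under the generator's independence assumptions
and serves as the parameter-recovery oracle: on a 20-patient cohort at
defaults the observed mean percent overlap must sit within three
Monte-Carlo standard errors of it.

### What the generator does and does not show

Passing tests on synthetic cohorts demonstrate that the set algebra,
filter semantics and pipeline plumbing are correct, and that filters
planted with signal (dbSNP, proximity) are recovered as
error-discriminating while the truth-blind LOH filter removes true calls
at its configured rate. They do **not** show that real tumor data behaves
this way: the generator has no sequence context, no mutational signatures,
no subclonal structure, and its quality-score distributions are
placeholders — in particular, with true-call scores centered at 120 the
VAQ filter removes almost none of the synthetic overlap, whereas on real
cohorts low-VAQ calls can be abundant among concordant calls. Similarly,
because the false-call means are fixed while the true burden varies, the
expected percent overlap *increases* with mutation burden in the
generator; the flat burden-vs-overlap relationship reported for real
tumors is an empirical property of data, not of this model, and is
deliberately not asserted as a package invariant.

## Numerical and engineering choices

* All internal coordinates are 1-based (VCF convention); BED input is
  converted from 0-based half-open at the boundary, and the conversion is
  tested against literal per-base expansion.
* Proximity filters use interval overlap machinery (GenomicRanges) with a
  candidate superset (`maxgap`) followed by an exact distance check, and
  are pinned to an O(n²) all-pairs oracle in tests.
* Multi-allelic VCF records are decomposed at parse time into one call per
  alternate allele; the model layer only ever sees biallelic SNVs. Records
  whose REF or ALT spans more than one base become indel records.
* The tumor sample defaults to the last VCF sample column; the dialect
  makes it explicit because reading the wrong column silently inverts
  depths.
* Report tables render doubles at six significant digits, which keeps
  regression comparisons byte-stable; run manifests record parameters,
  seed and md5 checksums but no paths or timestamps.
* Undefined statistics propagate as `NA` through tables and summaries.
* Default problem sizes (20-patient cohorts for parameter-recovery and
  truth-discrimination checks, 10 patients for end-to-end determinism,
  ≤200-call sets for oracle equivalence) were chosen as the smallest
  cohorts at which the Monte-Carlo bands are tight enough to be
  informative.

## Known limitations

* Concordance is computed between exactly two labelled replicates
  (WGS/WGA); k-replicate designs are out of scope.
* The dbSNP build, and whether its matching should be allele-aware, are
  configuration rather than opinion; defaults are allele-aware matching.
* `genome_size_mbp` (default 30, exome scale) is only a denominator for
  the mutations-per-Mbp summary; nothing else depends on it.
* The package consumes somatic VCFs; producing them (alignment,
  recalibration, calling) is explicitly not its job.
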