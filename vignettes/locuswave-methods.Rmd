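---
title: "Evaluating GWAS locus-nomination methods across study waves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating GWAS locus-nomination methods across study waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locuswave)
```

## The problem

Many methods promise to squeeze additional trait-associated loci out of a
genome-wide association study (GWAS) that is too small to detect them at the
conventional `p < 5e-8` threshold -- by reweighting p-values with functional
annotation, borrowing power across pleiotropic traits, or aggregating
evidence over eQTLs and genes. Whether those nominations are *real* can be
checked without any new data: apply the method to an early GWAS wave
("GWAS1") and ask how many of its nominations become genome-wide significant
in a later, larger wave of the same trait ("GWAS2"), after discarding
everything GWAS1 had already found. The later wave is the gold standard.

`locuswave` implements that evaluation end to end: locus definition from
summary statistics, earlier-wave exclusion, classification at the variant,
locus, or gene level, sensitivity (SN) / positive predictive value (PPV) /
F1 metrics, competition ranking across traits, and ensemble-intersection
matrices. It also ships the three nomination procedures simple enough to be
specified fully by thresholds -- a suggestive p-value band, per-category
annotation thresholds, and weighted-Bonferroni eQTL prioritisation -- plus a
synthetic two-wave simulator so the whole pipeline can be exercised and
tested offline.

Because true negatives are unknowable in this design (a variant
non-significant in both waves may simply be underpowered twice), the
framework deliberately avoids TN-based metrics such as specificity or AUC;
SN and PPV are each a proportion of a well-defined denominator.

## Locus definition

All coordinates are 1-based and intervals closed; the overlap of
`[a1, a2]` and `[b1, b2]` is `min(a2, b2) - max(a1, b1) + 1` bases. The
choice is fixed once and used everywhere, including the 250 kb
true-positive rule (compared with `>=`).

`define_loci()` turns summary statistics into significant loci by stepwise
windowing:

1. collect all variants with `p < 5e-8`;
2. take the remaining variant with the smallest p-value (ties broken by
   chromosome, then position, so the result is order-invariant), emit the
   window `[pos - 500 kb, pos + 500 kb]`, and remove every significant
   variant inside it;
3. repeat until no significant variant remains;
4. merge emitted windows that overlap by at least one base;
5. collapse chromosome-6 loci touching the extended HLA/MHC region
   (25,000,000-35,000,000) into a single locus, as the union of the fixed
   region with every locus touching it -- so a locus reaching past 35 Mb
   keeps its extension, and no captured variant is lost.

The output partitions the significant variants: each belongs to exactly one
locus, and loci never overlap within a chromosome. The same procedure
defines GWAS1 loci (for exclusion), GWAS2 loci (the gold standard), and --
via `windows_from_points()` -- nominated loci, so every method is measured
with the same ruler.

Windows are never clipped at chromosome ends or centromeres; a gene-midpoint
locus can legitimately start at a negative coordinate. Only the BED exporter
clamps at zero (and says so).

```{r loci-example}
rec <- data.frame(chrom = "1", pos = c(1e6, 1.4e6, 2.1e6),
                  pvalue = c(1e-10, 1e-9, 1e-9))
define_loci(rec)[, 1:7]
```

## Exclusion of earlier-wave hits

A method must not get credit for re-discovering what GWAS1 already found.
`exclude_overlapping()` removes from the GWAS2 loci any locus overlapping a
GWAS1 locus by *any* amount (one base suffices); what remains is the gold
standard. On the nomination side, variant-level nominations inside a GWAS1
locus are dropped (`exclude_points_in_loci()`), and gene-level nominations
are dropped when the gene midpoint lies within 500 kb of a GWAS1 locus
(`exclude_genes_near_loci()`). All methods pass through the identical
filters; the nomination procedures themselves exclude nothing.

## Classification and metrics

At locus level (`classify_locus_level()`), a nominated locus is a true
positive when it overlaps at least one gold locus by 250 kb or more, and a
false positive otherwise; a gold locus is covered when some nominated locus
overlaps it by that amount, and a false negative otherwise. PPV is the
proportion of nominated loci confirmed; SN is the proportion of gold loci
covered. The two numerators are carried separately because one wide
nominated locus can cover two gold loci: it then counts once toward PPV
while both gold loci count toward SN, keeping each metric a true proportion
of its own denominator. F1 is the harmonic mean, 0 when both inputs are 0,
undefined when either is.

Variant-level classification (`classify_variant_level()`) requires exact
(chrom, pos) matches. Gene-level classification (`classify_gene_level()`)
supports three strategies: direct key matching (Ensembl id or symbol)
against the Bonferroni-significant gold gene set; annotated gene boundaries
as loci with a 2,500-base overlap rule; or midpoint +/- 500 kb windows with
the 250 kb rule. In the locus modes, overlapping gene windows are merged
first to avoid double counting.

The 250 kb requirement is a tunable: `overlap_sensitivity_sweep()` re-runs
the classification at 1 base, 250 kb, 500 kb, and 750 kb, and the
true-positive count is provably non-increasing along that grid.

## The built-in nomination procedures

**Suggestive band.** Variants with `5e-8 <= p < 1e-5`. The band and the
genome-wide significant set are disjoint and together exactly cover
`{p < 1e-5}` -- a property the test suite asserts rather than assumes.

**Annotation-category thresholds.** Each variant carries one of four impact
categories with its own threshold: loss-of-function `5.5e-7`, moderate
`1.1e-7`, low `1.0e-8`, other `1.7e-9`. Unannotated variants fall into
"other", the catch-all and most stringent category -- the conservative
reading of a classification whose fourth level is defined by exclusion.

**Weighted-Bonferroni eQTL prioritisation.** Each of the M variants gets a
raw weight: `sqrt(-log10(p_eQTL))` for eSNPs and 1 otherwise (general
mode), or a single configurable ratio for eSNPs (binary mode). Weights are
normalized to mean 1 over all M variants and applied as
`p_w = min(1, p / w)`; significance is `p_w < 5e-8`. Mean-1 normalization
with division of p-values is the standard weighted-Bonferroni convention:
it leaves the family-wise error budget, and hence the expected null
nomination count `M * 5e-8`, unchanged -- a calibration the acceptance
suite verifies by simulation at M = 10^6. The closed-form optimal binary
weight (a function of the error target, power target, M, and the eSNP
fraction) is deliberately not hard-coded; `binary_ratio` stays explicit and
the nominal `alpha = 0.05` / `power = 0.6` targets are recorded in the
configuration. Exclusion of already-significant variants is left to the
evaluation stage by default (`novel_only = FALSE`) so the procedure is
filtered exactly like every other method.

Generic machinery: `bonferroni_significant()` (threshold `alpha/n` on the
valid p-values) and `fdr_significant()` (Benjamini-Hochberg step-up,
`q < 0.05`). BH is used rather than a local-FDR estimator: local FDR
requires a density estimate with tuning choices that cannot be pinned down
reproducibly, while BH is exact, assumption-light, and always yields a
superset of the Bonferroni calls at the same level -- the property tests
rely on.

## Ranking methods across traits

For each trait, each method carries its best PPV (over any annotation
database options) into `rank_methods()`: rank = number of methods with PPV
greater than or equal to one's own, so ties share the *lowest* rank of
their block (competition / "Olympic" ranking), and methods that nominated
nothing rank 18 -- strictly below a PPV of exactly zero. `median_rank()`
aggregates across traits with the middle order statistic (lower middle for
even counts, keeping ranks integral).

The package ships a published 18-method x 5-trait benchmark table
(`published_method_ranking()`) as a fixture. Feeding its printed best-PPV
columns through `rank_methods()` reproduces 88 of the 90 printed rank
cells and all 18 printed median ranks. The two remaining cells (the
bipolar-disorder column's Sherlock and fgwas entries) are mutually swapped
in the printed table itself: no ranking that is monotone in the printed
PPVs can place PPV 0.182 below PPV 0.143, so the discrepancy is attributed
to a typesetting transposition in the source table and left as a recorded
failure rather than special-cased. A companion "median rank excluding one
trait" column printed in the same table is internally inconsistent under
every median convention and is not emulated.

SN/PPV scatter reporting assigns quadrants with strict boundaries
(`quadrant_assign()`): quadrant I means both above 0.5; points exactly on
0.5 count as low. Methods with zero nominations appear in the ranking
(rank 18) but not in the scatter.

## Ensemble intersection matrices

`build_ensemble_matrix()` asks whether loci nominated by many methods are
more often real. Methods are processed from most to fewest nominated loci
(ties by name); the first seeds the matrix; later methods add only loci not
already overlapping a matrix locus by 250 kb; and each added locus is
tested against *every* method's loci to fill its row -- including methods
processed earlier, so membership does not depend on processing order. Rows
therefore never overlap each other by 250 kb or more, each row has at least
one member, and the per-method counts of newly contributed loci sum to the
row count. `ppv_by_support()` then reports PPV both cumulatively (loci
nominated by at least k methods -- the reading that supports a "minimum
number of methods" statement) and exactly at k (which exposes
non-monotonicity).

With `min_overlap = Inf` deduplication is impossible and the matrix
degenerates to the concatenation of all methods' loci with singleton
membership -- a useful boundary case for testing.

## The synthetic two-wave generator

`simulate_two_wave_gwas()` emulates exactly the features the framework
consumes and nothing more:

* one shared variant set across both waves, positions uniform per
  chromosome (default: two 50 Mb chromosomes, 20,000 variants -- compact
  enough for fast tests, large enough for multi-locus structure);
* planted causal leads kept more than 2 x 500 kb apart so planted loci
  cannot merge and remain unambiguous truth;
* a deterministic shared signal `mu = effect_scale * exp(-d / decay_bp)`
  for variants within `3 * decay_bp` of a lead (default decay 50 kb),
  scaled per wave by `sqrt(n_wave / n1)`; independent standard-normal noise
  per wave; two-sided normal p-values floored at `7.41e-323`, the smallest
  value that survives a text round trip through double precision;
* defaults `n1 = 20,000`, `n2 = 80,000`, `effect_scale = 4.5`: the wave-1
  lead z-score sits just below the significance threshold (detected only
  with favourable noise) while the wave-2 z-score of ~9 is detected
  essentially always -- so wave 2 recovers a superset of wave-1 loci and a
  non-trivial set of novel gold loci exists, mirroring the two-wave design
  the framework is built for.

The generator deliberately omits linkage disequilibrium, realistic allele
frequencies, and case-control liability: the evaluation framework consumes
only positions and p-values, so distance-decayed shared signal is
sufficient to exercise locus collapsing, and nothing downstream would see
the difference. Passing tests on this generator therefore validate the
*evaluation arithmetic*, not any claim about how real functional-weighting
methods behave on real LD structure.

Randomness follows a one-root-seed contract: the root seed is expanded once
into named per-stage seeds (positions, leads, per-wave noise, annotations,
genes), so adding a stage never perturbs earlier draws and every output is
byte-identical under a repeated seed.

`make_nominations()` builds nomination sets of exactly known composition:
`n_tp` points at the leads of gold loci chosen so their windows cannot
merge or cross-cover, and `n_fp` decoys rejection-sampled to keep their
windows below the overlap rule against every gold, avoided, and sibling
locus. The construction is verified internally by running the classifier;
an over-crowded genome raises an error instead of silently shifting counts.
This is what makes exact end-to-end assertions like
`SN = n_tp / |gold|` possible.

## Numerical and degenerate-input choices

* P-values of zero (underflow in text files) are floored at `7.41e-323`,
  idempotently; rows with NA, negative, or `> 1` p-values are dropped with
  a count rather than an error, since real summary-statistics files are
  dirty.
* Duplicate positions keep the smallest p-value; exact p ties break by
  lexicographic rsid, then first occurrence -- determinism over elegance.
* Chromosome labels are normalized by stripping a leading `chr`; builds are
  never converted (inputs are assumed on one build per run).
* Empty inputs flow through: an empty significant set yields an empty locus
  list, a method with zero nominations gets SN 0 and undefined PPV, and
  undefined metrics propagate as `NA` rather than 0.
* `rank_methods()` refuses duplicated method names; `median_rank()` of an
  empty vector is `NA`.

## Problem sizes used in the checks

The shipped verification suite runs entirely from code: oracle equivalence
compares the stepwise algorithms against quadratic brute-force scans on
1,000 random instances (up to 200 variants or 50 loci each); planted-truth
recovery runs 100 seeded compositions through the full pipeline; null
calibration simulates 20 null GWAS of 10^6 variants each and checks both
the genome-wide significant count and the weighted-eQTL nomination count
against their binomial expectations within three standard errors. These
sizes were chosen to make the binomial expectations sharp enough to detect
a miscalibrated tail while keeping the whole suite comfortably
interactive.

## Known limitations

* No LD-aware clumping or conditional analysis: loci are distance-based by
  design, and the framework cannot say whether a nomination tags the causal
  variant.
* The 14 external functional-weighting tools are consumed as nomination
  files, never re-implemented; gene-based association p-values are likewise
  inputs.
* Genome-build liftover is out of scope.
* The gold-standard design equates "significant in the later wave" with
  truth; loci that even the later wave is underpowered to detect are
  invisible to SN and can depress PPV.
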