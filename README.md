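# locuswave

Wave-based evaluation of GWAS locus-nomination methods.

## The problem

Functional-weighting methods — annotation scores, pleiotropy models,
eQTL-based prioritisation — promise to nominate trait-associated loci that a
genome-wide association study (GWAS) is too small to detect at
`p < 5×10⁻⁸`. Are the nominations real? When a later, larger GWAS wave of
the same trait exists, it answers the question without new data: apply a
method to the early wave (GWAS1), discard everything GWAS1 had already
found, and check the surviving nominations against the loci that reach
genome-wide significance for the first time in the later wave (GWAS2, the
gold standard).

`locuswave` implements that benchmarking framework for R users working with
summary statistics:

* **Locus definition** (`define_loci`): stepwise ±500 kb windows around
  successive smallest-p lead variants, merged on any overlap, with the
  extended HLA/MHC region (chr6:25–35 Mb) collapsed into a single locus.
* **Earlier-wave exclusion** (`exclude_overlapping`,
  `exclude_points_in_loci`, `exclude_genes_near_loci`): any degree of
  overlap with a GWAS1 locus removes a gold locus; nominated variants and
  genes are filtered identically for every method.
* **Classification & metrics** (`classify_variant_level`,
  `classify_locus_level`, `classify_gene_level`): a nominated locus is a
  true positive when it overlaps a gold locus by ≥250 kb. Sensitivity
  SN = covered gold loci / all gold loci; positive predictive value
  PPV = confirmed nominations / all nominations; F1 = harmonic mean.
  True negatives are undefined in this design and never used.
* **Ranking** (`rank_methods`, `median_rank`): competition ("Olympic")
  ranking of methods by best PPV per trait — ties share the lowest rank,
  methods nominating nothing rank below PPV = 0 — aggregated across traits
  by median rank.
* **Ensemble analysis** (`build_ensemble_matrix`, `ppv_by_support`):
  stepwise deduplicated loci × methods membership matrix (UpSet-style) and
  PPV stratified by the number of nominating methods.
* **Built-in nomination procedures** (`nominate_suggestive`,
  `nominate_sveinbjornsson`, `weighted_eqtl_nominate`,
  `bonferroni_significant`, `fdr_significant`): the suggestive band
  `5×10⁻⁸ ≤ p < 10⁻⁵`; four impact-category thresholds
  (5.5×10⁻⁷ / 1.1×10⁻⁷ / 1.0×10⁻⁸ / 1.7×10⁻⁹); weighted-Bonferroni eQTL
  prioritisation with mean-1 weights `w = √(−log₁₀ p_eQTL)` and
  `p_w = p/w < 5×10⁻⁸`; plus generic Bonferroni and Benjamini–Hochberg
  machinery.
* **Synthetic two-wave simulator** (`simulate_two_wave_gwas`,
  `make_nominations`, `simulate_annotations`, `simulate_gene_table`):
  planted causal loci with distance-decayed shared signal, wave-scaled by
  `√(n_wave/n1)`, and nomination sets of exactly known TP/FP composition —
  so the whole pipeline runs and is tested with no downloads.

External method outputs enter as plain files (`read_nominations`); the 14
published functional-weighting tools themselves are out of scope, as are
LD-aware clumping and genome-build liftover. See the methods vignette
(`vignettes/locuswave-methods.Rmd`) for the model, conventions, and design
rationale.

## Worked example

```r
library(locuswave)

cfg  <- sim_config(seed = 7)            # two 50 Mb chromosomes, 4 planted loci
sim  <- simulate_two_wave_gwas(cfg)     # n1 = 20k, n2 = 80k samples

gwas1_loci <- define_loci(sim$wave1)
gold <- exclude_overlapping(define_loci(sim$wave2), gwas1_loci, min_overlap = 1)
gold[, c("chrom", "start", "end", "lead_pos", "lead_p", "n_members")]
#>   chrom    start      end lead_pos       lead_p n_members
#> 1     1 28449216 29449216 28949216 2.501916e-22         6
#> 2     1 45696834 46696834 46196834 2.278534e-21        11

run <- run_full_evaluation(run_config(
  trait = "synthetic", wave1 = sim$wave1, wave2 = sim$wave2,
  nominations = list(nominate_suggestive(sim$wave1))))
run$metrics[, c("method", "n_nominated", "tp", "fp", "fn", "sn", "ppv", "f1", "quadrant")]
#>       method n_nominated tp fp fn sn ppv f1 quadrant
#> 1 suggestive           2  2  0  0  1   1  1        I
```

Wave 1 detects 2 of the 4 planted loci; the two loci novel to wave 2 form
the gold standard. Variants in wave 1's suggestive band cluster under the
two not-yet-significant planted leads, so after exclusion of wave-1 regions
the suggestive method nominates 2 merged loci, both confirmed: SN, PPV, and
F1 all equal 1 and the method lands in quadrant I (both metrics > 0.5). On
real traits the same machinery exposes the typical SN/PPV trade-off rather
than a perfect score.

Ranking works the same way on any best-PPV table. Using the shipped
published benchmark column for schizophrenia:

```r
pub <- published_method_ranking()
head(sort(rank_methods(pub$ppv[, "SCZ"], n_total = 18)), 8)
#>        MTAG       Jepeg       moloc       COLOC TWAS/FUSION      UTMOST
#>           2           2           3           4           6           6
#>  Suggestive      EUGENE
#>           7           8
```

MTAG and JEPEG tie at PPV 1.000 and both receive rank 2 — the competition
rule assigns tied methods the lowest rank of their block.

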