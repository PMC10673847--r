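test_that("variant-level classification requires exact position matches", {
  nom <- nomination_set("m", "variant", data.frame(chrom = "1", pos = 100))
  gold <- data.frame(chrom = "1", pos = 100, pvalue = 1e-9)
  r <- classify_variant_level(nom, gold)
  expect_equal(c(r$tp_nominated, r$fp, r$fn), c(1, 0, 0))
  expect_equal(c(r$sn, r$ppv), c(1, 1))

  off <- classify_variant_level(nom, data.frame(chrom = "1", pos = 101))
  expect_equal(c(off$tp_nominated, off$fp, off$fn), c(0, 1, 1))

  nom3 <- nomination_set("m", "variant",
                         data.frame(chrom = "1", pos = c(1, 2, 3)))
  gold4 <- data.frame(chrom = "1", pos = c(2, 3, 8, 9))
  r3 <- classify_variant_level(nom3, gold4)
  expect_equal(r3$sn, 0.5)
  expect_equal(r3$ppv, 2 / 3)

  glev <- nomination_set("m", "gene", data.frame(gene_id = "g"))
  expect_error(classify_variant_level(glev, gold), "variant")
})

test_that("locus-level classification applies the 250 kb overlap rule", {
  cfg <- eval_config()
  gold <- windows_from_points(data.frame(chrom = "1", pos = 5e6))
  near <- windows_from_points(data.frame(chrom = "1", pos = 5.3e6))
  expect_equal(overlap_length(near, gold), 700001)
  r <- classify_locus_level(near, gold, cfg)
  expect_equal(c(r$tp_nominated, r$gold_covered, r$fp, r$fn), c(1, 1, 0, 0))

  far <- windows_from_points(data.frame(chrom = "1", pos = 5.8e6))
  expect_equal(overlap_length(far, gold), 200001)
  r2 <- classify_locus_level(far, gold, cfg)
  expect_equal(c(r2$tp_nominated, r2$fp, r2$fn), c(0, 1, 1))
  expect_equal(r2$sn, 0)
  expect_equal(r2$ppv, 0)

  none <- classify_locus_level(gold[0, ], gold, cfg)
  expect_equal(none$sn, 0)
  expect_true(is.na(none$ppv))
})

test_that("one nominated locus covering two gold loci counts once toward PPV", {
  gold <- rbind(
    data.frame(chrom = "1", start = 1e6, end = 2e6),
    data.frame(chrom = "1", start = 2.4e6, end = 3.4e6)
  )
  wide <- data.frame(chrom = "1", start = 1.5e6, end = 2.9e6)
  r <- classify_locus_level(wide, gold, eval_config())
  expect_equal(r$tp_nominated, 1)
  expect_equal(r$gold_covered, 2)
  expect_equal(r$sn, 1)
  expect_equal(r$ppv, 1)
})

test_that("gene-level id matching uses the Bonferroni-significant gold set", {
  genes <- data.frame(
    gene_id = sprintf("ENSG%04d", 1:10),
    symbol = sprintf("G%d", 1:10), chrom = "1",
    start = (1:10) * 1e6, end = (1:10) * 1e6 + 50000,
    pvalue = c(1e-4, 2e-3, rep(0.3, 8))
  )
  gold_sig <- gold_significant_genes(genes)
  expect_equal(nrow(gold_sig), 2L) # threshold 0.05 / 10 = 5e-3
  expect_equal(attr(gold_sig, "threshold"), 0.005)

  nom <- nomination_set("m", "gene",
                        data.frame(gene_id = c("ENSG0001", "ENSG0005")))
  r <- classify_gene_level(nom, genes, eval_config())
  expect_equal(c(r$tp_nominated, r$fp, r$fn), c(1, 1, 1))

  sym <- nomination_set("m", "gene", data.frame(symbol = "G1"))
  expect_error(classify_gene_level(sym, genes, eval_config()), "symbol")
  cfg_sym <- eval_config(id_mode = "symbol")
  rs <- classify_gene_level(sym, genes, cfg_sym)
  expect_equal(rs$tp_nominated, 1)
})

test_that("gene-level locus modes merge overlapping gene windows first", {
  genes <- data.frame(
    gene_id = c("A", "B", "C"), symbol = c("A", "B", "C"), chrom = "1",
    start = c(1e6, 1.2e6, 9e6), end = c(1.1e6, 1.3e6, 9.1e6),
    pvalue = c(1e-6, 1e-6, 0.9)
  )
  nom <- nomination_set("m", "gene",
                        data.frame(gene_id = c("A", "B"), chrom = "1",
                                   start = c(1e6, 1.2e6),
                                   end = c(1.1e6, 1.3e6)))
  cfg <- eval_config(gene_locus_mode = "midpoint_flank")
  # midpoint windows of A and B overlap -> one merged nominated locus
  gold_loci <- windows_from_points(data.frame(chrom = "1", pos = 1.15e6))
  r <- classify_gene_level(nom, genes, cfg, gold_loci = gold_loci)
  expect_equal(r$tp_nominated + r$fp, 1)
  expect_equal(r$tp_nominated, 1)
})

test_that("gene boundary-mode classification agrees with a brute-force scan", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 60
    genes <- data.frame(
      gene_id = sprintf("ENSG%04d", 1:n), symbol = sprintf("G%d", 1:n),
      chrom = sample(c("1", "2"), n, replace = TRUE),
      start = sample.int(2e7, n)
    )
    genes$end <- genes$start + sample.int(3e5, n)
    genes$pvalue <- runif(n)
    genes$pvalue[sample.int(n, 8)] <- 1e-6
    nom_idx <- sample.int(n, 20)
    nom <- nomination_set("m", "gene", genes[nom_idx, ])
    cfg <- eval_config(gene_locus_mode = "boundaries")
    r <- classify_gene_level(nom, genes, cfg)

    gold_sig <- gold_significant_genes(genes)
    nom_loci <- merge_loci(gene_to_locus(genes[nom_idx, ], "boundaries"))
    gold_loci <- merge_loci(gene_to_locus(gold_sig, "boundaries"))
    o <- oracle_classify(nom_loci, gold_loci, 2500)
    expect_equal(r$tp_nominated, o$tp)
    expect_equal(r$fp, o$fp)
    expect_equal(r$gold_covered, o$gold_covered)
    expect_equal(r$fn, o$fn)
  }
})

test_that("midpoint proximity exclusion strips genes near earlier-wave loci", {
  loci <- data.frame(chrom = "1", start = 4.5e6, end = 5.5e6)
  genes <- data.frame(gene_id = c("near", "far"), chrom = "1",
                      start = c(5.9e6, 7e6), end = c(6.1e6, 7.2e6))
  out <- exclude_genes_near_loci(genes, loci)
  expect_equal(out$gene_id, "far") # midpoint 6e6 within 500 kb of locus end
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("F1 is the harmonic mean with guarded edge cases", {
  expect_equal(compute_f1(0.5, 0.5), 0.5)
  expect_equal(compute_f1(1, 0), 0)
  expect_equal(compute_f1(0.747, 0.25), 2 * 0.747 * 0.25 / (0.747 + 0.25))
  expect_true(is.na(compute_f1(NA, 0.5)))
  sn <- runif(50); ppv <- runif(50)
  f1 <- mapply(compute_f1, sn, ppv)
  expect_true(all(f1 <= pmax(sn, ppv) + 1e-12))
  expect_true(all(f1 <= 2 * pmin(sn, ppv) + 1e-12))
})

test_that("competition ranking assigns tied methods the lowest rank and NA last", {
  ppv <- c(a = 0.9, b = 0.5, c = 0.5, d = 0.1, e = NA)
  r <- rank_methods(ppv, n_total = 18)
  expect_equal(unname(r), c(1L, 3L, 3L, 4L, 18L))
  distinct <- c(x = 0.3, y = 0.2, z = 0.1)
  expect_equal(unname(rank_methods(distinct, 3)), 1:3)
  # zero PPV still outranks a missing PPV
  zero <- rank_methods(c(p = 0, q = NA), n_total = 18)
  expect_equal(unname(zero), c(1L, 18L))
  expect_error(rank_methods(c(a = 1, a = 2)), "named")
})

test_that("median rank takes the middle (or lower middle) order statistic", {
  expect_equal(median_rank(c(3, 18, 6, 4, 8)), 6)
  expect_equal(median_rank(c(6, 9, 7, 10, 9)), 9)
  expect_equal(median_rank(c(5, 5)), 5)
  expect_equal(median_rank(c(2, 4)), 2)
  expect_true(is.na(median_rank(integer(0))))
})

test_that("overlap sweep is monotone and rejects non-positive overlaps", {
  gold <- windows_from_points(data.frame(chrom = "1", pos = c(5e6, 12e6)))
  # 300 kb from the first gold lead (700,001 b overlap), 800 kb from the
  # second (200,001 b), plus one clear decoy
  nom <- windows_from_points(data.frame(chrom = "1", pos = c(5.3e6, 12.8e6,
                                                             30e6)))
  sweep <- overlap_sensitivity_sweep(nom, gold)
  expect_equal(sweep$min_overlap, c(1, 250000, 500000, 750000))
  expect_true(all(diff(sweep$tp) <= 0))
  expect_true(all(diff(sweep$gold_covered) <= 0))
  expect_equal(sweep$tp, c(2, 1, 1, 0))
  expect_error(overlap_sensitivity_sweep(nom, gold, overlaps = c(0, 1)),
               "positive")
})
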