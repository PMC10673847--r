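test_that("stepwise locus definition matches hand-computed windows", {
  expect_equal(nrow(define_loci(
    data.frame(chrom = "1", pos = 1e6, pvalue = 1e-6))), 0L)

  one <- define_loci(data.frame(chrom = "1", pos = 1e6, pvalue = 1e-9))
  expect_equal(one$start, 5e5)
  expect_equal(one$end, 1.5e6)
  expect_equal(one$lead_pos, 1e6)

  rec <- data.frame(chrom = "1", pos = c(1e6, 1.4e6, 2.1e6),
                    pvalue = c(1e-10, 1e-9, 1e-9))
  loci <- define_loci(rec)
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$start, c(5e5, 1.6e6))
  expect_equal(loci$end, c(1.5e6, 2.6e6))
  expect_equal(loci$n_members, c(2L, 1L))
  expect_equal(loci$members[[1]], c(1e6, 1.4e6))
})

test_that("chromosome-6 loci collapse into the extended HLA region", {
  loci <- define_loci(data.frame(chrom = "6", pos = 26e6, pvalue = 1e-12))
  expect_equal(nrow(loci), 1L)
  expect_true(loci$is_hla)
  expect_true(loci$start <= 25e6 && loci$end >= 35e6)

  # a locus extending past the fixed bounds keeps its extension
  far <- define_loci(data.frame(chrom = "6", pos = c(26e6, 35.2e6),
                                pvalue = c(1e-12, 1e-9)))
  expect_equal(nrow(far), 1L)
  expect_equal(far$end, 35.7e6)
  expect_equal(far$start, 25e6)
  expect_equal(far$n_members, 2L)

  # chr6 loci clear of the region are untouched
  clear <- define_loci(data.frame(chrom = "6", pos = 50e6, pvalue = 1e-9))
  expect_false(clear$is_hla)
})

test_that("every significant variant lands in exactly one locus and loci are disjoint", {
  for (seed in 1:20) {
    rec <- random_records(150, seed)
    loci <- define_loci(rec)
    sig <- rec[rec$pvalue < 5e-8, ]
    counts <- vapply(seq_len(nrow(sig)), function(i) {
      sum(loci$chrom == sig$chrom[i] & loci$start <= sig$pos[i] &
            loci$end >= sig$pos[i])
    }, numeric(1))
    expect_true(all(counts == 1))
    if (nrow(loci) > 1) {
      for (i in seq_len(nrow(loci) - 1)) {
        for (j in (i + 1):nrow(loci)) {
          expect_equal(overlap_length(loci[i, ], loci[j, ]), 0)
        }
      }
    }
  }
})

test_that("locus definition is invariant to input record order", {
  rec <- random_records(120, 7)
  loci_a <- define_loci(rec)
  set.seed(99)
  loci_b <- define_loci(rec[sample.int(nrow(rec)), ])
  expect_equal(loci_a[, c("chrom", "start", "end")],
               loci_b[, c("chrom", "start", "end")])
})

test_that("raising the significance threshold never shrinks covered bases", {
  rec <- random_records(200, 11, p_sig = 0.5)
  covered <- function(thr) {
    loci <- define_loci(rec, locus_config(sig_threshold = thr))
    if (nrow(loci) == 0) 0 else sum(loci$end - loci$start + 1)
  }
  cov <- vapply(c(1e-12, 1e-10, 5e-8, 1e-6), covered, numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("point windows merge on >= 1 base overlap, never across chromosomes", {
  merged <- windows_from_points(data.frame(chrom = "2", pos = c(1e6, 1.9e6)))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 5e5)
  expect_equal(merged$end, 2.4e6)

  apart <- windows_from_points(data.frame(chrom = c("1", "2"),
                                          pos = c(1e6, 1e6)))
  expect_equal(nrow(apart), 2L)

  single <- windows_from_points(data.frame(chrom = "1", pos = 1e7))
  expect_equal(single$end - single$start + 1, 1000001)

  withp <- windows_from_points(data.frame(chrom = "2", pos = c(1e6, 1.9e6),
                                          pvalue = c(1e-6, 1e-9)))
  expect_equal(withp$lead_pos, 1.9e6)
  expect_equal(withp$lead_p, 1e-9)
})

test_that("overlap length uses closed-interval arithmetic", {
  w <- windows_from_points(data.frame(chrom = "1", pos = 1e6))
  expect_equal(overlap_length(w, w), 1000001)
  a <- data.frame(chrom = "1", start = 1, end = 1e6)
  b <- data.frame(chrom = "1", start = 750001, end = 2e6)
  expect_equal(overlap_length(a, b), 250000)
  expect_equal(overlap_length(a, data.frame(chrom = "2", start = 1, end = 10)), 0)
  expect_equal(overlap_length(data.frame(chrom = "1", start = 1, end = 5),
                              data.frame(chrom = "1", start = 5, end = 9)), 1)
})

test_that("exclusion removes loci with any overlap at the default threshold", {
  excl <- data.frame(chrom = "1", start = 1e6, end = 2e6)
  onebase <- data.frame(chrom = "1", start = 2e6, end = 3e6) # shares 1 base
  out <- exclude_overlapping(onebase, excl, min_overlap = 1)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "n_removed"), 1L)

  disjoint <- data.frame(chrom = "1", start = 5e6, end = 6e6)
  expect_equal(nrow(exclude_overlapping(disjoint, excl)), 1L)

  targets <- data.frame(chrom = "1", start = c(1.5e6, 5e6, 8e6),
                        end = c(2.5e6, 6e6, 9e6))
  expect_equal(nrow(exclude_overlapping(targets, excl)), 2L)

  # self-exclusion empties any set
  loci <- random_loci(10, 3)
  expect_equal(nrow(exclude_overlapping(loci, loci, 1)), 0L)
})

test_that("points inside earlier-wave loci are removed", {
  loci <- windows_from_points(data.frame(chrom = "1", pos = 1e6,
                                         pvalue = 1e-9))
  pts <- data.frame(chrom = "1", pos = c(1e6, 1.5e6, 1500001, 2100001))
  out <- exclude_points_in_loci(pts, loci)
  expect_equal(out$pos, c(1500001, 2100001)) # boundary inclusive
  expect_equal(attr(out, "n_removed"), 2L)
  expect_identical(exclude_points_in_loci(pts, merge_loci(windows_from_points(
    data.frame(chrom = character(0), pos = numeric(0)))))$pos, pts$pos)
})

test_that("gene loci honour boundary and midpoint modes without clipping", {
  g <- data.frame(gene_id = "ENSG0001", chrom = "1",
                  start = 100000, end = 200000)
  mid <- gene_to_locus(g, "midpoint_flank")
  expect_equal(mid$start, -350000) # unclipped below 1
  expect_equal(mid$end, 650000)
  bound <- gene_to_locus(g, "boundaries")
  expect_equal(c(bound$start, bound$end), c(100000, 200000))
  zero <- gene_to_locus(data.frame(gene_id = "g", chrom = "1",
                                   start = 5e6, end = 5e6), "midpoint_flank")
  expect_equal(zero$end - zero$start + 1, 1000001)
})
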