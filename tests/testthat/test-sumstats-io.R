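write_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

test_that("summary statistics parse, drop dirty rows, and sort by position", {
  path <- write_tsv(c("CHR\tPOS\tSNP\tP",
                      "2\t500\trs3\t0.01",
                      "1\t900\trs2\t0.20",
                      "1\t100\trs1\t0.05"))
  rec <- read_sumstats(path, sumstats_dialect(rsid = "SNP"))
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$chrom, c("1", "1", "2"))
  expect_equal(rec$pos, c(100, 900, 500))
  expect_equal(attr(rec, "n_dropped"), 0L)

  dirty <- write_tsv(c("CHR\tPOS\tSNP\tP",
                       "1\t100\trs1\t0.05",
                       "1\t200\trs2\tNA",
                       "1\t300\trs3\t1.5",
                       "1\t400\trs4\t-0.1",
                       "chrX\t500\trs5\t0.2"))
  rec <- suppressMessages(read_sumstats(dirty, sumstats_dialect(rsid = "SNP")))
  expect_equal(nrow(rec), 2L)
  expect_equal(attr(rec, "n_dropped"), 3L)
  expect_equal(rec$chrom, c("1", "X")) # "chr" prefix stripped

  nopos <- write_tsv(c("CHR\tSNP\tP", "1\trs1\t0.05"))
  expect_error(read_sumstats(nopos), "pos")
})

test_that("p-value truncation floors underflowed values and is idempotent", {
  rec <- data.frame(chrom = "1", pos = 1:4,
                    pvalue = c(0, 1e-330, 1e-300, 0.5))
  out <- truncate_pvalues(rec)
  expect_equal(out$pvalue, c(7.41e-323, 7.41e-323, 1e-300, 0.5))
  expect_identical(truncate_pvalues(out), out)
  expect_true(all(out$pvalue > 0))
})

test_that("positional dedup keeps the smallest p, breaking ties by rsid", {
  rec <- data.frame(chrom = c("1", "1", "1"), pos = c(100, 100, 200),
                    rsid = c("rs9", "rs5", "rs1"),
                    pvalue = c(0.01, 0.002, 0.5))
  out <- dedupe_by_position(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$pvalue[out$pos == 100], 0.002)

  tie <- data.frame(chrom = "1", pos = c(100, 100),
                    rsid = c("rs2", "rs1"), pvalue = c(0.01, 0.01))
  expect_equal(dedupe_by_position(tie)$rsid, "rs1")

  expect_identical(dedupe_by_position(out), out) # idempotent
  nodup <- data.frame(chrom = "1", pos = c(1, 2), rsid = c("a", "b"),
                      pvalue = c(0.1, 0.2))
  expect_equal(dedupe_by_position(nodup)$pos, c(1, 2))
})

test_that("field-validity filtering counts retained records", {
  rec <- data.frame(chrom = "1", pos = 1:5,
                    rsid = c("rs1", ".", "rs3", "rs4", "rs5"),
                    freq = c(0.1, 0.2, NA, 0.4, NA),
                    effect = c(1, 2, 3, NA, 5),
                    pvalue = 0.5)
  expect_equal(nrow(filter_valid(rec, "rsid")), 4L)
  expect_equal(nrow(filter_valid(rec, c("rsid", "freq"))), 2L)
  expect_equal(nrow(filter_valid(rec, "freq")), 3L) # two records lack freq
  expect_identical(filter_valid(rec)[, names(rec)], rec)
  expect_equal(attr(filter_valid(rec, "effect"), "n_retained"), 4L)
})

test_that("gene tables parse with midpoints and reject inverted boundaries", {
  path <- write_tsv(c("GENE\tCHR\tSTART\tEND\tSYMBOL\tP",
                      "ENSG0001\tchr1\t100000\t200000\tAAA\t1e-7",
                      "ENSG0002\t1\t900\t100\tBBB\t0.5",
                      "ENSG0003\t2\t500\t500\tCCC\tNA"))
  genes <- suppressWarnings(
    read_gene_table(path, gene_dialect(symbol = "SYMBOL", pvalue = "P"))
  )
  expect_equal(nrow(genes), 2L)
  expect_equal(attr(genes, "n_dropped"), 1L)
  expect_equal(genes$midpoint[genes$gene_id == "ENSG0001"], 150000)
  expect_true(is.na(genes$pvalue[genes$gene_id == "ENSG0003"]))
  expect_equal(genes$chrom[1], "1")
})

test_that("nomination files load at each level and empty sets are valid", {
  vpath <- write_tsv(c("CHR\tPOS", paste(1, (1:10) * 1000, sep = "\t")))
  nom <- read_nominations(vpath, "variant", method = "toy")
  expect_s3_class(nom, "nomination_set")
  expect_equal(nom$level, "variant")
  expect_equal(nrow(nom$items), 10L)
  expect_equal(nom$method, "toy")

  gpath <- write_tsv(c("SYMBOL", "AAA", "BBB"))
  gnom <- read_nominations(gpath, "gene", method = "sym_only")
  expect_true(all(is.na(gnom$items$gene_id)))
  expect_equal(gnom$items$symbol, c("AAA", "BBB"))

  epath <- write_tsv("CHR\tPOS")
  enom <- read_nominations(epath, "variant")
  expect_equal(nrow(enom$items), 0L)
})

test_that("summary-statistics round trip preserves chrom, pos, pvalue exactly", {
  rec <- data.frame(chrom = c("1", "2"), pos = c(123456789, 42),
                    rsid = c("rs1", "rs2"), a1 = "A", a2 = "G",
                    freq = c(0.123456789, 0.5), effect = c(-1.5, 2.25),
                    pvalue = c(7.41e-323, 0.123456789123456))
  path <- tempfile(fileext = ".tsv")
  write_sumstats(rec, path)
  back <- read_sumstats(path, sumstats_dialect(chrom = "CHR", pos = "POS",
                                               pvalue = "P", rsid = "SNP"))
  expect_identical(back$chrom, rec$chrom)
  expect_identical(back$pos, rec$pos)
  expect_identical(back$pvalue, rec$pvalue)
})

test_that("locus TSV round trip and BED export clamp behaviour", {
  loci <- windows_from_points(
    data.frame(chrom = c("1", "2"), pos = c(300000, 5e6),
               pvalue = c(1e-9, 1e-10))
  )
  path <- tempfile(fileext = ".tsv")
  write_loci(loci, path)
  back <- read_loci(path)
  expect_equal(back$start, loci$start) # includes a negative start
  expect_equal(back$end, loci$end)
  expect_equal(back$lead_p, loci$lead_p)

  bed <- tempfile(fileext = ".bed")
  res <- suppressMessages(write_bed(loci, bed))
  expect_equal(attr(res, "n_clamped"), 1L)
  lines <- read.delim(bed, header = FALSE)
  expect_equal(lines$V2[1], 0) # clamped at zero
  expect_equal(lines$V3, loci$end)
})
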