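write_tsv_genes <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("gene models resolve one 5'-most TSS per gene", {
  # GTF is 1-based inclusive; transcripts of one + gene at starts 10001/9001
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "transcript", 10001, 12000, ".", "+", ".",
          'gene_id "gA"; transcript_id "gA.1";', sep = "\t"),
    paste("chr1", "src", "transcript", 9001, 11000, ".", "+", ".",
          'gene_id "gA"; transcript_id "gA.2";', sep = "\t"),
    paste("chr1", "src", "transcript", 15000, 20000, ".", "-", ".",
          'gene_id "gB"; transcript_id "gB.1";', sep = "\t")), gtf)
  genes <- read_gene_models(gtf)
  expect_equal(genes$tss[genes$gene_id == "gA"], 9000)   # 5'-most, 0-based
  expect_equal(genes$tss[genes$gene_id == "gB"], 19999)  # - strand uses end
  # TSV path round-trips the same table
  f <- write_tsv_genes(genes)
  expect_equal(read_gene_models(f), genes)
})

test_that("promoter windows are strand-aware and half-open at both edges", {
  genes <- data.frame(gene_id = c("plus", "minus"), chrom = c("c1", "c2"),
                      tss = c(10000, 10000), strand = c("+", "-"))
  ann <- function(chrom, s0, e0) {
    annotate_regions(gr0(chrom, s0, e0), genes)
  }
  # + strand window is [tss-5000, tss+100) = [5000, 10100)
  expect_true(ann("c1", 9000, 9500)$in_promoter)
  expect_equal(ann("c1", 9000, 9500)$tss_distance, -501)  # upstream
  expect_true(ann("c1", 5000, 5001)$in_promoter)
  expect_false(ann("c1", 4999, 5000)$in_promoter)
  expect_true(ann("c1", 10099, 10100)$in_promoter)
  expect_false(ann("c1", 10100, 10200)$in_promoter)
  # - strand window reflects to [tss-99, tss+5001) = [9901, 15001)
  expect_true(ann("c2", 9901, 9902)$in_promoter)
  expect_false(ann("c2", 9900, 9901)$in_promoter)
  expect_true(ann("c2", 15000, 15001)$in_promoter)
  expect_false(ann("c2", 15001, 15002)$in_promoter)
  # distal regions still get the nearest gene, flagged distal
  far <- ann("c1", 500000, 500100)
  expect_false(far$in_promoter)
  expect_equal(far$gene_id, "plus")
  expect_equal(far$tss_distance, 490000)
})

test_that("assignment ties break by distance then gene id", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "c",
                      tss = c(1000, 3000), strand = c("+", "+"))
  # region edges sit exactly 996 bp from both TSSs (equidistant)
  a <- annotate_regions(gr0("c", 1996, 2005), genes, upstream = 5000,
                        downstream = 5000)
  expect_equal(a$gene_id, "gA")  # |d| ties at 996: lexicographic
  # every region gets exactly one row, in input order
  many <- annotate_regions(gr0("c", c(2900, 900), c(2950, 950)), genes)
  expect_equal(nrow(many), 2L)
  expect_equal(many$gene_id, c("gA", "gB"))
})

test_that("gene sets deduplicate and honour the promoter-only flag", {
  asg <- data.frame(gene_id = c("g1", "g1", "g2", NA),
                    in_promoter = c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(gene_sets_from_dbrs(asg), c("g1", "g2"))
  expect_equal(gene_sets_from_dbrs(asg, promoter_only = TRUE), "g1")
  expect_equal(gene_sets_from_dbrs(asg[0, ]), character(0))
})

test_that("gene-set overlap chi-squared matches the closed form", {
  uni <- sprintf("g%04d", 1:1000)
  a <- uni[1:100]
  b <- uni[c(1:20, 101:130)]  # overlap 20, |B| = 50
  res <- overlap_chi_squared(a, b, uni)
  expect_equal(res$overlap, 20L)
  expect_equal(res$statistic, oracle_chi2(20, 80, 30, 870), tolerance = 1e-10)
  expect_equal(res$statistic, 52.6315789, tolerance = 1e-6)
  expect_equal(res$pvalue, pchisq(res$statistic, 1, lower.tail = FALSE))
  # independence with proportional margins gives exactly 0
  a0 <- uni[1:100]
  b0 <- uni[c(1:10, 101:190)]  # overlap 10 = 100*100/1000
  expect_equal(overlap_chi_squared(a0, b0, uni)$statistic, 0)
  # label symmetry
  expect_equal(overlap_chi_squared(b, a, uni)$statistic, res$statistic)
  # guards
  expect_error(overlap_chi_squared(character(0), b, uni), "non-empty")
  expect_error(overlap_chi_squared(c(a, "not_in_universe"), b, uni), "subsets")
})

test_that("chi-squared agrees with a permutation null under fixed margins", {
  set.seed(501)
  uni <- sprintf("g%04d", 1:1000)
  a <- uni[1:200]
  b <- uni[c(1:40, 201:310)]  # |B| = 150, overlap 40 (expected 30)
  res <- overlap_chi_squared(a, b, uni)
  nperm <- 10000
  chi_perm <- replicate(nperm, {
    ov <- length(intersect(sample(uni, length(b)), a))
    oracle_chi2(ov, length(a) - ov, length(b) - ov,
                length(uni) - length(a) - length(b) + ov)
  })
  p_perm <- mean(chi_perm >= res$statistic - 1e-9)
  mc_err <- 3 * sqrt(max(p_perm, res$pvalue) / nperm)
  # the asymptotic and resampled tails agree up to MC noise plus the
  # discreteness of the overlap count
  expect_lt(abs(p_perm - res$pvalue), mc_err + 0.02)
})
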