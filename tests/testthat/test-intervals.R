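test_that("BED and narrowPeak parsing maps fields and coordinates", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("# a comment", "track name=x", "chr1\t100\t200"), f)
  gr <- read_regions(f, dialect = "bed3")
  expect_equal(as.character(seqnames(gr)), "chr1")
  expect_equal(start(gr) - 1L, 100L)
  expect_equal(end(gr), 200L)

  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c(paste("chr2", 1000, 2000, "peak1", 85, ".", 85, -1, -1, 300,
                     sep = "\t"),
               paste("chr2", 3000, 3500, "peak2", 10, ".", 10, -1, -1, -1,
                     sep = "\t")), np)
  gr <- read_regions(np)  # auto dialect from 10 columns
  expect_equal(gr$summit_offset, c(300L, NA))
  expect_equal(gr$name, c("peak1", "peak2"))
})

test_that("malformed peak lines are rejected with the line number", {
  f <- tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t500\t400"), f)
  expect_error(read_regions(f, dialect = "bed3"), "line 2")
  writeLines(c("chr1\t100\t200", "chr1\tabc\t400"), f)
  expect_error(read_regions(f, dialect = "bed3"), "line 2.*non-integer")
  writeLines("chr1\t100", f)
  expect_error(read_regions(f, dialect = "bed3"), "line 1")
  expect_error(read_regions(tempfile(), dialect = "bed3"), "not found")
})

test_that("write/read round trip is the identity on random sets", {
  set.seed(101)
  for (i in 1:100) {
    df <- rand_intervals(sample(0:40, 1))
    gr <- df_to_gr(df)
    n <- length(gr)
    mcols(gr) <- S4Vectors::DataFrame(
      name = if (n) paste0("p", seq_len(n)) else character(0),
      score = if (n) sample.int(1000, n, replace = TRUE) else numeric(0),
      summit_offset = if (n) ifelse(runif(n) < 0.3, NA_integer_,
                                    as.integer(floor(runif(n) * width(gr))))
                      else integer(0))
    f <- tempfile(fileext = ".narrowPeak")
    write_regions(gr, f, dialect = "narrowPeak")
    back <- read_regions(f, dialect = "narrowPeak")
    gr_sorted <- sort(GenomeInfoDb::sortSeqlevels(gr), ignore.strand = TRUE)
    expect_equal(gr_to_df(back), gr_to_df(gr_sorted))
    expect_equal(back$summit_offset, gr_sorted$summit_offset)
    expect_equal(back$name, gr_sorted$name)
    expect_equal(back$score, as.numeric(gr_sorted$score))
  }
  # empty set -> empty file, reads back empty
  f <- tempfile()
  write_regions(GRanges(), f, dialect = "bed6")
  expect_equal(length(read_regions(f, dialect = "bed6")), 0L)
})

test_that("merge_intervals matches the per-base coverage oracle", {
  set.seed(102)
  for (gap in c(0L, 37L, 1000L)) {
    df <- rand_intervals(200)
    got <- gr_to_df(merge_intervals(df_to_gr(df), max_gap = gap))
    expect_equal(got, oracle_merge(df, gap), info = paste("gap", gap))
  }
  # overlapping pair, empty set, argument validation
  expect_equal(gr_to_df(merge_intervals(gr0("c", c(100, 150), c(200, 250)), 0)),
               data.frame(chrom = "c", start = 100L, end = 250L))
  expect_equal(length(merge_intervals(GRanges(), 10)), 0L)
  expect_error(merge_intervals(GRanges(), -1), "non-negative")
})

test_that("merge_intervals is idempotent and monotone in max_gap", {
  set.seed(103)
  for (i in 1:20) {
    gr <- df_to_gr(rand_intervals(80))
    m1 <- merge_intervals(gr, 37)
    expect_identical(granges(merge_intervals(m1, 37)), granges(m1))
    wide <- merge_intervals(gr, 400)
    # every gap-37 run is contained in some gap-400 run
    ov <- findOverlaps(m1, wide, type = "within")
    expect_equal(length(unique(queryHits(ov))), length(m1))
  }
})

test_that("gap-tolerant overlap follows half-open gap arithmetic", {
  a <- gr0("chr1", 100, 200)
  expect_true(overlaps_with_gap(a, gr0("chr1", 1150, 1300), 1000))   # gap 950
  expect_false(overlaps_with_gap(a, gr0("chr1", 1201, 1300), 1000))  # gap 1001
  expect_true(overlaps_with_gap(a, gr0("chr1", 1200, 1300), 1000))   # gap 1000
  expect_true(overlaps_with_gap(a, a, 0))                            # identity
  expect_true(overlaps_with_gap(a, gr0("chr1", 200, 300), 0))        # touching
  expect_false(overlaps_with_gap(a, gr0("chr2", 100, 200), 1e6))     # chrom
  # symmetry on random pairs, and agreement with the arithmetic oracle
  set.seed(104)
  for (i in 1:200) {
    d <- rand_intervals(2)
    x <- gr0(d$chrom[1], d$start[1], d$end[1])
    y <- gr0(d$chrom[2], d$start[2], d$end[2])
    g <- sample(c(0, 10, 100), 1)
    expect_equal(overlaps_with_gap(x, y, g), overlaps_with_gap(y, x, g))
    expect_equal(overlaps_with_gap(x, y, g),
                 oracle_gap(d$chrom[1], d$start[1], d$end[1],
                            d$chrom[2], d$start[2], d$end[2]) <= g)
  }
})

test_that("subset_by_overlap matches the all-pairs oracle and partitions", {
  set.seed(105)
  for (i in 1:30) {
    q <- rand_intervals(100)
    s <- rand_intervals(100)
    qg <- df_to_gr(q)
    sg <- df_to_gr(s)
    keep <- subset_by_overlap(qg, sg, max_gap = 1000)
    drop <- subset_by_overlap(qg, sg, max_gap = 1000, invert = TRUE)
    expect_equal(gr_to_df(keep), sort_df(oracle_subset(q, s, 1000)))
    # disjoint partition reassembling the query
    expect_equal(length(keep) + length(drop), length(qg))
    expect_equal(gr_to_df(sort(c(keep, drop), ignore.strand = TRUE)),
                 gr_to_df(sort(qg, ignore.strand = TRUE)))
  }
  qg <- df_to_gr(rand_intervals(10))
  expect_identical(subset_by_overlap(qg, qg, 0), qg)           # self-overlap
  expect_identical(subset_by_overlap(qg, GRanges(), 0, TRUE), qg)
  expect_equal(length(subset_by_overlap(qg, GRanges(), 0)), 0L)
})

test_that("chromosome-dialect mixing is a hard error", {
  a <- gr0("chr1", 0, 10)
  b <- gr0("1", 0, 10)
  expect_error(baseline_enhancers(a, b), "dialect")
})
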