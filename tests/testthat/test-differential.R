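make_cm <- function(y, groups = rep(c("WT", "KO"), each = ncol(y) / 2),
                    lib_sizes = NULL) {
  colnames(y) <- paste0("s", seq_len(ncol(y)))
  regions <- GRanges("chr1", IRanges(seq_len(nrow(y)) * 3000, width = 1000))
  if (is.null(lib_sizes)) lib_sizes <- setNames(rep(1e5, ncol(y)), colnames(y))
  else lib_sizes <- setNames(lib_sizes, colnames(y))
  count_matrix(regions, y, setNames(groups, colnames(y)), lib_sizes)
}

test_that("summit windows recentre on the summit or the midpoint", {
  # no summit: midpoint 1500, half-width 500 -> the 1000 bp interval itself
  r <- gr0("c", 1000, 2000)
  expect_equal(gr_to_df(summit_windows(r, 500)),
               data.frame(chrom = "c", start = 1000L, end = 2000L))
  # narrowPeak summit offset 300, half-width 150 -> [1150, 1450)
  mcols(r)$summit_offset <- 300L
  expect_equal(gr_to_df(summit_windows(r, 150)),
               data.frame(chrom = "c", start = 1150L, end = 1450L))
  # summit near the chromosome origin clamps at 0
  r2 <- gr0("c", 50, 150)
  mcols(r2)$summit_offset <- 50L  # summit at base 100
  expect_equal(gr_to_df(summit_windows(r2, 500)),
               data.frame(chrom = "c", start = 0L, end = 600L))
  # one window per region, order preserved
  rr <- gr0("c", c(5000, 1000), c(6000, 2000))
  w <- summit_windows(rr, 100)
  expect_equal(length(w), 2L)
  expect_equal(start(w) - 1L, c(5400L, 1400L))
})

test_that("fragment-midpoint counting matches the quadratic oracle", {
  win <- gr0("c", c(100, 300), c(200, 400))
  expect_warning(
    cmx <- count_fragments(win, list(s1 = GRanges(), s2 = gr0("c", 140, 180)),
                           c(s1 = "WT", s2 = "KO")),
    "empty")
  expect_equal(unname(cmx$counts[, "s1"]), c(0L, 0L))
  expect_equal(unname(cmx$counts[, "s2"]), c(1L, 0L))  # midpoint 160
  set.seed(301)
  for (i in 1:20) {
    wdf <- rand_intervals(20)
    f1 <- rand_intervals(200)
    f2 <- rand_intervals(200)
    got <- count_fragments(df_to_gr(wdf),
                           list(a = df_to_gr(f1), b = df_to_gr(f2)),
                           c(a = "WT", b = "KO"))
    # count_fragments sees windows in the given (unsorted) order
    expect_equal(unname(got$counts[, "a"]), oracle_count(wdf, f1))
    expect_equal(unname(got$counts[, "b"]), oracle_count(wdf, f2))
    expect_equal(unname(got$lib_sizes), c(200, 200))
  }
})

test_that("TMM factors normalise composition and match edgeR", {
  set.seed(302)
  y <- matrix(rnbinom(500 * 4, mu = 100, size = 10), ncol = 4)
  # identical columns -> all factors 1
  cm_id <- make_cm(matrix(rep(y[, 1], 4), ncol = 4))
  expect_equal(unname(tmm_factors(cm_id)), rep(1, 4))
  # doubling every count with doubled library size leaves factors at 1
  y2 <- cbind(y[, 1], y[, 1] * 2L)
  cm2 <- make_cm(y2, groups = c("WT", "KO"), lib_sizes = colSums(y2))
  f2 <- tmm_factors(cm2)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-10)
  eff <- cm2$lib_sizes * f2
  expect_equal(unname(eff[2] / eff[1]), 2, tolerance = 1e-10)
  # geometric mean is exactly 1
  set.seed(303)
  y3 <- matrix(rnbinom(2000 * 6, mu = exp(runif(2000 * 6, 3, 5)), size = 5),
               ncol = 6)
  cm3 <- make_cm(y3, lib_sizes = colSums(y3))
  f3 <- tmm_factors(cm3)
  expect_equal(exp(mean(log(f3))), 1, tolerance = 1e-12)
  # independent implementation: edgeR's TMM on the same matrix
  f_edger <- edgeR::calcNormFactors(
    edgeR::DGEList(counts = cm3$counts, lib.size = unname(cm3$lib_sizes)),
    method = "TMM")$samples$norm.factors
  expect_equal(unname(f3), f_edger, tolerance = 1e-8)
  expect_error(tmm_factors(make_cm(matrix(0L, 5, 4))), "all-zero")
})

test_that("dispersion estimation recovers the simulated truth", {
  set.seed(304)
  n <- 2000
  # Poisson counts: estimates collapse toward zero
  yp <- matrix(rpois(n * 6, 100), ncol = 6)
  dp <- estimate_dispersions(make_cm(yp))
  expect_lte(median(dp), 0.05)
  # NB at phi = 0.2: estimates bracket the truth
  yn <- matrix(rnbinom(n * 6, mu = 100, size = 5), ncol = 6)
  dn <- estimate_dispersions(make_cm(yn))
  expect_gte(median(dn), 0.1)
  expect_lte(median(dn), 0.4)
  # identical counts in every sample: zero variance clamps to the floor
  yc <- matrix(50L, nrow = 10, ncol = 6)
  dc <- estimate_dispersions(make_cm(yc))
  expect_equal(unname(dc), rep(1e-8, 10))
  # a group with a single replicate is refused
  expect_error(
    estimate_dispersions(make_cm(yp[, 1:3], groups = c("WT", "WT", "KO"))),
    "2 replicates")
})

test_that("the conditional exact test reduces to the binomial at phi -> 0", {
  # symmetric case is exactly p = 1
  expect_equal(nb_exact_pvalue(10, 10, 3, 3, 0.1), 1)
  # Poisson-limit worked case: 3 vs 7 -> 2 * P(Binom(10, 1/2) <= 3)
  expect_equal(nb_exact_pvalue(3, 7, 3, 3, 0), 0.34375, tolerance = 1e-12)
  # small exhaustive grid against the enumeration oracle
  for (n in c(5L, 12L, 25L)) {
    for (a in 0:n) {
      expect_equal(nb_exact_pvalue(a, n - a, 3, 3, 0),
                   oracle_binom_twosided(a, n, 0.5), tolerance = 1e-12)
    }
  }
  # unequal group sizes use the matching binomial proportion
  expect_equal(nb_exact_pvalue(4, 8, 2, 4, 0),
               oracle_binom_twosided(4, 12, 2 / 6), tolerance = 1e-12)
  # label-swap invariance at positive dispersion
  set.seed(305)
  for (i in 1:50) {
    a <- sample(0:60, 1); b <- sample(0:60, 1)
    expect_equal(nb_exact_pvalue(a, b, 3, 3, 0.15),
                 nb_exact_pvalue(b, a, 3, 3, 0.15), tolerance = 1e-12)
  }
  expect_error(nb_exact_pvalue(1, 2, 3, 3, -0.1), "non-negative")
})

test_that("per-region exact tests agree with edgeR's smallp rejection region", {
  set.seed(306)
  n <- 1000
  mu <- exp(runif(n, log(20), log(300)))
  lfc <- ifelse(runif(n) < 0.1, sample(c(-2, 2), n, replace = TRUE), 0)
  y <- cbind(matrix(rnbinom(n * 3, mu = mu, size = 10), ncol = 3),
             matrix(rnbinom(n * 3, mu = mu * 2^lfc, size = 10), ncol = 3))
  cm <- make_cm(y)
  p_mine <- nb_exact_test(cm, dispersions = 0.1)$pvalue
  d <- edgeR::DGEList(counts = cm$counts, group = cm$groups,
                      lib.size = unname(cm$lib_sizes))
  p_edger <- edgeR::exactTest(d, dispersion = 0.1,
                              rejection.region = "smallp")$table$PValue
  dlog <- abs(log(pmax(p_mine, 1e-300)) - log(pmax(p_edger, 1e-300)))
  expect_lt(quantile(dlog, 0.99), 1e-10)  # ties may differ on a handful
  expect_lt(max(abs(p_mine - p_edger) / pmax(p_edger, 1e-12)), 0.1)
  # identical groups give p = 1 and log2fc = 0
  cm_eq <- make_cm(cbind(y[, 1:3], y[, 1:3]))
  res <- nb_exact_test(cm_eq, dispersions = 0.1)
  expect_equal(res$pvalue, rep(1, n))
  expect_equal(res$log2fc, rep(0, n))
})

test_that("null counts give a calibrated type-I error rate", {
  set.seed(307)
  n <- 2000
  y <- matrix(rnbinom(n * 6, mu = 100, size = 10), ncol = 6)
  cm <- make_cm(y)
  res <- nb_exact_test(cm, dispersions = estimate_dispersions(cm),
                       factors = tmm_factors(cm))
  frac <- mean(res$pvalue < 0.05)
  expect_gte(frac, 0.025)
  expect_lte(frac, 0.075)
})

test_that("BH adjustment matches direct step-up enumeration", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))  # all-equal fixed point
  set.seed(308)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_true(all(q[order(p)] == cummax(q[order(p)])))  # monotone
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "missing")
})

test_that("DBR calls apply strict FDR and sign rules", {
  regions <- gr0("c", c(0, 100, 200, 300), c(50, 150, 250, 350))
  mcols(regions) <- S4Vectors::DataFrame(
    log2fc = c(1.2, 0.8, -0.3, 0), qvalue = c(0.049, 0.05, 0.01, 0.001))
  sets <- call_dbrs(regions, alpha = 0.05)
  expect_equal(sets$call, c("gained", "ns", "lost", "ns"))
  expect_equal(length(sets$gained), 1L)
  expect_equal(length(sets$lost), 1L)
  # partition: gained, lost and ns cover all regions disjointly
  expect_equal(sum(table(sets$call)), length(regions))
})
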