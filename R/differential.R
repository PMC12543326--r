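## Summit-centred windows, fragment counting, TMM normalisation,
## dispersion estimation, the conditional NB exact test, BH adjustment and
## DBR calling.
##
## The statistical engine is written out in full here: trimmed mean of
## M-values for composition normalisation, a method-of-moments dispersion
## with shrinkage toward the common value, and a two-group exact test that
## conditions on the window total.  Under negative-binomial sampling with
## a shared dispersion the group sum given the total follows a
## beta-binomial-type law that is free of the unknown mean, which is what
## makes the exact test possible.

#' Summit-centred testing windows
#'
#' Maps each region to a fixed-width window centred on its summit
#' (`summit_offset` metadata when present, otherwise the region midpoint).
#' The conventional widths are 1000 bp (`half_width = 500`) for broadish
#' marks and 300 bp (`half_width = 150`) for H3K4me3. Windows are clamped
#' at position 0 and at the chromosome length when known; one window is
#' returned per input region, order preserved.
#'
#' @param regions A `GRanges`, optionally with a `summit_offset` column.
#' @param half_width Positive half-width in bp.
#' @return `GRanges` of windows (metadata column `name` kept if present).
#' @export
summit_windows <- function(regions, half_width = 500) {
  if (length(half_width) != 1L || is.na(half_width) || half_width <= 0) {
    stop("half_width must be a single positive number")
  }
  hw <- as.integer(half_width)
  if (length(regions) == 0L) return(GenomicRanges::granges(regions))
  start0 <- BiocGenerics::start(regions) - 1L
  end0 <- BiocGenerics::end(regions)
  mc <- S4Vectors::mcols(regions)
  summit0 <- if ("summit_offset" %in% names(mc)) {
    ifelse(is.na(mc$summit_offset), (start0 + end0) %/% 2L,
           start0 + mc$summit_offset)
  } else {
    (start0 + end0) %/% 2L
  }
  ws <- pmax(summit0 - hw, 0L)
  we <- summit0 + hw
  sl <- GenomeInfoDb::seqlengths(regions)
  if (any(!is.na(sl))) {
    lim <- sl[as.character(GenomeInfoDb::seqnames(regions))]
    we <- ifelse(is.na(lim), we, pmin(we, lim))
    ws <- ifelse(is.na(lim), ws, pmin(ws, pmax(lim - 1L, 0L)))
  }
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(regions),
                                IRanges::IRanges(ws + 1L, we),
                                seqinfo = GenomeInfoDb::seqinfo(regions))
  if ("name" %in% names(mc)) S4Vectors::mcols(out)$name <- mc$name
  out
}

#' Region-by-sample count matrix container
#'
#' Bundles testing windows with an integer count matrix, sample group
#' labels and library sizes. Library sizes default to the column totals
#' but should normally be the total fragment count per sample.
#'
#' @param regions `GRanges` of tested windows (rows).
#' @param counts Integer matrix, `length(regions)` x samples; column
#'   names are the sample ids.
#' @param groups Named character vector mapping each sample id to its
#'   condition (e.g. `"WT"`/`"KO"`).
#' @param lib_sizes Named positive numeric vector of per-sample library
#'   sizes.
#' @return An object of class `chip_counts`.
#' @export
count_matrix <- function(regions, counts, groups,
                         lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have sample column names")
  if (length(regions) != nrow(counts)) {
    stop("nrow(counts) must equal length(regions)")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  samples <- colnames(counts)
  if (!all(samples %in% names(groups))) {
    stop("every sample needs a group label")
  }
  groups <- setNames(as.character(groups[samples]), samples)
  lib_sizes <- lib_sizes[samples]
  if (anyNA(lib_sizes) || any(lib_sizes <= 0)) {
    stop("lib_sizes must be positive for every sample")
  }
  structure(list(regions = regions, counts = counts, samples = samples,
                 groups = groups, lib_sizes = setNames(as.numeric(lib_sizes),
                                                       samples)),
            class = "chip_counts")
}

#' @export
print.chip_counts <- function(x, ...) {
  cat("chip_counts:", nrow(x$counts), "regions x", ncol(x$counts),
      "samples\n")
  cat("groups:", paste(sprintf("%s=%s", x$samples, x$groups), collapse = ", "),
      "\n")
  invisible(x)
}

#' Count fragment midpoints in testing windows
#'
#' `counts[r, s]` is the number of fragments of sample `s` whose midpoint
#' falls inside window `r`. Midpoint counting keeps counts disjoint across
#' abutting windows. Library sizes are the total fragment counts per
#' sample (not the in-window totals).
#'
#' @param windows `GRanges` of testing windows.
#' @param fragments Named list of `GRanges`, one per sample.
#' @param groups Named character vector mapping sample id to condition.
#' @return A [count_matrix()] object.
#' @export
count_fragments <- function(windows, fragments, groups) {
  if (is.null(names(fragments))) stop("fragments list must be named by sample")
  counts <- vapply(fragments, function(fr) {
    if (length(fr) == 0L) {
      warning("empty fragment set; zero column")
      return(integer(length(windows)))
    }
    m0 <- (BiocGenerics::start(fr) - 1L + BiocGenerics::end(fr)) %/% 2L
    mids <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(fr),
                                   IRanges::IRanges(m0 + 1L, m0 + 1L))
    suppressWarnings(GenomicRanges::countOverlaps(windows, mids,
                                                  ignore.strand = TRUE))
  }, integer(length(windows)))
  counts <- matrix(counts, nrow = length(windows),
                   dimnames = list(NULL, names(fragments)))
  ## an empty sample keeps its zero column; library size 1 is a neutral
  ## placeholder so the container's positivity invariant holds
  count_matrix(windows, counts, groups,
               lib_sizes = pmax(vapply(fragments, length, numeric(1)), 1))
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes per-sample composition scaling factors by the trimmed,
#' precision-weighted mean of log2 count ratios (M) against a reference
#' sample, trimming `trim_m` of the M distribution on each side and
#' `trim_a` of the average-abundance (A) distribution. The reference is
#' the sample whose upper-quartile count fraction is closest to the mean
#' upper quartile. Factors are rescaled to geometric mean 1; the
#' effective library size is `lib_size * factor`.
#'
#' @param counts A `chip_counts` object or integer matrix.
#' @param lib_sizes Library sizes (taken from the object when omitted).
#' @param trim_m,trim_a Two-sided trim fractions for M and A (defaults
#'   0.3 and 0.05).
#' @return Named numeric vector of scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_sizes = NULL, trim_m = 0.3, trim_a = 0.05) {
  if (inherits(counts, "chip_counts")) {
    if (is.null(lib_sizes)) lib_sizes <- counts$lib_sizes
    counts <- counts$counts
  }
  y <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(y)
  if (all(y == 0)) stop("cannot estimate scaling factors from an all-zero matrix")
  if (!any(rowSums(y > 0) == ncol(y))) {
    stop("need at least one region with positive counts in every sample")
  }
  f75 <- vapply(seq_len(ncol(y)), function(s) {
    stats::quantile(y[, s] / lib_sizes[s], 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(y)), function(s) {
    .tmm_pair(y[, s], y[, ref], lib_sizes[s], lib_sizes[ref], trim_m, trim_a)
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  setNames(fac, colnames(y))
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) stop("no region with positive counts in both samples")
  p_o <- obs[keep] / n_obs
  p_r <- ref[keep] / n_ref
  m <- log2(p_o / p_r)
  a <- 0.5 * log2(p_o * p_r)
  ## delta-method variance of each M value; precision 1/v weights the mean
  v <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
    (n_ref - ref[keep]) / (n_ref * ref[keep])
  fin <- is.finite(m) & is.finite(a) & is.finite(v) & v > 0
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  n <- length(m)
  if (n == 0L) return(1)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm <- rank(m)
  ra <- rank(a)
  keep2 <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  2^(sum(m[keep2] / v[keep2]) / sum(1 / v[keep2]))
}

#' Per-region negative-binomial dispersions
#'
#' Method-of-moments estimate on the normalised scale: counts are scaled
#' to a common effective library size, the within-group mean/variance
#' relation `var = mu + phi * mu^2` is solved for `phi` per group and
#' pooled by degrees of freedom, the raw value is clamped at `floor`, and
#' every region is shrunk toward the common (all-region mean) dispersion
#' with weight `prior_df / (prior_df + df_region)`. The mean is used for
#' the common value because the per-region ratio estimates are
#' right-skewed at few degrees of freedom: their median sits well below
#' the true dispersion, which would make the exact test liberal.
#'
#' @param counts A `chip_counts` object.
#' @param factors Scaling factors from [tmm_factors()] (all 1 when
#'   omitted).
#' @param prior_df Prior degrees of freedom of the shrinkage (default 10).
#' @param floor Lower clamp for the dispersion (default `1e-8`).
#' @return Numeric vector of dispersions, one per region.
#' @export
estimate_dispersions <- function(counts, factors = NULL, prior_df = 10,
                                 floor = 1e-8) {
  stopifnot(inherits(counts, "chip_counts"))
  y <- counts$counts
  grp <- counts$groups
  tab <- table(grp)
  if (any(tab < 2L)) {
    stop("every group needs >= 2 replicates to estimate dispersion; ",
         "supply a fixed dispersion to nb_exact_test instead")
  }
  if (is.null(factors)) factors <- setNames(rep(1, ncol(y)), colnames(y))
  eff <- counts$lib_sizes * factors[counts$samples]
  lbar <- exp(mean(log(eff)))
  z <- sweep(y, 2L, lbar / eff, `*`)
  glev <- names(tab)
  df_r <- ncol(y) - length(glev)
  raw <- rep(NA_real_, nrow(y))
  num <- rep(0, nrow(y))
  den <- rep(0, nrow(y))
  for (g in glev) {
    zg <- z[, grp == g, drop = FALSE]
    ng <- ncol(zg)
    mg <- rowMeans(zg)
    vg <- rowSums((zg - mg)^2) / (ng - 1L)
    phig <- ifelse(mg > 0, (vg - mg) / mg^2, 0)
    num <- num + (ng - 1L) * phig
    den <- den + (ng - 1L)
  }
  raw <- pmax(num / den, floor)
  common <- mean(raw)
  w <- prior_df / (prior_df + df_r)
  pmax(w * common + (1 - w) * raw, floor)
}

#' Two-sided conditional NB exact p-value for two group sums
#'
#' Given the summed (pseudo-)counts of two groups of `n_a` and `n_b`
#' samples at common effective library size, computes the probability,
#' conditional on the total, of all group-A sums at most as probable as
#' the observed one, under negative-binomial sampling with dispersion
#' `phi`. At `phi = 0` the sampling law is Poisson and the conditional
#' distribution is Binomial(total, n_a / (n_a + n_b)).
#'
#' @param sum_a,sum_b Non-negative group sums.
#' @param n_a,n_b Number of samples in each group.
#' @param phi Dispersion (>= 0).
#' @return p-value in (0, 1].
#' @export
nb_exact_pvalue <- function(sum_a, sum_b, n_a, n_b, phi) {
  if (length(phi) != 1L || is.na(phi) || phi < 0) {
    stop("phi must be a single non-negative number")
  }
  n <- sum_a + sum_b
  if (n == 0) return(1)
  a <- 0:n
  if (phi < 1e-10) {
    lp <- stats::dbinom(a, n, n_a / (n_a + n_b), log = TRUE)
  } else {
    ra <- n_a / phi
    rb <- n_b / phi
    lp <- stats::dnbinom(a, size = ra, prob = 0.5, log = TRUE) +
      stats::dnbinom(n - a, size = rb, prob = 0.5, log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  p <- p / sum(p)
  pobs <- p[sum_a + 1L]
  min(1, sum(p[p <= pobs * (1 + 1e-8)]))
}

## Quantile-match a count from its own NB law to the common library size
## (mid-P continuity), so unequal libraries can be summed within groups.
.quantile_adjust <- function(y, mu_own, mu_common, phi) {
  if (mu_own <= 0 || mu_common <= 0) return(y)
  if (phi < 1e-10) {
    fmid <- stats::ppois(y, mu_own) - 0.5 * stats::dpois(y, mu_own)
    stats::qpois(pmin(pmax(fmid, 1e-12), 1 - 1e-12), mu_common)
  } else {
    sz <- 1 / phi
    fmid <- stats::pnbinom(y, size = sz, mu = mu_own) -
      0.5 * stats::dnbinom(y, size = sz, mu = mu_own)
    stats::qnbinom(pmin(pmax(fmid, 1e-12), 1 - 1e-12), size = sz,
                   mu = mu_common)
  }
}

#' Conditional NB exact test per region
#'
#' For each region, counts are quantile-adjusted to a common effective
#' library size (geometric mean of `lib_size * factor`), summed per group
#' and compared by [nb_exact_pvalue()]. The log2 fold change is
#' `log2((mean normalised KO + c) / (mean normalised WT + c))` with
#' pseudo-count `c` (default 0.125) so zero groups stay finite.
#'
#' @param counts A `chip_counts` object with exactly two groups.
#' @param dispersions Per-region dispersions (recycled when scalar).
#' @param factors Scaling factors from [tmm_factors()] (all 1 when
#'   omitted).
#' @param reference Group label used as denominator of the fold change
#'   (default `"WT"` when present, otherwise the first group level).
#' @param pseudo Fold-change pseudo-count (default 0.125).
#' @return `data.frame` with columns `log2fc`, `pvalue`.
#' @export
nb_exact_test <- function(counts, dispersions, factors = NULL,
                          reference = NULL, pseudo = 0.125) {
  stopifnot(inherits(counts, "chip_counts"))
  y <- counts$counts
  grp <- counts$groups
  glev <- unique(grp)
  if (length(glev) != 2L) stop("exactly two groups required")
  if (is.null(reference)) reference <- if ("WT" %in% glev) "WT" else glev[1L]
  if (!reference %in% glev) stop("reference group not found")
  other <- setdiff(glev, reference)
  if (any(dispersions < 0)) stop("dispersions must be >= 0")
  phi <- rep_len(dispersions, nrow(y))
  if (is.null(factors)) factors <- setNames(rep(1, ncol(y)), colnames(y))
  eff <- counts$lib_sizes * factors[counts$samples]
  lbar <- exp(mean(log(eff)))
  equal_libs <- max(abs(eff / lbar - 1)) < 1e-9
  is_a <- grp == reference
  n_a <- sum(is_a)
  n_b <- sum(!is_a)
  z <- sweep(y, 2L, lbar / eff, `*`)
  log2fc <- log2((rowMeans(z[, !is_a, drop = FALSE]) + pseudo) /
                 (rowMeans(z[, is_a, drop = FALSE]) + pseudo))
  rate <- rowSums(y) / sum(eff)
  pvalue <- vapply(seq_len(nrow(y)), function(r) {
    if (equal_libs) {
      ps <- y[r, ]
    } else {
      mu_own <- eff * rate[r]
      mu_common <- lbar * rate[r]
      ps <- vapply(seq_along(eff), function(s) {
        .quantile_adjust(y[r, s], mu_own[s], mu_common, phi[r])
      }, numeric(1))
    }
    nb_exact_pvalue(round(sum(ps[is_a])), round(sum(ps[!is_a])),
                    n_a, n_b, phi[r])
  }, numeric(1))
  data.frame(log2fc = log2fc, pvalue = pvalue)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the input and applies the step-up procedure
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1, returned in input
#' order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially bound regions
#'
#' A region is `gained` when `qvalue < alpha` and `log2fc > 0`, `lost`
#' when `qvalue < alpha` and `log2fc < 0` (strict inequalities throughout,
#' so `q = alpha` is not significant), otherwise `ns`.
#'
#' @param results `GRanges` with metadata columns `log2fc` and `qvalue`
#'   (e.g. from [test_differential_binding()]).
#' @param alpha FDR threshold (default 0.05).
#' @return List with elements `gained`, `lost` (`GRanges`) and `call`
#'   (character vector over all input regions).
#' @export
call_dbrs <- function(results, alpha = 0.05) {
  mc <- S4Vectors::mcols(results)
  stopifnot(all(c("log2fc", "qvalue") %in% names(mc)))
  call <- rep("ns", length(results))
  call[mc$qvalue < alpha & mc$log2fc > 0] <- "gained"
  call[mc$qvalue < alpha & mc$log2fc < 0] <- "lost"
  list(gained = results[call == "gained"], lost = results[call == "lost"],
       call = call)
}

#' Full differential-binding test for one mark
#'
#' Convenience wrapper running [tmm_factors()], [estimate_dispersions()],
#' [nb_exact_test()], [bh_adjust()] and [call_dbrs()] in sequence.
#'
#' @inheritParams nb_exact_test
#' @param alpha FDR threshold for the DBR call.
#' @param trim_m,trim_a TMM trim fractions.
#' @param prior_df Dispersion shrinkage prior.
#' @param dispersion Optional fixed dispersion overriding estimation.
#' @return The region `GRanges` with metadata columns `log2fc`, `pvalue`,
#'   `qvalue`, `call`.
#' @export
test_differential_binding <- function(counts, alpha = 0.05, trim_m = 0.3,
                                      trim_a = 0.05, prior_df = 10,
                                      dispersion = NULL, reference = NULL,
                                      pseudo = 0.125) {
  stopifnot(inherits(counts, "chip_counts"))
  fac <- tmm_factors(counts, trim_m = trim_m, trim_a = trim_a)
  phi <- if (is.null(dispersion)) {
    estimate_dispersions(counts, factors = fac, prior_df = prior_df)
  } else {
    rep_len(dispersion, nrow(counts$counts))
  }
  res <- nb_exact_test(counts, dispersions = phi, factors = fac,
                       reference = reference, pseudo = pseudo)
  q <- bh_adjust(res$pvalue)
  out <- GenomicRanges::granges(counts$regions)
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    log2fc = res$log2fc, pvalue = res$pvalue, qvalue = q)
  S4Vectors::mcols(out)$call <- call_dbrs(out, alpha = alpha)$call
  out
}
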