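# Brute-force oracles, kept deliberately naive and independent of the
# package's sweep-line/GRanges implementations.  All oracles work on plain
# data.frames with 0-based half-open coordinates.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# random interval table on a small coordinate space
rand_intervals <- function(n, chroms = c("chrA", "chrB"), maxpos = 2000,
                           maxlen = 120) {
  s <- sample.int(maxpos, n, replace = TRUE)
  w <- sample.int(maxlen, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE), start = s, end = s + w,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) {
  GRanges(df$chrom, IRanges(df$start + 1L, df$end))
}

sort_df <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), c("chrom", "start", "end")]
  rownames(df) <- NULL
  df
}

gr_to_df <- function(gr) {
  sort_df(data.frame(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
                     end = end(gr), stringsAsFactors = FALSE))
}

# per-base boolean-coverage merge: mark covered bases, bridge gaps <=
# max_gap, extract runs
oracle_merge <- function(df, max_gap) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, ]
    m <- max(d$end) + 1L
    cov <- logical(m)
    for (i in seq_len(nrow(d))) cov[(d$start[i] + 1L):d$end[i]] <- TRUE
    if (max_gap > 0) {
      r <- rle(cov)
      pos <- cumsum(r$lengths)
      for (j in seq_along(r$lengths)) {
        if (!r$values[j] && j > 1 && j < length(r$lengths) &&
            r$lengths[j] <= max_gap) {
          cov[(pos[j] - r$lengths[j] + 1L):pos[j]] <- TRUE
        }
      }
    }
    r <- rle(cov)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep))
      out[[ch]] <- data.frame(chrom = ch, start = s[keep] - 1L, end = e[keep],
                              stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  if (is.null(d)) data.frame(chrom = character(0), start = integer(0),
                             end = integer(0)) else {
    rownames(d) <- NULL
    d
  }
}

# gap between two 0-based half-open intervals (Inf across chromosomes)
oracle_gap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(Inf)
  max(0L, max(s2 - e1, s1 - e2))
}

# all-pairs subset-by-overlap
oracle_subset <- function(query, subject, max_gap, invert = FALSE) {
  hit <- vapply(seq_len(nrow(query)), function(i) {
    any(vapply(seq_len(nrow(subject)), function(j) {
      oracle_gap(query$chrom[i], query$start[i], query$end[i],
                 subject$chrom[j], subject$start[j], subject$end[j]) <= max_gap
    }, logical(1)))
  }, logical(1))
  if (invert) query[!hit, , drop = FALSE] else query[hit, , drop = FALSE]
}

# per-base replicate support counting
oracle_consensus <- function(rep_dfs, k) {
  all_df <- do.call(rbind, rep_dfs)
  out <- list()
  for (ch in sort(unique(all_df$chrom))) {
    m <- max(all_df$end[all_df$chrom == ch]) + 1L
    supp <- integer(m)
    for (d in rep_dfs) {
      d <- d[d$chrom == ch, ]
      if (nrow(d) == 0) next
      cov <- logical(m)
      for (i in seq_len(nrow(d))) cov[(d$start[i] + 1L):d$end[i]] <- TRUE
      supp <- supp + cov
    }
    r <- rle(supp >= k)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep))
      out[[ch]] <- data.frame(chrom = ch, start = s[keep] - 1L, end = e[keep],
                              stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  if (is.null(d)) data.frame(chrom = character(0), start = integer(0),
                             end = integer(0)) else {
    rownames(d) <- NULL
    d
  }
}

# quadratic midpoint-containment counting
oracle_count <- function(win_df, frag_df) {
  mid <- (frag_df$start + frag_df$end) %/% 2L
  vapply(seq_len(nrow(win_df)), function(r) {
    sum(frag_df$chrom == win_df$chrom[r] & mid >= win_df$start[r] &
          mid < win_df$end[r])
  }, integer(1))
}

# two-sided conditional binomial test by direct enumeration
oracle_binom_twosided <- function(a, n, prob) {
  k <- 0:n
  p <- exp(lchoose(n, k) + k * log(prob) + (n - k) * log1p(-prob))
  min(1, sum(p[p <= p[a + 1] * (1 + 1e-8)]))
}

# BH step-up by direct enumeration
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# closed-form Pearson chi-squared for a 2x2 table
oracle_chi2 <- function(a, b, cc, d) {
  a <- as.numeric(a); b <- as.numeric(b); cc <- as.numeric(cc)
  d <- as.numeric(d)
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
}

# small helper: GRanges from 0-based half-open triple
gr0 <- function(chrom, start0, end0) {
  GRanges(chrom, IRanges(start0 + 1L, end0))
}
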