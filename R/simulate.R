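## Planted-truth simulator: a complete in-silico histone-mark experiment
## (3 clones x 2 genotypes x 4 marks) with known locus classes,
## differential effects and expected enhancer states, written as
## narrowPeak + fragment BED + TSS table + truth table, so every pipeline
## stage can be validated against ground truth.

SIM_MARKS <- c("H3K4me3", "H3K27me3", "H3K4me1", "H3K27ac")
SIM_CONDITIONS <- c("WT", "KO")

#' Simulation configuration
#'
#' Defines the planted architecture. Defaults emulate the study design:
#' two 10 Mb synthetic chromosomes; 600 promoter loci (60% bivalent,
#' carrying H3K27me3 on top of H3K4me3), 300 poised enhancers (H3K4me1
#' only), 300 active enhancers with H3K4me1 and 300 without; 200 planted
#' differential regions per mark at |log2FC| = 2 split evenly between
#' gained and lost; 50 of the H3K4me3 gains coincide with H3K27me3 losses
#' at the same promoter (the planted bivalency-resolution set); 3
#' replicates per genotype; NB fragment counts with dispersion 0.1 and
#' mean 100 per true peak; replicate peak boundaries jittered (sd 25 bp)
#' and dropped with probability 0.05.
#'
#' @param genome Named vector of chromosome lengths.
#' @param n_promoter,n_poised,n_active_with_k4me1,n_active_no_k4me1
#'   Planted locus counts per class.
#' @param bivalent_fraction Fraction of promoters also carrying H3K27me3.
#' @param n_diff_per_mark Named vector: planted differential loci per
#'   mark (split evenly gained/lost).
#' @param n_bivalency_resolved Promoters planted with simultaneous
#'   H3K4me3 gain and H3K27me3 loss.
#' @param log2fc Magnitude of the planted effects.
#' @param replicates Replicates per condition.
#' @param dispersion NB dispersion of fragment counts.
#' @param mean_fragments Mean fragments per true peak per sample (WT
#'   level).
#' @param jitter_sd SD (bp) of replicate peak-boundary jitter.
#' @param dropout Probability a replicate misses a true peak.
#' @param fragment_length Simulated fragment length (bp).
#' @param background_per_mb Background fragments per Mb per sample.
#' @param peak_width Range (min, max) of true peak widths in bp.
#' @param min_spacing Minimum distance between planted loci (bp).
#' @param seed RNG seed; a fixed seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome = c(chrS1 = 1e7, chrS2 = 1e7),
                       n_promoter = 600, n_poised = 300,
                       n_active_with_k4me1 = 300, n_active_no_k4me1 = 300,
                       bivalent_fraction = 0.6,
                       n_diff_per_mark = c(H3K4me3 = 200, H3K27me3 = 200,
                                           H3K4me1 = 200, H3K27ac = 200),
                       n_bivalency_resolved = 50,
                       log2fc = 2, replicates = 3, dispersion = 0.1,
                       mean_fragments = 100, jitter_sd = 25, dropout = 0.05,
                       fragment_length = 200, background_per_mb = 2000,
                       peak_width = c(600, 1400), min_spacing = 5000,
                       seed = 1) {
  cfg <- list(genome = genome, n_promoter = n_promoter, n_poised = n_poised,
              n_active_with_k4me1 = n_active_with_k4me1,
              n_active_no_k4me1 = n_active_no_k4me1,
              bivalent_fraction = bivalent_fraction,
              n_diff_per_mark = n_diff_per_mark,
              n_bivalency_resolved = n_bivalency_resolved,
              log2fc = log2fc, replicates = replicates,
              dispersion = dispersion, mean_fragments = mean_fragments,
              jitter_sd = jitter_sd, dropout = dropout,
              fragment_length = fragment_length,
              background_per_mb = background_per_mb,
              peak_width = peak_width, min_spacing = min_spacing, seed = seed)
  stopifnot(length(cfg$genome) >= 1, all(cfg$genome > 0),
            cfg$n_promoter >= 0, cfg$n_poised >= 0,
            cfg$n_active_with_k4me1 >= 0, cfg$n_active_no_k4me1 >= 0,
            cfg$bivalent_fraction >= 0, cfg$bivalent_fraction <= 1,
            all(cfg$n_diff_per_mark >= 0),
            cfg$replicates >= 1, cfg$dispersion >= 0,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$jitter_sd >= 0, length(cfg$peak_width) == 2,
            cfg$peak_width[1] <= cfg$peak_width[2])
  class(cfg) <- "sim_config"
  cfg
}

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

## Planted marks per locus class (presence, independent of effects).
.class_marks <- function(class, bivalent) {
  switch(class,
    promoter = if (bivalent) c("H3K4me3", "H3K27me3") else "H3K4me3",
    poised = "H3K4me1",
    active_withK4me1 = c("H3K27ac", "H3K4me1"),
    active_noK4me1 = "H3K27ac")
}

#' Simulate a complete planted-truth ChIP-seq experiment
#'
#' Places the configured loci with at least `min_spacing` bp between
#' them, gives each locus the peaks of its class, applies the planted
#' knockout effects by scaling NB fragment means by `2^log2fc`, draws
#' per-sample fragment counts and positions, jitters and drops replicate
#' peak boundaries, and writes everything to `out_dir`:
#' `peaks/<mark>_<cond>_rep<i>.narrowPeak`,
#' `fragments/<mark>_<cond>_rep<i>.bed`, `genes.tsv` (one gene per
#' promoter locus, TSS at the locus centre) and `truth_loci.tsv` (class,
#' per-mark planted log2FC, expected enhancer state).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list: `samples` (data.frame with mark, condition,
#'   replicate, peak and fragment paths), `genes_path`, `truth_path`,
#'   `truth` (the truth data.frame), `config`.
#' @export
simulate_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(file.path(out_dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "fragments"), recursive = TRUE,
             showWarnings = FALSE)
  .with_seed(config$seed, {
    truth <- .sim_place_loci(config)
    truth <- .sim_plant_effects(config, truth)
    genes <- .sim_genes(truth)
    utils::write.table(genes, file.path(out_dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    samples <- .sim_write_samples(config, truth, out_dir)
    utils::write.table(truth, file.path(out_dir, "truth_loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })
  invisible(list(samples = samples, genes_path = file.path(out_dir, "genes.tsv"),
                 truth_path = file.path(out_dir, "truth_loci.tsv"),
                 truth = truth, config = config))
}

.sim_place_loci <- function(config) {
  classes <- c(rep("promoter", config$n_promoter),
               rep("poised", config$n_poised),
               rep("active_withK4me1", config$n_active_with_k4me1),
               rep("active_noK4me1", config$n_active_no_k4me1))
  n <- length(classes)
  if (n == 0L) stop("no loci configured")
  classes <- sample(classes)
  chrom <- rep(names(config$genome), length.out = n)
  maxw <- config$peak_width[2]
  centers <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    gaps <- config$min_spacing + maxw +
      round(stats::runif(length(idx), 0, config$min_spacing))
    pos <- cumsum(gaps)
    if (pos[length(pos)] + maxw >= config$genome[[ch]]) {
      stop("cannot place ", length(idx), " loci on ", ch,
           " without overlap; use a larger genome")
    }
    centers[idx] <- pos
  }
  bival <- rep(FALSE, n)
  prom_idx <- which(classes == "promoter")
  n_biv <- round(config$bivalent_fraction * length(prom_idx))
  bival[sample(prom_idx, n_biv)] <- TRUE
  ## per-locus, per-mark peak widths (0 = mark absent at locus)
  widths <- matrix(0L, nrow = n, ncol = length(SIM_MARKS),
                   dimnames = list(NULL, SIM_MARKS))
  for (i in seq_len(n)) {
    for (mk in .class_marks(classes[i], bival[i])) {
      widths[i, mk] <- round(stats::runif(1, config$peak_width[1],
                                          config$peak_width[2]))
    }
  }
  truth <- data.frame(locus_id = sprintf("L%04d", seq_len(n)),
                      chrom = chrom, center = centers, class = classes,
                      bivalent = bival, stringsAsFactors = FALSE)
  truth$start <- centers - maxw %/% 2L
  truth$end <- centers + maxw %/% 2L
  for (mk in SIM_MARKS) truth[[paste0("width_", mk)]] <- widths[, mk]
  for (mk in SIM_MARKS) truth[[paste0("lfc_", mk)]] <- 0
  truth$gene_id <- NA_character_
  truth$gene_id[truth$class == "promoter"] <-
    sprintf("G%04d", seq_len(sum(truth$class == "promoter")))
  truth$gene_strand <- NA_character_
  truth$gene_strand[truth$class == "promoter"] <-
    sample(c("+", "-"), sum(truth$class == "promoter"), replace = TRUE)
  truth$enhancer_state <- ""
  truth
}

.sim_plant_effects <- function(config, truth) {
  lfc <- config$log2fc
  half <- function(k) c(rep(lfc, ceiling(k / 2)), rep(-lfc, floor(k / 2)))
  nd <- config$n_diff_per_mark

  ## H3K4me3 / H3K27me3 effects live at promoters; a planted subset of
  ## bivalent promoters resolves (K4me3 up + K27me3 down at one gene).
  prom <- which(truth$class == "promoter")
  biv <- which(truth$class == "promoter" & truth$bivalent)
  n_res <- min(config$n_bivalency_resolved, length(biv),
               floor(nd[["H3K4me3"]] / 2), floor(nd[["H3K27me3"]] / 2))
  resolved <- sample(biv, n_res)
  truth$lfc_H3K4me3[resolved] <- lfc
  truth$lfc_H3K27me3[resolved] <- -lfc
  ## remaining H3K4me3 effects on other promoters
  pool <- setdiff(prom, resolved)
  k <- nd[["H3K4me3"]] - n_res
  pick <- sample(pool, min(k, length(pool)))
  truth$lfc_H3K4me3[pick] <- half(length(pick))
  ## remaining H3K27me3 effects on other bivalent promoters
  pool <- setdiff(biv, resolved)
  k <- nd[["H3K27me3"]] - n_res
  pick <- sample(pool, min(k, length(pool)))
  truth$lfc_H3K27me3[pick] <- half(length(pick))

  ## H3K4me1 effects at poised loci define poised gained/lost states.
  poised <- which(truth$class == "poised")
  pick <- sample(poised, min(nd[["H3K4me1"]], length(poised)))
  eff <- half(length(pick))
  truth$lfc_H3K4me1[pick] <- eff
  truth$enhancer_state[pick] <- ifelse(eff > 0, "poised_gained", "poised_lost")

  ## H3K27ac effects split across the two active classes.
  for (cls in c("active_withK4me1", "active_noK4me1")) {
    idx <- which(truth$class == cls)
    pick <- sample(idx, min(floor(nd[["H3K27ac"]] / 2), length(idx)))
    eff <- half(length(pick))
    truth$lfc_H3K27ac[pick] <- eff
    truth$enhancer_state[pick] <- paste0(cls, "_",
                                         ifelse(eff > 0, "gained", "lost"))
  }
  truth
}

.sim_genes <- function(truth) {
  prom <- truth[truth$class == "promoter", ]
  data.frame(gene_id = prom$gene_id, chrom = prom$chrom, tss = prom$center,
             strand = prom$gene_strand, stringsAsFactors = FALSE)[
               order(prom$gene_id), ]
}

.sim_write_samples <- function(config, truth, out_dir) {
  genome <- config$genome
  fl <- config$fragment_length
  rows <- list()
  for (mark in SIM_MARKS) {
    wcol <- truth[[paste0("width_", mark)]]
    lcol <- truth[[paste0("lfc_", mark)]]
    has <- which(wcol > 0L)
    for (cond in SIM_CONDITIONS) {
      mu <- if (cond == "KO") config$mean_fragments * 2^lcol[has]
            else rep(config$mean_fragments, length(has))
      for (rep_i in seq_len(config$replicates)) {
        stem <- sprintf("%s_%s_rep%d", mark, cond, rep_i)
        ## fragments: NB count per true peak + uniform background
        cnt <- if (config$dispersion > 0) {
          stats::rnbinom(length(has), mu = mu, size = 1 / config$dispersion)
        } else {
          stats::rpois(length(has), mu)
        }
        mid_chrom <- rep(truth$chrom[has], cnt)
        lo <- rep(truth$center[has] - wcol[has] %/% 2L, cnt)
        hi <- rep(truth$center[has] + wcol[has] %/% 2L, cnt)
        mids <- floor(stats::runif(sum(cnt), lo, hi))
        nbg <- stats::rpois(1, config$background_per_mb * sum(genome) / 1e6)
        bg_chrom <- sample(names(genome), nbg, replace = TRUE,
                           prob = genome / sum(genome))
        bg_mid <- floor(stats::runif(nbg, fl, genome[bg_chrom] - fl))
        fchrom <- c(mid_chrom, bg_chrom)
        fmid <- c(mids, bg_mid)
        fs0 <- pmax(fmid - fl %/% 2L, 0)
        fe0 <- pmin(fmid + fl %/% 2L, genome[fchrom])
        frag <- GenomicRanges::GRanges(fchrom, IRanges::IRanges(fs0 + 1, fe0))
        frag_path <- file.path(out_dir, "fragments", paste0(stem, ".bed"))
        write_regions(frag, frag_path, dialect = "bed3")
        ## replicate peak file: jitter + dropout
        kept <- has[stats::runif(length(has)) >= config$dropout]
        ps0 <- truth$center[kept] - wcol[kept] %/% 2L
        pe0 <- truth$center[kept] + wcol[kept] %/% 2L
        if (config$jitter_sd > 0) {
          ps0 <- ps0 + round(stats::rnorm(length(kept), 0, config$jitter_sd))
          pe0 <- pe0 + round(stats::rnorm(length(kept), 0, config$jitter_sd))
        }
        ps0 <- pmax(ps0, 0)
        pe0 <- pmax(pe0, ps0 + 1)
        summit <- pmin(pmax(truth$center[kept] - ps0, 0), pe0 - ps0 - 1)
        peaks <- GenomicRanges::GRanges(truth$chrom[kept],
                                        IRanges::IRanges(ps0 + 1, pe0))
        S4Vectors::mcols(peaks) <- S4Vectors::DataFrame(
          name = paste0(stem, "_", truth$locus_id[kept]),
          score = round(if (cond == "KO") config$mean_fragments * 2^lcol[kept]
                        else rep(config$mean_fragments, length(kept))),
          summit_offset = as.integer(summit))
        peak_path <- file.path(out_dir, "peaks", paste0(stem, ".narrowPeak"))
        write_regions(peaks, peak_path, dialect = "narrowPeak")
        rows[[stem]] <- data.frame(mark = mark, condition = cond,
                                   replicate = rep_i, peak_path = peak_path,
                                   fragment_path = frag_path,
                                   stringsAsFactors = FALSE)
      }
    }
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  samples
}

#' Score pipeline calls against the planted truth
#'
#' Matches calls to planted loci by at least 1 bp overlap. For enhancer
#' states, a planted differential enhancer counts as recovered when some
#' overlapping call carries its exact state; a call is a true positive
#' when it overlaps a planted locus of its state. For per-mark DBRs, a
#' planted effect is recovered when an overlapping tested window is
#' called in the planted direction.
#'
#' @param enhancer_calls `GRanges` with a `state` column (from
#'   [classify_differential_enhancers()]); `NULL` to skip.
#' @param truth Truth `data.frame` (or path to `truth_loci.tsv`).
#' @param dbr_results Optional named list (by mark) of `GRanges` with
#'   `call` columns from [test_differential_binding()].
#' @return List of data.frames: `enhancer` (per-state sensitivity and
#'   precision plus an `overall` row with accuracy and empirical FDR) and
#'   `dbr` (per-mark sensitivity and empirical FDR). Undefined rates are
#'   `NA`.
#' @export
evaluate_against_truth <- function(enhancer_calls, truth,
                                   dbr_results = NULL) {
  if (is.character(truth)) {
    truth <- utils::read.table(truth, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  truth_gr <- GenomicRanges::GRanges(truth$chrom,
                                     IRanges::IRanges(truth$start + 1,
                                                      truth$end))
  out <- list()
  if (!is.null(enhancer_calls)) {
    tr_idx <- which(nzchar(truth$enhancer_state))
    states <- ENHANCER_STATES
    calls <- enhancer_calls[S4Vectors::mcols(enhancer_calls)$state %in% states]
    cst <- S4Vectors::mcols(calls)$state
    ov <- suppressWarnings(GenomicRanges::findOverlaps(
      truth_gr[tr_idx], calls, ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    rec <- logical(length(tr_idx))
    rec[qh[cst[sh] == truth$enhancer_state[tr_idx][qh]]] <- TRUE
    ## precision: calls overlapping a planted locus of the same state
    ov <- suppressWarnings(GenomicRanges::findOverlaps(calls, truth_gr,
                                                       ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    good_call <- logical(length(calls))
    good_call[qh[truth$enhancer_state[sh] == cst[qh]]] <- TRUE
    per_state <- do.call(rbind, lapply(states, function(st) {
      ti <- tr_idx[truth$enhancer_state[tr_idx] == st]
      ci <- which(cst == st)
      data.frame(state = st,
                 n_truth = length(ti), n_called = length(ci),
                 sensitivity = if (length(ti)) mean(rec[match(ti, tr_idx)])
                               else NA_real_,
                 precision = if (length(ci)) mean(good_call[ci]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    overall <- data.frame(state = "overall", n_truth = length(tr_idx),
                          n_called = length(calls),
                          sensitivity = if (length(tr_idx)) mean(rec)
                                        else NA_real_,
                          precision = if (length(calls)) mean(good_call)
                                      else NA_real_,
                          stringsAsFactors = FALSE)
    out$enhancer <- rbind(per_state, overall)
    out$enhancer$empirical_fdr <- 1 - out$enhancer$precision
  }
  if (!is.null(dbr_results)) {
    out$dbr <- do.call(rbind, lapply(names(dbr_results), function(mark) {
      res <- dbr_results[[mark]]
      call <- S4Vectors::mcols(res)$call
      lfc_truth <- truth[[paste0("lfc_", mark)]]
      diff_idx <- which(lfc_truth != 0 & truth[[paste0("width_", mark)]] > 0)
      dir_truth <- ifelse(lfc_truth > 0, "gained", "lost")
      ov <- suppressWarnings(GenomicRanges::findOverlaps(
        truth_gr[diff_idx], res, ignore.strand = TRUE))
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      rec <- logical(length(diff_idx))
      rec[qh[call[sh] == dir_truth[diff_idx][qh]]] <- TRUE
      called_idx <- which(call != "ns")
      ov2 <- suppressWarnings(GenomicRanges::findOverlaps(
        res[called_idx], truth_gr, ignore.strand = TRUE))
      qh <- S4Vectors::queryHits(ov2); ti <- S4Vectors::subjectHits(ov2)
      good <- logical(length(called_idx))
      good[qh[lfc_truth[ti] != 0 &
                dir_truth[ti] == call[called_idx][qh]]] <- TRUE
      data.frame(mark = mark, n_truth = length(diff_idx),
                 n_called = length(called_idx),
                 sensitivity = if (length(diff_idx)) mean(rec) else NA_real_,
                 empirical_fdr = if (length(called_idx)) mean(!good)
                                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  out
}
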