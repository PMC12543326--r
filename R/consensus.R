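## Replicate-consensus peaksets.

#' Consensus peakset across replicates
#'
#' Builds the regions supported by at least `min_support` of the replicate
#' peaksets of one condition and mark. Support is counted per base: each
#' replicate contributes at most 1 to a base it covers (its peaks are
#' merged at gap 0 first), the per-base support profile is thresholded at
#' `min_support`, and maximal runs are returned. With
#' `extent = "span"` the runs are instead extended to the merged span of
#' every replicate peak touching a supported run (the DiffBind-style
#' reading).
#'
#' @param replicates List of `GRanges`, one per replicate.
#' @param min_support Minimum number of supporting replicates `k`,
#'   `1 <= k <= length(replicates)`. The classic design is 2 of 3.
#' @param extent `"support"` (base-level support runs, default) or
#'   `"span"` (merged span of peaks overlapping a supported run).
#' @return Sorted `GRanges` of consensus regions (no summits; testing
#'   windows recompute them, see [summit_windows()]).
#' @export
consensus_peaks <- function(replicates, min_support = 2,
                            extent = c("support", "span")) {
  extent <- match.arg(extent)
  if (!is.list(replicates) || length(replicates) == 0L) {
    stop("replicates must be a non-empty list of GRanges")
  }
  k <- as.integer(min_support)
  if (is.na(k) || k < 1L || k > length(replicates)) {
    stop("min_support must be between 1 and the number of replicates (",
         length(replicates), ")")
  }
  reds <- lapply(replicates, function(g) {
    GenomicRanges::reduce(sort(g, ignore.strand = TRUE), ignore.strand = TRUE)
  })
  lv <- Reduce(union, lapply(reds, GenomeInfoDb::seqlevels))
  if (length(lv) == 0L) return(GenomicRanges::GRanges())
  ## common coverage width per chromosome: declared length if known,
  ## otherwise the maximal end observed in any replicate
  maxend <- setNames(rep(0L, length(lv)), lv)
  for (g in reds) {
    if (length(g) == 0L) next
    ends <- tapply(BiocGenerics::end(g), as.character(GenomeInfoDb::seqnames(g)), max)
    maxend[names(ends)] <- pmax(maxend[names(ends)], ends)
  }
  for (g in reds) {
    sl <- GenomeInfoDb::seqlengths(g)
    known <- !is.na(sl)
    if (any(known)) maxend[names(sl)[known]] <- pmax(maxend[names(sl)[known]],
                                                     sl[known])
  }
  covs <- lapply(reds, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    GenomicRanges::coverage(g, width = maxend)
  })
  support <- Reduce(`+`, covs)
  seeds <- GenomicRanges::GRanges(IRanges::slice(support, lower = k,
                                                 rangesOnly = TRUE))
  if (extent == "span" && length(seeds) > 0L) {
    allp <- suppressWarnings(do.call(c, lapply(reds, GenomicRanges::granges)))
    hit <- subset_by_overlap(allp, seeds, max_gap = 0)
    seeds <- GenomicRanges::reduce(suppressWarnings(c(seeds, hit)),
                                   ignore.strand = TRUE)
  }
  sort(seeds, ignore.strand = TRUE)
}
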