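## Poised/active enhancer catalogs and the six-way differential
## classification from H3K4me1/H3K27ac evidence.
##
## Poised enhancer: H3K4me1 without H3K27ac.  Active enhancer: H3K27ac,
## with or without H3K4me1.  Cross-mark presence/absence checks tolerate a
## maximum gap (default 1000 bp) between peaks of the two marks.

#' Baseline poised and active enhancer catalogs
#'
#' From the consensus peaksets of one condition: poised enhancers are the
#' H3K4me1 regions with no H3K27ac peak within `max_gap` bp; active
#' enhancers are the H3K27ac regions, partitioned by H3K4me1
#' co-occurrence in the metadata column `has_k4me1`.
#'
#' @param k4me1,k27ac Consensus `GRanges` of the two marks.
#' @param max_gap Maximum tolerated gap in bp for cross-mark overlap
#'   (default 1000).
#' @return List with `poised` and `active` (`GRanges`; `active` carries a
#'   logical `has_k4me1` column).
#' @export
baseline_enhancers <- function(k4me1, k27ac, max_gap = 1000) {
  .check_chrom_dialect(list(H3K4me1 = k4me1, H3K27ac = k27ac))
  poised <- subset_by_overlap(k4me1, k27ac, max_gap = max_gap, invert = TRUE)
  active <- k27ac
  has <- rep(FALSE, length(k27ac))
  if (length(k4me1) > 0L && length(k27ac) > 0L) {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      k27ac, k4me1, maxgap = as.integer(max_gap), ignore.strand = TRUE))
    has[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  S4Vectors::mcols(active)$has_k4me1 <- has
  list(poised = poised, active = active)
}

ENHANCER_STATES <- c("poised_gained", "poised_lost",
                     "active_noK4me1_gained", "active_noK4me1_lost",
                     "active_withK4me1_gained", "active_withK4me1_lost")

#' Classify differential enhancer states in the knockout
#'
#' Applies the three criteria to the per-mark differentially bound
#' regions (DBRs), checking presence/absence against the knockout (KO)
#' consensus peaksets of the opposite mark within `max_gap` bp:
#' * gained/lost **poised**: H3K4me1 DBR up/down with **no** KO H3K27ac
#'   consensus peak nearby;
#' * gained/lost **active without H3K4me1**: H3K27ac DBR up/down with
#'   **no** KO H3K4me1 consensus peak nearby;
#' * gained/lost **active with H3K4me1**: H3K27ac DBR up/down **with** a
#'   KO H3K4me1 consensus peak nearby.
#'
#' H3K4me1 DBRs that fail the poised criterion (H3K27ac present) receive
#' no enhancer state: the criteria define none for them. They are kept in
#' the output with state `"unclassified_k4me1"` so every input DBR
#' appears exactly once.
#'
#' @param k4me1_gained,k4me1_lost,k27ac_gained,k27ac_lost `GRanges` of
#'   DBRs per mark and direction (from [call_dbrs()]).
#' @param ko_k4me1_consensus,ko_k27ac_consensus KO consensus peaksets.
#' @param max_gap Maximum tolerated cross-mark gap in bp (default 1000).
#' @return `GRanges` with metadata columns `state`, `evidence_mark`,
#'   `evidence_direction`.
#' @export
classify_differential_enhancers <- function(k4me1_gained, k4me1_lost,
                                            k27ac_gained, k27ac_lost,
                                            ko_k4me1_consensus,
                                            ko_k27ac_consensus,
                                            max_gap = 1000) {
  .check_chrom_dialect(list(
    k4me1_gained = k4me1_gained, k4me1_lost = k4me1_lost,
    k27ac_gained = k27ac_gained, k27ac_lost = k27ac_lost,
    ko_k4me1_consensus = ko_k4me1_consensus,
    ko_k27ac_consensus = ko_k27ac_consensus))
  piece <- function(dbrs, mark, direction) {
    if (length(dbrs) == 0L) {
      return(GenomicRanges::GRanges(
        state = character(0), evidence_mark = character(0),
        evidence_direction = character(0)))
    }
    gr <- GenomicRanges::granges(dbrs)
    if (mark == "H3K4me1") {
      absent <- subset_by_overlap(gr, ko_k27ac_consensus, max_gap = max_gap,
                                  invert = TRUE)
      present <- subset_by_overlap(gr, ko_k27ac_consensus, max_gap = max_gap)
      st <- c(rep(paste0("poised_", direction), length(absent)),
              rep("unclassified_k4me1", length(present)))
      out <- c(absent, present)
    } else {
      absent <- subset_by_overlap(gr, ko_k4me1_consensus, max_gap = max_gap,
                                  invert = TRUE)
      present <- subset_by_overlap(gr, ko_k4me1_consensus, max_gap = max_gap)
      st <- c(rep(paste0("active_noK4me1_", direction), length(absent)),
              rep(paste0("active_withK4me1_", direction), length(present)))
      out <- c(absent, present)
    }
    S4Vectors::mcols(out)$state <- st
    S4Vectors::mcols(out)$evidence_mark <- rep(mark, length(out))
    S4Vectors::mcols(out)$evidence_direction <- rep(direction, length(out))
    out
  }
  calls <- suppressWarnings(c(
    piece(k4me1_gained, "H3K4me1", "gained"),
    piece(k4me1_lost, "H3K4me1", "lost"),
    piece(k27ac_gained, "H3K27ac", "gained"),
    piece(k27ac_lost, "H3K27ac", "lost")))
  sort(calls, ignore.strand = TRUE)
}
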