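#!/usr/bin/env Rscript

# Stage 4 — six-way differential enhancer-state classification.
#
# H3K4me1 DBRs with no KO H3K27ac consensus peak within 1000 bp become
# gained/lost poised enhancers; H3K27ac DBRs split into gained/lost
# active enhancers with or without a KO H3K4me1 consensus peak nearby.
# Also records the baseline WT poised/active catalogs.

suppressPackageStartupMessages({
  library(enhancerstate)
  library(GenomicRanges)
})

rd <- function(fmt, ...) read_regions(sprintf(fmt, ...))

base <- baseline_enhancers(rd("results/consensus/H3K4me1_WT.bed"),
                           rd("results/consensus/H3K27ac_WT.bed"),
                           max_gap = 1000)
message("WT baseline: ", length(base$poised), " poised, ",
        length(base$active), " active enhancers (",
        sum(base$active$has_k4me1), " with H3K4me1)")
write_regions(base$poised, "results/baseline_poised_WT.bed")
write_regions(base$active, "results/baseline_active_WT.bed")

calls <- classify_differential_enhancers(
  rd("results/dbr_H3K4me1_gained.bed"), rd("results/dbr_H3K4me1_lost.bed"),
  rd("results/dbr_H3K27ac_gained.bed"), rd("results/dbr_H3K27ac_lost.bed"),
  rd("results/consensus/H3K4me1_KO.bed"),
  rd("results/consensus/H3K27ac_KO.bed"),
  max_gap = 1000)
tab <- data.frame(chrom = as.character(seqnames(calls)),
                  start = start(calls) - 1L, end = end(calls),
                  state = calls$state, evidence_mark = calls$evidence_mark,
                  evidence_direction = calls$evidence_direction)
write.table(tab, "results/enhancer_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
counts <- table(calls$state)
for (st in names(counts)) message(st, ": ", counts[[st]])
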