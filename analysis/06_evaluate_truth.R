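#!/usr/bin/env Rscript

# Stage 6 — score every call against the planted ground truth.

suppressPackageStartupMessages({
  library(enhancerstate)
  library(GenomicRanges)
})

truth <- "results/sim/truth_loci.tsv"
calls_df <- read.table("results/enhancer_calls.tsv", header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
calls <- GRanges(calls_df$chrom, IRanges(calls_df$start + 1L, calls_df$end),
                 state = calls_df$state)
dbrs <- lapply(setNames(nm = c("H3K4me3", "H3K27me3", "H3K4me1", "H3K27ac")),
               function(mark) {
  d <- read.table(sprintf("results/dbr_%s.tsv", mark), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
  GRanges(d$chrom, IRanges(d$start + 1L, d$end), call = d$call)
})

m <- evaluate_against_truth(calls, truth, dbr_results = dbrs)
write.table(m$enhancer, "results/truth_enhancer_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(m$dbr, "results/truth_dbr_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ov <- m$enhancer[m$enhancer$state == "overall", ]
message("enhancer-state recovery: sensitivity ", round(ov$sensitivity, 3),
        ", precision ", round(ov$precision, 3))
for (i in seq_len(nrow(m$dbr))) {
  message(m$dbr$mark[i], " DBRs: sensitivity ",
          round(m$dbr$sensitivity[i], 3), ", empirical FDR ",
          round(m$dbr$empirical_fdr[i], 3))
}
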