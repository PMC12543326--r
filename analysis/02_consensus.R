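#!/usr/bin/env Rscript

# Stage 2 — replicate-consensus peaksets.
#
# For every histone mark and genotype, keep the regions supported by at
# least 2 of the 3 replicate peak files (base-level support).

suppressPackageStartupMessages(library(enhancerstate))

samples <- read.table("results/sample_sheet.tsv", header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
dir.create("results/consensus", showWarnings = FALSE, recursive = TRUE)

for (mark in unique(samples$mark)) {
  for (cond in unique(samples$condition)) {
    sel <- samples[samples$mark == mark & samples$condition == cond, ]
    reps <- lapply(sel$peak_path, read_regions)
    cons <- consensus_peaks(reps, min_support = 2)
    path <- sprintf("results/consensus/%s_%s.bed", mark, cond)
    write_regions(cons, path)
    message(mark, " ", cond, ": ",
            paste(vapply(reps, length, integer(1)), collapse = "/"),
            " replicate peaks -> ", length(cons), " consensus regions")
  }
}
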