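#!/usr/bin/env Rscript

# Stage 1 — generate the planted in-silico experiment.
#
# Emulates the study design: 3 replicate clones x 2 genotypes (WT, KO) x
# 4 histone marks (H3K4me3, H3K27me3, H3K4me1, H3K27ac) on two synthetic
# 10 Mb chromosomes, with 200 planted differential regions per mark at
# |log2FC| = 2, NB fragment counts (phi = 0.1, mean 100 per peak),
# replicate peak jitter (sd 25 bp) and 5% dropout.  Writes narrowPeak +
# fragment BED files and the ground-truth locus table.

suppressPackageStartupMessages(library(enhancerstate))

seed <- if (length(commandArgs(TRUE)) >= 1) {
  as.integer(commandArgs(TRUE)[1])
} else 1L
out <- "results/sim"

cfg <- sim_config(seed = seed)
sim <- simulate_experiment(cfg, out)
write.table(sim$samples, "results/sample_sheet.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- sim$truth
message("simulated ", nrow(truth), " loci on ",
        length(cfg$genome), " chromosomes (seed ", seed, ")")
message("locus classes: ",
        paste(names(table(truth$class)), table(truth$class),
              sep = "=", collapse = ", "))
message("planted enhancer states: ",
        sum(nzchar(truth$enhancer_state)), " loci")
message("bundle written under ", out, "; sample sheet in results/sample_sheet.tsv")
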