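#!/usr/bin/env Rscript

# Stage 5 — promoter annotation and the bivalency-resolution overlap test.
#
# Genes are assigned to DBRs through promoter windows (5000 bp upstream
# to 100 bp downstream of the TSS).  The gene sets "gained H3K4me3" and
# "lost H3K27me3" are intersected and tested for association with a 2x2
# chi-squared over all genes reachable from either mark's tested windows.

suppressPackageStartupMessages({
  library(enhancerstate)
  library(GenomicRanges)
})

genes <- read_gene_models("results/sim/genes.tsv")
dbr <- function(mark) {
  d <- read.table(sprintf("results/dbr_%s.tsv", mark), header = TRUE,
                  sep = "\t", stringsAsFactors = FALSE)
  GRanges(d$chrom, IRanges(d$start + 1L, d$end), call = d$call)
}
k4 <- dbr("H3K4me3")
k27 <- dbr("H3K27me3")
ann <- function(gr) annotate_regions(gr, genes, upstream = 5000,
                                     downstream = 100)

set_a <- gene_sets_from_dbrs(ann(k4[k4$call == "gained"]))
set_b <- gene_sets_from_dbrs(ann(k27[k27$call == "lost"]))
universe <- union(gene_sets_from_dbrs(ann(k4)), gene_sets_from_dbrs(ann(k27)))
res <- overlap_chi_squared(set_a, set_b, universe)

message(length(set_a), " genes gain H3K4me3; ", length(set_b),
        " genes lose H3K27me3; ", res$overlap,
        " genes do both (universe ", length(universe), ")")
message("chi-squared = ", signif(res$statistic, 6), ", p = ",
        signif(res$pvalue, 3))
jsonlite::write_json(list(n_gained_H3K4me3 = length(set_a),
                          n_lost_H3K27me3 = length(set_b),
                          overlap = res$overlap,
                          universe = length(universe),
                          chi_squared = res$statistic,
                          pvalue = res$pvalue),
                     "results/bivalency_overlap.json", auto_unbox = TRUE,
                     digits = NA)
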