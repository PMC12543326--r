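# Scaled-down simulation configuration (same architecture as the default,
# ~8x smaller) used by the unit tests; acceptance checks use the default.
small_config <- function(...) {
  sim_config(genome = c(chrS1 = 2e6, chrS2 = 2e6),
             n_promoter = 80, n_poised = 40, n_active_with_k4me1 = 40,
             n_active_no_k4me1 = 40,
             n_diff_per_mark = c(H3K4me3 = 24, H3K27me3 = 24,
                                 H3K4me1 = 24, H3K27ac = 24),
             n_bivalency_resolved = 6, background_per_mb = 500, ...)
}

small_config_args <- function(...) {
  list(genome = c(chrS1 = 2e6, chrS2 = 2e6),
       n_promoter = 80, n_poised = 40, n_active_with_k4me1 = 40,
       n_active_no_k4me1 = 40,
       n_diff_per_mark = c(H3K4me3 = 24, H3K27me3 = 24,
                           H3K4me1 = 24, H3K27ac = 24),
       n_bivalency_resolved = 6, background_per_mb = 500, ...)
}
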