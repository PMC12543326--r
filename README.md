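# enhancerstate

Differential histone-mark ChIP-seq analysis for two-condition designs:
replicate-consensus peaksets, summit-window count testing, six-way
poised/active enhancer gain/loss classification, promoter-window gene
annotation, and a chi-squared gene-overlap test for bivalency resolution
— with a planted-truth simulator so the whole pipeline can be validated
end to end.

The package targets the downstream half of a typical knockout-vs-wildtype
epigenome study (e.g. IκBα-KO vs WT mouse embryonic stem cells profiled
for H3K4me3, H3K27me3, H3K4me1 and H3K27ac with three replicate clones
per genotype). It starts from called peaks (narrowPeak/BED) and fragment
intervals; trimming, alignment and peak calling are out of scope.

## The statistics at its core

**Consensus.** For each mark and condition, a base `x` is in the
consensus when `support(x) = #{replicates with a peak covering x} >= k`
(default `k = 2` of `n = 3`).

**Differential binding.** Testing intervals are windows
`[s - w, s + w)` centred on the consensus summit `s` (region midpoint
when no summit is available), with `w = 500` bp, or 150 bp for the sharp
H3K4me3 mark. Fragment-midpoint counts `y_rs` are modelled as negative
binomial, `y_rs ~ NB(mu_rs, phi_r)` with `Var = mu + phi mu^2`.
Composition is normalised by TMM (trimmed mean of M-values; trim 30% on
M, 5% on A, precision-weighted). Dispersions are method-of-moments
estimates shrunk toward the common value with prior weight
`prior_df / (prior_df + df_r)`. The two genotypes are compared with a
conditional exact test: with a shared dispersion, the group sum given the
window total follows a beta-binomial-type law free of the unknown mean,
and the two-sided p-value sums all outcomes at most as probable as the
observed one (at `phi = 0` this is exactly the conditional binomial
test). P-values are Benjamini–Hochberg adjusted; a window is a
differentially bound region (DBR) when `q < 0.05`, *gained* if
`log2FC > 0` and *lost* if `log2FC < 0` (KO vs WT).

**Enhancer states.** Cross-mark presence/absence tolerates a maximum gap
of 1000 bp. Gained/lost *poised* enhancers are H3K4me1 DBRs with no KO
H3K27ac consensus peak nearby; gained/lost *active* enhancers are
H3K27ac DBRs, split by the presence of a KO H3K4me1 consensus peak.

**Bivalency resolution.** DBRs are assigned to genes through promoter
windows (5000 bp upstream to 100 bp downstream of the TSS,
strand-aware; nearest TSS otherwise). The gene sets "gained H3K4me3" and
"lost H3K27me3" are intersected and tested with Pearson's chi-squared
(1 df, no continuity correction) on the 2×2 table over the gene universe.

## Worked example

The numbered drivers under `analysis/` run the whole study on the
default simulated experiment (1500 loci, 200 planted DBRs per mark at
|log2FC| = 2, dispersion 0.1, 3 + 3 replicates, seed 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_consensus.R
Rscript analysis/03_differential_binding.R
Rscript analysis/04_enhancer_states.R
Rscript analysis/05_bivalency_overlap.R
Rscript analysis/06_evaluate_truth.R
```

Output (abridged):

```
H3K4me3 WT: 575/557/569 replicate peaks -> 595 consensus regions
H3K4me3: 600 windows (300 bp); 124 gained, 88 lost at FDR < 0.05
H3K4me1: 600 windows (1000 bp); 105 gained, 103 lost at FDR < 0.05
poised_gained: 101
poised_lost: 99
active_withK4me1_gained: 50
124 genes gain H3K4me3; 119 genes lose H3K27me3; 58 genes do both (universe 600)
chi-squared = 71.3509, p = 2.99e-17
enhancer-state recovery: sensitivity 0.985, precision 0.98
H3K4me3 DBRs: sensitivity 0.985, empirical FDR 0.071
```

So against the planted truth (100 gained/100 lost poised, 50 of each
active state, 200 DBRs per mark), the pipeline recovers 98.5% of the
planted enhancer states with 2% false calls, and DBR calling holds its
FDR near the nominal 5%. The 58-gene overlap recovers the planted
bivalency-resolution architecture (chi-squared rejects independence).

The same run as a single call:

```r
library(enhancerstate)
report <- run_pipeline(list(simulate = list(seed = 1)), "out/")
```

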