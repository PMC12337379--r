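# uromethylome

Genome-wide differential-methylation analysis of urinary cell-pellet DNA
for non-invasive bladder-cancer (BC) detection, starting from nanopore
5mC pileups in bedMethyl format.

Urine from BC patients contains an admixture of tumour- and normal-cell
DNA. Long-read sequencing with direct 5mC calling measures, at every CpG
site, a modified count `n_mod` out of `n_valid` confident calls; the
methylation fraction is `n_mod / n_valid`. Comparing a BC group against a
non-cancer group, tumour DNA manifests as spatially correlated shifts —
promoter hypermethylation and broad intergenic/repeat hypomethylation —
diluted linearly by the per-sample tumour fraction. This package
implements the full analysis chain around that signal and a synthetic
cohort generator with a ground-truth ledger for validating every stage.

## The model

**Segmentation.** Per CpG site, counts are pooled within each group and
scored with a binomial log-likelihood ratio of "Different" (free
per-group rates) versus "Same" (one pooled rate):

```
llr = [ l(mA, tA; pA) + l(mB, tB; pB) ] - [ l(mA, tA; p) + l(mB, tB; p) ]
l(m, t; p) = m log p + (t - m) log(1 - p),   pA = (mA + e) / (tA + 2e)
```

A two-state hidden Markov model (states *Same*/*Different*, sticky
transitions, chains broken at gaps > 1 kb) is decoded by Viterbi; maximal
runs of *Different* become candidate DMR segments carrying the summed
`llr` as their HMM score, pooled group means, and deltas on the fraction
and log2 scales.

**Selection.** Candidates are filtered on length, HMM score, CpG count
and `|delta|`, then triaged with a two-sided Mann–Whitney test on
per-sample coverage-weighted segment scores (exact null when there are no
ties); selection uses raw p < 0.05 with Benjamini–Hochberg values
reported alongside.

**Validation layers.** Label-permutation re-runs of the whole pipeline
and random-segment preranked GSEA provide the two null models; genomic
context (promoter ±3 kb > exonic > intronic > intergenic), repeat
content, metaplots with ±500 bp flanks, delta-ranked GSEA with
sign-matched NES, shallow 500-kb-bin copy-number burden, and PCA /
hierarchical clustering / replicate correlation complete the analysis.

## Worked example

Simulate a 13 BC vs 8 non-BC cohort on a 2 × 3 Mb genome with 10 planted
hypermethylated and 12 hypomethylated regions, call and select DMRs, and
score recovery against the truth ledger:

```r
library(uromethylome)

cfg    <- sim_config(chrom_sizes = c(chr1 = 3e6, chr2 = 3e6), n_genes = 60L,
                     n_hyper = 10L, n_hypo = 12L)
ann    <- simulate_annotation(cfg, seed = 11)
cohort <- simulate_cohort(cfg, ann, seed = 12)
cm     <- build_cohort_matrix(cohort$methylomes)
cm
#> cohort_matrix: 42943 CpG sites x 21 samples (13 BC, 8 nonBC), min_cov = 3

segs <- viterbi_segment(pool_evidence(cm))
sel  <- select_dmrs(segs, cm)
str(sel$summary[c("n_candidates", "n_selected", "n_hyper", "n_hypo",
                  "mean_abs_delta_log2_hyper", "mean_abs_delta_log2_hypo")])
#> List of 6
#>  $ n_candidates             : int 159
#>  $ n_selected               : int 22
#>  $ n_hyper                  : int 10
#>  $ n_hypo                   : int 12
#>  $ mean_abs_delta_log2_hyper: num 1.94
#>  $ mean_abs_delta_log2_hypo : num 0.714

rec <- evaluate_recovery(sel$table[selected == TRUE], cohort$truth)
c(rec$sensitivity, rec$base_precision)
#> [1] 1.000 0.990
```

All 22 planted regions are recovered (sensitivity 1.0) and 99% of called
bases lie inside planted intervals; hypermethylated DMRs show the larger
log2 deltas (1.94 vs 0.71), the asymmetry expected when promoters jump
from a low baseline while hypomethylation erodes a high one. The full
orchestration — simulation, segmentation, selection, both null models,
context annotation, GSEA, copy number and discrimination, with a
reproducibility manifest — is available as `run_pipeline(outdir, seed)`.

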