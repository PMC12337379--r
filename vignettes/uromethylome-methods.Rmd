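---
title: "Methods: urinary-methylome differential analysis and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary-methylome differential analysis and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `uromethylome`, the
design decisions that were genuinely open, the synthetic cohort the
package validates itself against, and the limits of what that validation
shows about real data.

## The measurement model

Urinary cell-pellet DNA from a cancer patient is a mixture: a tumour
fraction `tf` of tumour-cell DNA diluted in normal-cell DNA. At CpG site
`i` of sample `s`, direct 5mC calling yields `n_mod` modified calls out
of `n_valid` confident calls; the underlying expected fraction is

```
p_is = tf_s * pT_i + (1 - tf_s) * pN_i
```

where `pN` is the normal methylome (low at promoter CpG islands, high
elsewhere) and `pT` the tumour methylome. Differential signal therefore
scales linearly with `tf_s`, which is the central obstacle at realistic
tumour fractions and shallow (2–5x) coverage: single sites are
uninformative and evidence must be aggregated along the genome.

## Two-state HMM segmentation

Counts are pooled per group (the cancer group A and control group B) at
every site and scored with a binomial log-likelihood ratio (LLR) of the
two-rate versus the pooled-rate model, with a pseudocount `eps = 0.5`
shrinking the rate estimates. A two-state HMM over the ordered sites —
states *Same* and *Different* — captures the spatial correlation of
methylation changes; Viterbi decoding yields maximal *Different* runs as
candidate segments.

**Emission offset.** The *Same* state scores 0 and the *Different* state
scores `llr - llr_threshold` per site. The offset is essential rather
than cosmetic: the LLR of a free-versus-pooled binomial comparison is
half a 1-df chi-square under the null, so its null expectation is ~0.5
nats per site and any long stretch of null sites would otherwise
accumulate enough raw LLR to out-score the bounded transition penalty
and be decoded as one endless *Different* run. Between-sample
overdispersion (real in this design, see the generator below) raises the
null mean further. The default of 2 nats sits at roughly the null 95th
percentile, so the *Different* state only pays for itself where per-site
evidence exceeds ordinary sampling noise. Setting `llr_threshold = 0`
recovers the plain LLR-emission model.

**Transitions and chain breaks.** Sticky defaults
(`p_stay_same = 0.95`, `p_stay_diff = 0.90`, start probability 0.95 for
*Same*) favour *Same* a priori so isolated noisy sites do not seed
segments. Chains restart at chromosome boundaries and at inter-CpG gaps
above `max_gap = 1000` bp; restarting is deliberate — paying many
transitions to bridge a CpG desert would let unrelated regions merge.
Segments never span a chain break even when both sides are decoded
*Different*. Viterbi ties resolve to *Same*, making the decoding
deterministic. Forward–backward posteriors are available as a diagnostic
under exactly the same model. Both the decoder and the posteriors are
tested against exhaustive 2^n path enumeration on small instances.

## Filtering and Mann–Whitney triage

Candidates pass four thresholds — length ≥ 500 bp, HMM score ≥ 20 nats,
≥ 5 member CpGs, `|delta_frac|` ≥ 0.2 — all configuration, not
constants, since the appropriate stringency depends on depth and cohort
size. Surviving segments get a per-sample score: the coverage-weighted
fraction `sum(n_mod) / sum(n_valid)` over member sites, which is robust
at 2–5x where a mean of per-site fractions is dominated by 1-read sites.
A two-sided Mann–Whitney test compares the score vectors of the two
groups (exact null distribution when no ties, tie-corrected normal
approximation otherwise); selection uses raw p < 0.05, with BH-adjusted
values reported alongside rather than used as the gate — at 13-vs-8
scale with thousands of candidates, rank tests cannot clear an FDR
threshold, and the burden of evidence is carried by the null models
below.

## Null models

Two complementary randomisations quantify chance discovery:

* **Label permutation** re-partitions the cohort into pseudo-groups of
  the true sizes, 50 times by default, and re-runs pooling, HMM,
  filtering and testing through the *same functions* as the true
  analysis, recording selected-DMR counts. A real signal shows as a
  true-label count far above the permutation maximum.
* **Random segment sets** draw 50 sets of ~5% of the filtered candidate
  pool (the pool-size-scaled analogue of drawing the selected-set size
  from the full filtered set) and run preranked GSEA per set. At desk
  scale the stringent filter leaves a pool dominated by genuine DMRs, so
  a 5% draw yields a gene ranking too sparse for pathways to reach the
  eligibility size — the desk-scale mechanism by which random draws
  dilute coherent pathway signal to a median of zero significant
  pathways.

## Genomic context, repeats and metaplots

Each DMR receives exactly one context class by any-overlap precedence
promoter (TSS ± 3 kb) > exonic > intronic > intergenic. Any-overlap was
chosen over majority-overlap because long hypomethylated blocks often
graze an annotation feature; precedence makes the call stable and
auditable. Gene association is broader than the class: a DMR is linked
to every gene whose promoter or body it overlaps, which is what the
gene-delta aggregation consumes. Context enrichment of hyper versus hypo
calls uses a Pearson chi-square without continuity correction plus the
promoter odds ratio. Repeat content is exact interval arithmetic on the
merged repeat set. Metaplots rescale each DMR body to 50 bins with
25-bp-binned ±500 bp flanks and pool counts per group; the discriminating
signature is group separation inside the body that vanishes in the
flanks (the absolute flank level depends on where the DMR sits — island
flanks are high-methylation background, not low).

## Delta-ranked GSEA

Gene deltas are the mean `delta_log2` over a gene's promoter/body DMRs;
the mean (not the extremum) was chosen so a gene hit by one strong and
one weak DMR is not driven by the outlier. The ranking is decreasing
delta with lexicographic tie-breaks, hence fully deterministic. The
enrichment score is the classical weighted Kolmogorov–Smirnov running
sum (weight exponent 1); when the positive and negative extrema tie in
magnitude the score is defined as 0 (the convention of reference GSEA
implementations, against which the statistic is cross-checked). The
null permutes gene labels — with a single cohort-level delta list there
is no sample dimension left to permute — and NES normalises by the mean
magnitude of sign-matched null scores; p-values are the sign-matched
exceedance fraction floored at `1/n_perm`, BH-adjusted across eligible
pathways (5–500 genes in the ranking), with significance at the dual
threshold `p_adj < 0.05` and `|NES| >= 1.5`. Type-I error at p < 0.05 is
verified at 0.05 ± 0.02 under shuffled deltas.

## Copy-number burden

Reads are binned at 500 kb (the low-pass regime appropriate to 2–5x
data), scaled to per-sample median 1, divided by a cohort-internal
reference (per-bin median of the control samples) and log2-transformed
with median recentring. Calls threshold a 5-bin rolling median at ±0.2
with isolated single-bin calls reverted; burden is the called percentage
of analysed genome, compared between groups by the same Mann–Whitney
routine. The ±0.2 threshold detects arm-scale events down to roughly
tf ≈ 0.3 (a diluted single-copy gain at tf = 0.5 sits at log2 1.25 ≈
0.32) while staying silent at tf ≤ 0.1 — deliberately mirroring the
non-detection of copy-number change in low-tumour-fraction samples. GC
and mappability correction are intentionally absent: the synthetic data
carry no such biases, and for real data a dedicated caller with loess
correction and blacklists should replace this stage (a documented
limitation, not an oversight).

## Discrimination

PCA runs on the centred (unscaled) DMR score matrix — fraction-scale
scores are already commensurate, and scaling would up-weight
low-coverage noise; missing scores are imputed by the per-DMR cohort
mean and counted. Component signs are fixed (largest-magnitude loading
positive) for reproducibility. Hierarchical clustering defaults to
Ward.D2 on Euclidean distances with a k = 2 cut; correlation distance
and complete/average linkage are available. Replicate concordance is
Pearson correlation over shared covered sites, or over per-DMR pooled
scores when restricted to a DMR set — the restriction averages away
per-site sampling noise, which is why the DMR-restricted correlation of
a high/low-coverage replicate pair exceeds its all-site correlation.

## The synthetic cohort

The generator emulates the study conditions the analysis is built for:
13 BC samples with tumour fractions uniform in 0.3–0.65 and 8 non-BC
samples at zero, mean depth 20x (a `mixed` tier layout with ~3x
multiplexed samples is available), on a desk-scale genome of 2 × 10 Mb
with 200 genes, TSS-centred CpG islands (±1 kb at ~40 bp spacing inside,
~150 bp outside) and repeats tiling ~52% of intergenic space.

Planted effects: 20 hypermethylated intervals (70% on promoter islands,
the rest on island/shore-like low-baseline intervals elsewhere — a gain
is only a gain if the baseline is low) rising to 0.85, and 50
hypomethylated intervals (70% seeded in intergenic repeats, 30% in gene
bodies) falling to 0.10, each guaranteed ≥ 10 CpGs and mutually
disjoint; a global 0.05 hypomethylation shift outside promoters; one
clonal copy-4 event covering 20% of the genome in all BC samples; and 50
pathway gene sets of which one designated set (size 20) draws 60% of its
members from the planted promoter-hyper genes. The hypo majority (50 vs
20) and the resulting delta asymmetry (hyper log2 deltas ~2, hypo ~0.7)
reproduce the landscape asymmetry of tumour methylomes as a truth
property. Noise is a per-sample, per-region logit-normal jitter
(sd 0.3, 5-kb background regions) — chosen over per-site beta-binomial
because it preserves the between-sample heterogeneity that the
Mann–Whitney stage needs in order to be a meaningful test; coverage is
Poisson, modified counts binomial. All stages draw from named substream
seeds of one master seed, so cohorts, pipelines and outputs are
byte-reproducible.

What the generator does **not** emulate — and hence what green tests do
not show about real data: GC/mappability coverage bias, fragment-length
structure, read-level errors, subclonal heterogeneity (one clonal tumour
profile per cohort), continuous effect-size spectra (planted effects are
near-binary, so real borderline DMRs will behave worse than synthetic
ones), haplotype effects, and SNVs.

## Problem sizes and numerical choices

The test suite and acceptance analyses run at the default desk scale
(~140k CpGs × 21 samples, ~10 s to simulate and segment), with 50 label
permutations, 50 random segment sets, and 1000 GSEA permutations; HMM
oracle checks enumerate all paths for up to 10 sites. Numerical
conventions collected in one place: LLRs are clipped at 0; `delta_log2`
uses a 0.01 pseudo-fraction on both group means; Viterbi ties go to
*Same*; ES extrema ties give 0; GSEA p-values are floored at `1/n_perm`;
empty-coverage segment scores are `NA` and excluded from tests (a
segment unscorable in every sample is flagged); CNV normalisation adds
0.5 to counts to stabilise empty shallow-coverage bins; zero-reference
bins are masked.

## Known limitations

Threshold defaults (filter stringency, CNV ±0.2, NES 1.5) are tuned to
the default cohort conditions and exposed as configuration; real cohorts
with different depths or tumour-fraction ranges will need them revisited.
The Mann–Whitney stage ignores covariates (age, batch, depth tier). The
label-permutation null does not exclude partitions close to the true
labels. The CNV stage is a burden estimator, not a full caller. The
package starts from bedMethyl pileups; basecalling, alignment and
modification calling are out of scope.
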