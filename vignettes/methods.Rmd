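---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`dacpdx` analyses pre-clinical decitabine trials in T-LBL PDX models:
methylation arrays, RNA-seq counts, Hi-C compartment calls and in-vivo
outcome tables. This vignette explains the statistical models behind each
stage, the tunable parameters and their defaults, what the synthetic
cohort does and does not emulate, and the design decisions taken where
several reasonable conventions exist.

## Methylation profiling

**QC.** An array entry is treated as missing when its detection p-value
exceeds `detection_alpha` (default 0.05, strictly greater: an entry at
exactly 0.05 is retained). Probes flagged as multimapping, carrying a SNP
within 5 bp of the interrogated CpG, or acting as meQTLs are removed
entirely. QC is idempotent and logs the counts it masks and drops.

**Imputation.** K-nearest-neighbour imputation operates in probe space
(`k = 10`, Euclidean distance over the samples in which the target probe
is observed; donors are fully observed probes). Probe-space KNN is the
standard array convention; whether sample-space KNN would behave
differently at these cohort sizes is untested. Imputed values are clipped
to [0, 1]. The pipeline imputes only the EpiTOC panel, because that is
the one downstream statistic that requires complete data — CIMP
percentages and delta-beta use available-case computations. A probe
missing everywhere cannot be imputed and raises an error naming it.

**CIMP classification.** The CIMP methylation percentage of a sample is
the percentage of evaluable panel CpGs with β at or above
`methylated_beta` (default 0.3). A sample is CIMP+ when that percentage
is strictly greater than 40. The 0.3 "methylated" cutoff is a
configurable convention — the classification literature defines the
panel and the 40% cut but not a universal per-probe cutoff — so it is
surfaced in the run configuration and logs rather than hidden. Because
of the strict cut, a sample at 43.3% is CIMP+ while one at exactly 40%
is CIMP−.

**EpiTOC mitotic age.** The epigenetic timer-of-cancer age is the
arithmetic mean β over the EpiTOC panel probes present on the array
after QC, a number in [0, 1] that rises with the tissue's accumulated
cell divisions.

**Differential methylation.** Δβ is defined on group means:
mean(treated β) − mean(vehicle β), available-case per probe. A probe is
DM when |Δβ| > 0.2, strictly; the aggregation over replicates is the
simplest estimator consistent with a per-probe Δβ, and the strict
inequality makes the boundary case unambiguous. Probes with no observed
value in an arm are excluded and reported.

## Expression analysis

**Size factors** are median-of-ratios against the geometric-mean
pseudo-reference over genes expressed in every sample. When no such gene
exists the function stops and suggests a pseudo-reference fallback
rather than silently switching estimators.

**The NB Wald test.** Each gene is modelled as negative binomial with a
mean per contrast group (estimated as size-factor-normalized group
totals, with a half-count shift so single-group zeros stay finite) and a
gene-wise dispersion. Dispersions are estimated by moments from
normalized counts, then shrunk toward a parametric trend
`a0 + a1/mu` fitted across genes by least squares. Two numerical choices
matter here:

* the trend is fitted on the *raw* moment estimates including negative
  ones — restricting to positive estimates selects the upper tail and
  biases the trend upward, which in turn deflates every Wald statistic;
* the shrinkage weight is `prior_n / (prior_n + df)` with `prior_n = 10`
  and `df = n − 2`, i.e. roughly 60/40 trend/gene at n = 8, reflecting
  how little information four replicates per arm carry about a
  second-moment parameter.

The Wald statistic uses the NB Fisher information at the estimates and a
standard normal reference. Under null simulations at the cohort's design
(4 vs 4, dispersion 0.05) the empirical type-I error at α = 0.05 sits
near 0.055; the test suite asserts the [0.03, 0.07] band. The test is
label-symmetric, and BH adjustment is applied across all tested genes
(all-zero genes excluded and logged).

**Preranked GSEA** uses the weighted Kolmogorov–Smirnov running sum with
weight exponent 1 and a gene-permutation null; the desktop-tool
parameters this emulates are not published, and weight 1 with gene
permutation is the common preranked default. NES divides the observed
score by the mean |null score| of the same sign; the permutation p uses
the same-sign null with an add-one correction, so it is never 0 and
never smaller than 1/(n_same + 1). Ties in the ranking are broken by
gene id, making results a function of the ranking values only. Sets
outside [5, 500] genes after filtering are skipped and listed.

**Sensitivity signature.** From the baseline (vehicle-only) comparison
of sensitive versus less-sensitive subgroups, genes with |log2FC| > 1
and adjusted p < 0.05 are ranked by ascending adjusted p, ties by
descending |log2FC|, ties by gene id, and truncated to 70. The filter
thresholds follow the emulated study; the |log2FC| reading of its
fold-change criterion is the standard volcano-plot convention (a plain
|FC| > 1 would be vacuous), and the ranking key is fixed here for
determinism because no ranking rule is published.

## Integration

A gene is hypomethylated as soon as one hypo DM probe links to it; a
probe linked to several genes contributes to each (annotation manifests
are many-to-many), and gene body / promoter / enhancer links are tallied
separately. This "≥ 1 DM probe" rule matches the observation that
DM-annotated gene counts run far larger than DE counts. Joint counts use
the adjusted-p DE rule by default for consistency with the DE stage; a
`de_rule = "raw"` flag reproduces analyses that join on raw p < 0.05.
Genes absent from the expression data stay in the methylation-only
counts but are excluded from joint counts. Cross-model concordance
returns genes present in at least k of n per-model joint sets; it is
monotone in k.

## Chromatin compartments

Consensus calling is unanimity: a 50 kb bin is A (open) only if every
sample calls it A, B only if every sample calls it B, ambiguous
otherwise — the strictest reading of consensus-with-discordance-removal.
Features are assigned by a single anchor point (a probe's coordinate;
a gene's transcription start, the conventional regulatory anchor, with a
midpoint option); features in ambiguous bins or outside the map are
excluded. The enrichment statistic is a relative risk of open-chromatin
location: the feature set's open proportion over the open proportion of
the background *excluding* the feature set. Full precision is kept
internally; two-decimal rounding is applied only when printing.

## Pre-clinical readouts

The absolute hCD45+ count per μL of stained blood follows the
counting-bead protocol formula exactly as used in the emulated
experiments:

```
count = (cell events × bead volume) /
        (bead events × cell volume × bead concentration)
```

Dimensionally this differs from the usual bead-counting convention
(which multiplies, rather than divides by, the bead concentration); the
protocol rendering may carry a typesetting artifact, so the conventional
variant is available as `formula = "standard"` and neither is asserted
to be the intended one. Normalized tumor growth divides the treated
arm's day-5/day-1 expansion of mean absolute counts by the vehicle
arm's. Kaplan–Meier estimation and the log-rank test are delegated to
the `survival` package; `logrank_test()` additionally offers a
permutation p-value (label resampling) for the small-arm situations
where the χ² reference is doubtful, and reports the conventional
significance band (*, **, ***). Survival time runs from treatment start,
and no multiplicity correction is applied across per-model comparisons,
matching per-comparison reporting practice.

## The synthetic cohort

The generator produces the statistical structure the analyses assume, at
desk scale, from one master seed (every stage draws from a named
substream, so identical configs are byte-identical).

* **Design**: 5 models, models 1–3 "sensitive", 4–5 "less sensitive";
  vehicle and DAC arms with 4 replicates (3 supported); 20,000 probes,
  3,000 genes, a 1099-CpG CIMP panel and a 200-CpG EpiTOC panel.
* **Methylation**: probe baselines from a two-component Beta mixture
  (methylated near 0.8, unmethylated near 0.1) plus Gaussian noise
  (sd 0.05); CIMP-panel probes methylated with per-model probabilities
  (0.90, 0.45, 0.95, 0.90, 0.55), spanning clear and borderline CIMP+
  cases; EpiTOC baselines increase with the model's CIMP probability so
  mitotic age and CIMP percentage are positively coupled. Treatment
  shifts 60% of non-CIMP probes by −0.25 (per-probe jitter sd 0.05,
  truncated to [0, 1]), sparing the CIMP panel. The shift acts on the
  beta scale because the Δβ rule lives on the beta scale.
* **Expression**: NB counts with log-normal baseline means
  (meanlog 5, sdlog 1.2) and dispersion 0.05, a realistic replicate-level
  value for PDX material; library sizes log-normal (sdlog 0.15).
  Responsive genes are drawn from genes that are expressed (baseline
  mean ≥ 50), linked to at least two probes that can actually lose
  methylation (methylated at baseline and treatment-affected), and
  located 90% in open chromatin. 400 genes respond in sensitive models
  and a subset of 80 in every model, with |log2FC| in [1.5, 3], 70%
  up-regulated; 30 of the common genes form a synthetic MYC-target set
  repressed at log2FC −2 everywhere. These effect sizes are deliberately
  at the clearly detectable end for a 4 vs 4 design, so that the
  recovery properties the package promises (≥ 80% recall of common
  responsive genes in the all-model concordant set) test the pipeline
  machinery rather than the power frontier. 100 further genes differ
  between subgroups at baseline (|log2FC| in [1.5, 3]), providing the
  substrate for the sensitivity signature.
* **Genome and compartments**: one linear chromosome of 2,000 contiguous
  50 kb bins, 60% A; probes land 82% and genes 74% in A bins, matching
  the emulated array and transcriptome backgrounds. Four per-sample
  tracks agree with the true bin label with probability 0.9; consensus
  ambiguity follows.
* **Outcomes**: exponential survival with mean 30 d (vehicle), 45 d (one
  DAC cycle), 60 d (two cycles), ×1.4 for sensitive models, 5 mice per
  arm, administrative censoring at day 250. Flow tables carry Poisson
  event counts around day-1 → day-5 growth factors of 4 (vehicle), 0.5
  (treated sensitive) and 2 (treated less-sensitive), with counting-bead
  events at 50 beads/μL × 50 μL and 30 μL of stained blood.

**What it does not emulate**: genome sequence and probe chemistry;
spatially coherent compartment structure (bins are independent);
physically consistent probe–gene placement (links are an id mapping, so
probe and gene open-chromatin fractions are set independently);
batch effects (the emulated study excluded a discordant batch rather
than modelling it); copy-number or subtype-specific expression
programmes beyond the baseline subgroup differences. Passing tests on
this cohort therefore demonstrate correctness of the statistical
machinery under the assumed generative model, not robustness to the
artefacts of real array or sequencing data.

## Problem sizes and determinism

The default end-to-end run (20,000 probes × 40 samples, 3,000 genes × 40
samples, 2,000 bins, 75 survival records) completes in a few seconds;
the full test suite, including null-calibration simulations (200 genes ×
50 replicates for type-I error; 500 random sets for GSEA p uniformity;
200 replicates for log-rank null uniformity; a 10,000-permutation
log-rank oracle), runs in about a minute on one CPU. All randomness
descends from a single integer seed; reruns reproduce every output
checksum, which the manifest records per file.

## Known limitations

* The NB test's normal Wald reference is calibrated for the simulated
  design; at 2 vs 2 replicates or much larger dispersions it would turn
  anticonservative, and no exact small-sample correction is attempted.
* Gene-level DM status ignores probe density: a gene with one DM probe
  and one with forty count equally.
* The published CIMP percentages of specific PDX models depend on the
  deposited data and panel composition and are not reproduction targets;
  the package reproduces the classification logic, not those numbers.
* The permutation p of `logrank_test()` resamples labels, which assumes
  exchangeability under the null — appropriate for randomized arms, not
  for observational contrasts.
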