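---
title: "Diagnostic and prognostic methylation signatures: methods and design"
author: "methylSigR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic and prognostic methylation signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylSigR)
```

# Overview

methylSigR builds two kinds of signatures from Illumina-450K-style DNA
methylation data, where each CpG marker is summarized per sample by a
beta value $\beta = M/(M+U) \in [0,1]$ (the fraction of methylated
signal):

1. a **diagnostic signature** that separates tumor from normal samples
   using a signed cumulative sum of beta values over a small ranked
   marker panel, and
2. a **prognostic signature** — a Cox proportional-hazards risk score
   over a small marker panel selected by a survival-screening cascade —
   evaluated by median-split survival analysis and time-dependent ROC.

Both arms are exercised end to end on a seeded synthetic-cohort
generator with planted effects, so every stage is testable without any
array download.

# Preprocessing

`filterProbes()` applies two ordered rules: markers on sex chromosomes
(labels `X`, `Y`, `chrX`, `chrY`, case-insensitive) or not mapping
uniquely to the genome are removed first; markers observed in fewer
than `availabilityMin` (default 0.9) of samples are removed second. A
report counts removals per rule; a marker is counted under the first
rule that removes it, so the counts and the retained total always sum
to the input count.

`imputeMissing()` replaces each missing entry with the median beta of
the same marker over the remaining samples. This assumes missingness is
unrelated to the underlying methylation state (completely at random);
the generator's missingness model matches that assumption. Note one
consequence the tests make visible: in a mixed tumor/normal cohort the
per-marker median is dominated by the larger group, so imputed entries
in the minority group are biased toward the majority group's level. For
a one-marker signature this can flip a prediction; larger panels dilute
the effect.

`normalizeBetweenSamples()` performs full quantile normalization
(through `limma::normalizeBetweenArrays`, its default method for a
single-channel matrix): after normalization every sample's sorted
vector equals the row-wise mean of sorted input vectors. Ranks within a
sample are preserved, tied values receive the mean of the reference
values at the tied ranks, and the output stays in $[0,1]$.

# Differential methylation and diagnostic candidates

For each marker, `computeMarkerStats()` reports the group means
(`Ave_T`, `Ave_N`), unbiased SDs, and the floored log2 fold change

$$\log_2 \mathrm{FC} = \log_2 \frac{\max(\mathrm{Ave}_T,\,0.01)}
{\max(\mathrm{Ave}_N,\,0.01)},$$

with a two-sided Wilcoxon rank-sum p-value and Benjamini–Hochberg FDR
across markers. The rank-sum test uses the exact distribution when both
groups have at most 20 samples and no ties, and the tie-corrected
normal approximation otherwise — a deterministic rule rather than a
sample-size-dependent heuristic. The SD is the $n-1$ sample SD (the
convention is not forced by the method; it is simply fixed and
documented).

`preselectDiagnosticCandidates()` keeps markers passing all three gates
with **strict** inequalities, defaults $(0.3, 1, 0.01, 0.2)$:
`Ave_T > 0.3` or `Ave_N > 0.3`; $|\log_2 \mathrm{FC}| > 1$ and
FDR $< 0.01$; both SDs $< 0.2$.

# The diagnostic class-score signature

Each candidate is scored by its best achievable **balanced accuracy**

$$\mathrm{BA} = \tfrac12\left(\frac{TP}{TP+FN} + \frac{TN}{TN+FP}\right)$$

over single-marker threshold rules. `optimalThreshold()` scans the
midpoints between consecutive distinct observed beta values in both
orientations (call tumor when $\beta \ge t$, or when $\beta \le t$).
Midpoints attain every achievable confusion table; the degenerate
all-one-class rules score exactly 0.5 in one orientation and can never
exceed the interior maximum, so they are not scanned. Orientation ties
prefer the tumor-when-high (hyper) reading and threshold ties take the
smallest threshold. A constant marker returns BA 0.5 with a warning
flag. The scan is verified against exhaustive brute force in the test
suite.

Candidates are ranked by BA (descending), ties broken by smaller FDR
then marker id. The **class-score** of sample $j$ over the top $k$
markers is the signed cumulative sum

$$\mathrm{Sum}_{kj} = \sum_{i \le k} s_i\,\beta_{ij}, \qquad
s_i = \begin{cases} +1 & \mathrm{Ave}_T > \mathrm{Ave}_N \\
-1 & \text{otherwise} \end{cases}$$

with the sign fixed **globally** from the full-training group means,
not re-estimated per subsample: the sign rule references the training
means, and re-estimation inside subsamples would only add variance to
the size-selection curve.

The classification cutoff is the lower outlier fence of the training
tumor scores,

$$M_T = Q_1 - 1.5\,(Q_3 - Q_1),$$

with quartiles by linear interpolation between order statistics
(`stats::quantile` type 7) — used consistently everywhere a quartile or
median appears. Samples with class-score **not less than** $M_T$ are
called tumor (the boundary value is tumor). The rule presumes the mean
tumor score exceeds the mean normal score; `fitDiagnostic()` enforces
this and errors otherwise, pointing at the marker directions.

`selectSignatureSize()` sizes the panel by repeated subsampling: in
each of `nSim` (default 100) simulations a subsample is drawn without
replacement, and for each $k \le k_\max$ the subsample's own tumor
quartiles give the cutoff, yielding a BA per $(k, \text{simulation})$.
The selected $k^\ast$ maximizes the mean BA, ties resolving to the
smallest $k$ (parsimony: both too small and too large panels destabilize
BA). The subsample defaults to **half of each group**; the source
protocol is ambiguous between half (186 of 371 tumors, 25 of 50
normals) and two-thirds in different passages, so the fraction is an
explicit parameter rather than a resolved constant. `kMax` defaults to
50 (it is bounded by the candidate count in practice).

## What "perfect" classification can and cannot mean

The fence $M_T$ sits about $2.7\sigma$ below the tumor score mean for a
near-Gaussian score. About 0.3–0.5% of tumors therefore fall below it
*by construction*, at any panel size and for any marker separation of
the kind the generator plants (bounded beta noise included). On a
held-out cohort of 200 tumors the expected number of misses is ~1, so
exact sensitivity 1.0 is a coin flip, not a property. The test suite
asserts this boundary honestly; the practically stable statements are
sensitivity above ~99% and AUC indistinguishable from 1 on separable
cohorts.

# The prognostic cascade

All stages operate on tumor samples with overall survival (time,
status), in this order (each candidate set nests in the previous one):

1. **Mean methylation**: keep markers with `Ave_T > 0.2` (strict).
2. **Survival fold change**: per marker, `MM` is the median tumor
   beta; `Time_H` and `Time_L` are the mean *observed* survival times
   of deceased patients with $\beta \ge MM$ and $\beta < MM$; keep
   markers with $\mathrm{FC} = Time_H / Time_L > 2$ or $< 0.5$.
   Censored patients are excluded from these means exactly as the
   definition states (they re-enter at the Cox stage); markers with
   zero deaths in either stratum are indeterminate and dropped. The
   statistic is deliberately crude — a prescreen, not an estimator; its
   bias under heavy censoring is one reason the Cox stages follow.
3. **Univariate Cox**: keep markers with Wald $p < 0.01$ from a
   proportional-hazards fit of survival on raw beta (Efron ties, the
   default and a documented choice — the source does not specify).
4. **LASSO-Cox**: L1-penalized Cox over the candidates;
   cross-validated partial-likelihood deviance selects lambda-min.
   "100-fold" cross-validation is interpreted as
   `nFolds = min(100, number of events)` with folds stratified by event
   status — literal 100-fold assignment degenerates on cohorts with
   fewer than 100 events. Fold assignment is seeded.
5. **Multivariate Cox**: an unpenalized fit over the selected markers
   gives the coefficients. The **risk score** is the linear predictor
   $\sum_m \hat\beta_m^{\mathrm{Cox}} \beta_m$ on *unstandardized* beta
   values (the published score formula multiplies coefficients by raw
   beta). The risk cutoff is the interpolated median of training
   scores; scores at or above it are high-risk.

Evaluation: `kmLogrank()` gives product-limit curves, the two-sample
log-rank test, and the high-vs-low hazard ratio with a Wald CI from a
Cox fit on the group indicator. `timeDependentAUC()` implements the
cumulative-case / dynamic-control AUC at horizon $t$ with
inverse-probability-of-censoring weights from the Kaplan–Meier
estimator of the censoring distribution: cases ($T \le t$, event)
weight $1/\hat G(T^-)$, controls ($T > t$) weight $1/\hat G(t)$, tied
scores half credit. With no censoring this reduces to direct
concordance counting, which the tests verify. Horizons beyond follow-up
are flagged undefined rather than extrapolated.
`stratifiedEvaluation()` applies the **global** training cutoff within
each stratum level (rather than refitting per stratum — the alternative
reading of per-stratum regrouping is noted, not implemented), skipping
levels below 20 samples.

# Expression correlation and the random-signature null

`correlateScoreWithGenes()` computes per-gene Pearson correlation with
the risk score and two-sided p-values via the $t$ transform
($t = r\sqrt{(n-2)/(1-r^2)}$); zero-variance genes are excluded with a
note rather than patched. Top-k positive/negative lists (default 10)
are restricted to $p < 0.001$.

`spmNull()` is a permutation null for gene-set association: each
repetition draws a random same-size marker panel ("simulated prognostic
model") from the candidate list, fits the same multivariate Cox model,
scores the samples, takes the top-k genes by positive correlation
(without a significance filter, so the list always has k genes), and
counts members of a user-supplied gene set. Significance of an observed
count is its empirical upper-tail proportion among the `nRep` (default
100) null counts; no multiplicity correction is layered on top because
the source of any such correction is not derivable from the
100-repetition design.

`panelClusterPrognosis()` clusters samples on a small expression panel —
per-gene standardized, Euclidean distance, Ward linkage, cut at two
groups (stated choices; only "unsupervised hierarchical clustering" is
inherited, so the linkage is configurable in principle and documented
here). The lower-mean group is labelled "low"; the report gives each
group's average observed survival time among deceased patients and the
log-rank comparison.

# The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, with every draw flowing from one seed:

* **Beta values** come from per-group beta distributions parameterized
  by (mean, SD) via method of moments — bounded and bimodal-capable
  like 450K data. Null markers share one distribution across groups
  (mean uniform on $[0.15, 0.85]$, SD `marker_sd` = 0.05); planted
  differential markers sit at $0.5 \pm$ `diff_delta`/2 (default 0.4),
  alternating hyper/hypo.
* **Planted prognostic markers** are variably methylated (mean 0.5, SD
  `prog_marker_sd` = 0.45, i.e. strongly bimodal, near 0/1) in both
  groups. The spread is what carries the survival signal: with the
  per-unit-beta log hazard ratios (+1.5, +1.0, +1.0, −1.2) a narrow
  marker cannot produce a detectable stratum contrast under the FC
  prescreen, whereas fully polarized CpGs — which dominate real
  survival-marker panels — can. This value was fixed once from that
  design consideration.
* **Survival** follows an exponential proportional-hazards model with
  hazard $h_0 \exp(\sum_m \theta_m \beta_m)$, $h_0$ = 0.08 per year
  (median OS ≈ 1.7 years, so 1/2/3-year horizons are all informative).
  Censoring is independent with per-sample censoring hazard
  $h \cdot c/(1-c)$, making the censoring probability exactly
  `censor_rate` for every sample (an exact closed-form variant of
  rate-calibrated exponential censoring); ties resolve as events.
  `censor_rate = 1` censors everyone; downstream death-dependent
  screens then error as documented.
* **Expression**: planted genes are generated as
  $\pm r z + \sqrt{1-r^2}\,\varepsilon$ on the standardized risk score
  (population correlation exactly $\pm r$, half each sign); remaining
  genes are independent noise; all shifted to a baseline mean of 5.
* **Missingness** is completely at random at `missing_rate` (default
  2%); the manifest flags 2% of markers as sex-chromosomal and 1% as
  multi-mapping, never overlapping planted markers.

What the generator does **not** emulate: batch and plate effects, type
I/II probe chemistry differences, correlated CpG blocks, informative
missingness, non-proportional hazards, and FFPE artifacts. Passing
tests therefore demonstrate correctness of the algorithms under the
stated model, not robustness to those real-data complications.

Default problem sizes (200 tumors / 50 normals / 2000 markers for the
diagnostic arm; 400 tumors / 604 markers for the prognostic arm; 100
subsampling simulations and 100 SPM repetitions) were chosen as the
smallest sizes at which the planted effects are comfortably estimable;
the test suite uses these and smaller.

# Degenerate inputs and numerical conventions

* Quartiles/medians: linear interpolation (type 7) everywhere.
* Classification and risk-group boundaries are inclusive on the
  high/tumor side (`score >= cutoff`).
* Constant markers: BA 0.5 with a warning (threshold scan); dropped
  with a warning (Cox screen); an error (multivariate fit, where a
  constant column makes the model unidentifiable).
* Fully missing markers are an error directing to `filterProbes()`.
* Beta values outside $[0,1]$ are rejected at parse time with the cell
  location.
* All LASSO, subsampling, SPM and generator randomness is seeded
  through explicit arguments; repeated calls with one seed are
  bit-identical.

# Known limitations

* The survival-FC prescreen uses deaths only and is biased when
  censoring correlates with methylation; it is kept because it defines
  the method being implemented.
* The Wald p in the univariate screen is unreliable under monotone
  likelihood (perfectly separating markers); such markers are rare
  under the generator but real cohorts may need a score or likelihood
  ratio test instead.
* Hierarchical-clustering group labels depend on the panel scaling
  choices documented above.
* The pipeline treats survival times as unit-agnostic; horizons must be
  expressed in the same unit (the defaults read naturally as years).
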