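# methylSigR

Diagnostic and prognostic DNA methylation signatures from
Illumina-450K-style beta-value matrices.

Tumor tissue shows characteristic gains and losses of CpG methylation,
quantified per marker and sample by the beta value
β = M/(M+U) ∈ [0,1]. methylSigR is for analysts who want to build, from
a markers × samples beta matrix with tumor/normal labels and overall
survival, two kinds of small marker panels:

* **Diagnostic signature.** Differentially methylated markers are
  gated on group means, floored log2 fold change
  (log2[max(Ave_T, 0.01)/max(Ave_N, 0.01)]), FDR and within-group SD,
  then ranked by the best balanced accuracy
  BA = (sensitivity + specificity)/2 achievable by a single beta
  threshold. A sample's **class-score** is the signed cumulative sum of
  the top-k markers' beta values (+β for hypermethylated markers, −β
  for hypomethylated); the panel size k is chosen by repeated
  subsampling, and samples are called tumor when the class-score is not
  less than the cutoff MT = Q1 − 1.5(Q3 − Q1) of the training tumor
  scores.
* **Prognostic signature.** Markers pass Ave_T > 0.2, then a survival
  fold-change prescreen (mean observed survival of deceased patients
  above vs below the marker's median beta; keep FC > 2 or < 0.5), then
  univariate Cox p < 0.01, then LASSO-Cox selection at cross-validated
  lambda-min; a multivariate Cox fit gives the **risk score**
  Σ coef_m · β_m. Patients at or above the training median score are
  high-risk; evaluation uses Kaplan–Meier/log-rank, the high-vs-low
  hazard ratio, and IPCW time-dependent ROC AUC at chosen horizons.

A downstream arm correlates the risk score with gene expression
genome-wide, counts top-correlated genes in an annotated set, and
calibrates that count against a random-signature ("simulated prognostic
model") permutation null. A seeded synthetic-cohort generator —
beta-distributed markers, planted differential and survival-associated
effects, exponential proportional-hazards survival with independent
censoring, correlated expression — makes the whole pipeline testable
without any array download. See the vignette
(`vignettes/methylation-signatures.Rmd`) for the methods and design
choices.

## Worked example

Diagnostic arm on the default synthetic cohort (200 tumors, 50 normals,
2000 markers, five planted differential markers at delta 0.4):

```r
library(methylSigR)

cohort <- simulateCohort(cohortConfig(seed = 1))
me <- cohort$methylation
me
#> MethylationExperiment with 2000 markers and 250 samples
#>   groups: 200 tumor / 50 normal
#>   missing: 2.01%

norm  <- normalizeBetweenSamples(imputeMissing(filterProbes(me)))
stats <- computeMarkerStats(norm)
sel   <- preselectDiagnosticCandidates(stats)
str(sel$report)
#> List of 5
#>  $ n_input      : int 1940
#>  $ n_fail_mean  : int 415
#>  $ n_fail_fc_fdr: int 1935
#>  $ n_fail_sd    : int 4
#>  $ n_retained   : int 5
```

1940 markers survive probe filtering (sex-chromosome, multi-mapping and
low-availability probes are dropped); the three preselection gates cut
them to exactly the five planted markers (almost every null marker
fails the |log2 FC| > 1 + FDR gate). Ranking, size selection and
fitting:

```r
ranked <- rankDiagnosticCandidates(norm, stats, sel$marker_ids)
size   <- selectSignatureSize(norm, ranked, nSim = 100, seed = 2)
round(size$mean_ba, 4)
#> [1] 0.9998 0.9998 0.9966 0.9918 0.9889
sig <- fitDiagnostic(norm, ranked, size$k_star)
sig
#> DiagnosticSignature with 1 markers (class-score cutoff 0.5667)
#>   cg0000001 (hyper)
```

The mean-BA curve peaks at k = 1 (ties resolve to the smallest panel),
so the fitted signature keeps the top-ranked planted marker and the
class-score cutoff 0.5667 derived from the training tumor quartiles.

Prognostic arm under planted survival effects (400 tumors, four markers
with log hazard ratios +1.5, +1.0, +1.0, −1.2 among 600 nulls, 35%
censoring):

```r
cohort <- simulateCohort(cohortConfig(n_tumor = 400, n_normal = 10,
    n_markers = 604, n_diff_markers = 0, n_prog_markers = 4,
    censor_rate = 0.35, missing_rate = 0, seed = 1))
b      <- betaValues(cohort$methylation)
g      <- sampleGroups(cohort$methylation)
tumors <- names(g)[g == "tumor"]
surv   <- survivalOutcome(cohort$methylation)

cascade <- prognosticCascade(b[, tumors], surv, seed = 1)
sapply(cascade$stages, length)
#> mean_methylation      survival_fc   univariate_cox            lasso
#>              557                4                4                4
#>            final
#>                4
cascade$model
#> PrognosticModel with 4 markers (risk cutoff -2.194, lambda 0.005446)
#>   risk score = +1.075 x cg0000001 +0.9999 x cg0000002
#>                -1.232 x cg0000004 -3.959 x cg0000227
```

The cascade narrows 557 → 4 markers and recovers three of the four
planted markers with their planted signs (cg0000003's effect is diluted
by its correlation with the stronger cg0000001 stratum contrast at this
seed; one null marker enters with a compensating coefficient).
Median-split survival and time-dependent AUC on the training cohort:

```r
scores <- riskScores(cascade$model, b[, tumors])
km <- kmLogrank(factor(assignRiskGroups(scores, cascade$model),
                       c("low", "high")), surv)
sprintf("HR %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g",
        km$hr, km$hr_lower, km$hr_upper, km$p)
#> [1] "HR 2.91 (95% CI 2.23-3.80), log-rank p = 3.44e-16"
timeDependentAUC(scores, surv, c(1, 2, 3))
#>   horizon       auc n_cases n_controls defined
#> 1       1 0.7752679     105        243    TRUE
#> 2       2 0.7670516     146        181    TRUE
#> 3       3 0.7962554     176        141    TRUE
```

High-risk patients die about three times faster than low-risk patients,
and the score discriminates one-to-three-year mortality with AUC
0.77–0.80.

`runPipeline(runConfig(), outDir)` chains all stages (simulate →
preprocess → differential methylation → diagnostic → prognostic →
correlation/SPM) and writes every artifact as TSV/JSON with a checksum
manifest; `resume = TRUE` re-runs only missing stages and their
descendants.

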