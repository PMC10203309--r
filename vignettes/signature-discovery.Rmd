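---
title: "Discovering proteomic signatures of rapid FEV1 decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering proteomic signatures of rapid FEV1 decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(declinesig)
```

## The problem

Chronic obstructive pulmonary disease progresses at highly variable rates:
some people lose lung function (FEV1, the forced expiratory volume in one
second) slowly, others lose more than 100 mL/year. `declinesig` implements a
multi-compartment biomarker-discovery pipeline for this setting: given a
large plasma protein panel (~1300 aptamer-based analytes), a small
bronchoalveolar-lavage (BAL) immunoassay panel (~48 analytes), and two-visit
spirometry several years apart, it asks which combination of baseline
proteins prospectively identifies the participants who will decline fastest.

Progression is operationalized as the annualized two-point slope

$$\Delta \mathrm{FEV}_1 = \frac{1000\,( \mathrm{FEV}_1^{V5} - \mathrm{FEV}_1^{V1})}{\text{days}(V1 \to V5)/365.2425} \quad [\mathrm{mL/year}],$$

with a fixed-length 365.2425-day year. The cohort is dichotomized at the
30th percentile of $\Delta \mathrm{FEV}_1$: the most negative
$\lceil 0.30\,n \rceil$ slopes are *greater decliners*, the rest *lesser
decliners* (for $n = 45$ this gives the 14/31 split, with a realized
threshold near $-70$ mL/year). A threshold-based alternative (rapid
$>100$, decliner $20{-}100$, stable $<20$ mL/year) is provided by
`threshold_classes()`; both boundaries are assigned to the middle class
because the published ranges are ambiguous about closure.

## The discovery procedure

The classifier at the core is two-class PLS discriminant analysis (PLSDA):
the analytes are autoscaled, the class is encoded as a single centered 0/1
response, and latent variables (LVs) are extracted by the classical
iterative NIPALS algorithm with deflation (tolerance $10^{-10}$, at most 500
iterations per LV; two LVs by default, matching the two-dimensional score
plots such data are summarized with). Classification thresholds the
predicted response at the midpoint of the calibration class means —
symmetric, deterministic, and the natural default when the underlying
toolbox convention is unpublished. LV1 is oriented so the greater-decliner
mean score is negative (so negatively loaded proteins are elevated in
greater decliners).

Feature selection proceeds in two stages:

1. **Balanced-resample elastic-net ranking.** Because the classes are
   imbalanced (14 vs 31), each of `n_iterations` resamples draws, without
   replacement, a subset of each class equal to the smallest class size; the
   minority class is therefore fully present in every resample and ranking
   variability comes from majority-class subsampling and the per-iteration
   penalty choice. On each resample an elastic-net-penalized logistic
   regression (mixing parameter $\alpha = 0.5$ by default — the paper-style
   analysis does not publish its value, and an even L1/L2 mix is the neutral
   choice) is fitted with the penalty strength chosen by internal 5-fold
   cross-validation at minimum deviance. An analyte's *selection frequency*
   is the fraction of iterations in which its coefficient is nonzero.
   Frequency ties are broken by higher mean absolute coefficient, then
   analyte id.

2. **Step-forward PLSDA.** Analytes enter the model one at a time in ranking
   order; each size is scored by stratified 6-fold cross-validation (folds of
   6–7 samples at $n = 45$), pooling out-of-fold predictions into balanced
   accuracy (the mean of sensitivity and specificity — the accuracy
   convention consistent with printing 98.4% alongside 100%/96.8%),
   sensitivity, specificity and ROC AUC. The optimal signature maximizes CV
   balanced accuracy; **accuracy ties are broken by the lowest
   cross-validated response RMSE, then the smallest size**. The RMSE
   tie-break matters: on strongly separable data the pooled CV accuracy
   saturates at 1.0 over a long run of sizes, and picking the smallest tied
   size truncates the signature while discarding analytes the ranking has
   in fact placed correctly; the continuous response error still
   discriminates among tied sizes and is the standard "cross-validated
   error" of the PLS literature.

Minimal signatures — candidate parsimonious predictors — are the steps with
fewer than 15 features and CV balanced accuracy strictly above 80%.
Meaningfulness of the optimum is checked against a random-signature null:
many feature sets of the same size, drawn uniformly, each evaluated by the
same 6-fold CV, summarized as an empirical $p = (1 + \#\{\mathrm{null} \ge
\mathrm{obs}\})/(1 + n_\mathrm{random})$ and a two-sample t-test of the
observed per-fold accuracies against the null accuracies.

### Orthogonalization

Fitted models are orthogonalized for interpretability: the latent space is
rotated so all response-predictive covariance concentrates on LV1 and the
remaining LVs carry response-orthogonal variation. Concretely, scores are
variance-normalized, an orthonormal rotation is built whose first axis is
the fitted-response direction, and loadings/weights are counter-rotated.
Predictions are exactly invariant, post-rotation LV$\ge$2 scores are exactly
uncorrelated with the centered response, and the transform is idempotent.
The commercial toolbox used in the published analysis does not document its
algorithm; this rotation is the package's own equivalent with the same
defining properties, and both properties are asserted in the test suite at
$10^{-10}$.

## Preprocessing rules

BAL immunoassay panels are censored at their detection limits before
anything else: values above an analyte's upper limit of detection are set to
that limit; values below the lower limit are set to a global imputation
constant equal to half the lowest minimum detectable concentration across
all analytes. Analytes with $\ge 50\%$ of measurements below their lower
limit are removed (the rule is inclusive: exactly half triggers removal).
Whether the published analysis imputed before or after normalization is
unstated; this pipeline imputes first, so the imputation constant lives on
the same raw concentration scale as the limits. BAL concentrations are then
normalized to each sample's total BAL protein (a plain ratio; units treated
as arbitrary but constant within a run), and every analyte — blood and BAL —
is log2-transformed. Base 2 is chosen because downstream fold changes are
reported as log2 ratios.

Because the classes are unevenly male (roughly 86% vs 55%), analytes
associated with sex (two-sample t-test, Benjamini–Hochberg across the panel,
$\alpha = 0.05$) are removed before modeling. The filter is computed on the
COPD analysis cohort, since it guards the COPD-only classifier. Compartments
are then merged column-wise with `blood:`/`bal:` id prefixes, so an analyte
measured on both platforms remains two distinct features.

The univariate screen reports, per analyte, the log2 fold change of
raw-scale (back-transformed) class means — the published convention divides
average concentrations, which is why printed fold changes near zero
correspond to near-unity ratios — with pooled-variance t-tests on the log
scale (the pooled variant reproduces the published cohort-table p-value of
0.017 from its summary statistics; Welch does not) and BH adjustment.

## Evaluation machinery

ROC curves come from a threshold sweep with tie handling; the trapezoid AUC
equals the Mann–Whitney statistic divided by $n_+ n_-$ (asserted against a
brute-force pairwise oracle at $10^{-12}$). AUC standard errors use the
Hanley–McNeil closed form from the Wilcoxon statistic, with
$Q_1 = A/(2-A)$ and $Q_2 = 2A^2/(1+A)$. Two AUCs measured on the same
samples are compared with the correlation-adjusted z-test
$z = (A_1 - A_2)/\sqrt{se_1^2 + se_2^2 - 2 r\, se_1 se_2}$. The published
correlation table for $r$ is not reproduced in accessible sources, so $r$
is estimated as the mean of the within-class Pearson correlations of the two
score vectors — an approximation the table closely tracks — and the test
suite cross-checks it by simulation (independent scores give $r \approx 0$
and agreement with the uncorrelated z-test; identical scores give $p = 1$).
Associations between LV scores and decline are ordinary least squares with
the usual adjustment set (age, race, height, sex, baseline FEV1 %predicted,
smoking status, pack-years, inhaled-corticosteroid use).

## Unsupervised profiles

PCA is always on autoscaled data. Sample outliers are flagged by the
Hotelling *reduced* T² — the T² over retained components divided by its 95%
confidence limit $\frac{A(n-1)}{n-A} F_{0.95}(A, n-A)$ — with threshold 2 on
the ratio; the statistic is named but not defined in the source analysis, so
this normalization is the package's definition, and the removal loop runs
once (flag, drop, refit), as the published analysis removed two samples in a
single pass. Group separation in the PC1–PC2 plane is tested by permutation
with the between-centroid Euclidean distance as the statistic (the published
analysis does not state its statistic or permutation count; 10,000
permutations by default, $p = (1 + \#\ge)/(1 + n_\mathrm{perm})$).
Signature clustering uses one minus the Spearman correlation between sample
profiles as the distance, average linkage, a two-cluster cut, and
majority-class mapping (ties toward the larger class). Score differences
across groups use one-way ANOVA with Tukey, Dunnett, Holm–Šídák or
Bonferroni post-hoc families.

## The synthetic cohort generator

Restricted-access study data cannot ship with the package, so
`generate_cohort()` emulates the structure the analysis assumes, and its
defaults are the study conditions: 14 greater / 31 lesser decliners plus a
40-person smoking-control reference group (TEPPS); annualized declines
drawn from $N(-104.6, 32.0^2)$ and $N(-28.8, 21.5^2)$ mL/year; follow-up
$N(6.31, 0.86^2)$ years; 1305 blood and 48 BAL analytes; 23 BAL analytes
constructed (via LLODs placed between empirical order statistics) to fail
the 50% rule exactly, leaving 25; 8 sex-associated blood analytes at 2 SD
with class-specific male proportions 85.7%/54.8%; and a planted
discriminative signature — by default 20 analytes at a standardized log-scale
effect of 1.5 SD, one of them in BAL, mirroring the 51-blood/1-BAL split of
the published signature. Analyte levels are Gaussian on the log2 scale
(log-normal concentrations) with analyte-specific baselines and SDs; the
aptamer platform's true distributional family is not published, so
log-normality is an assumption, made because the analysis log-transforms
"for normality". Raw BAL values scale with each sample's total protein, so
ratio normalization recovers the latent level exactly. $\Delta$FEV1 is drawn
first and V5 FEV1 back-computed from V1 FEV1 and the realized calendar
interval, so progression labeling round-trips exactly. TEPPS analyte
distributions default to the lesser-decliner parameters, reflecting the
observation that preserved-spirometry controls resemble lesser decliners.

What the generator does **not** emulate: assay chemistry, plate and batch
effects, analyte–analyte correlation beyond the planted structure,
visit-level trajectories beyond two timepoints, or missingness. Passing
tests therefore demonstrate that the pipeline recovers structure it is
pointed at under idealized independence — not that real panels satisfy these
assumptions.

Two behaviors of the *study-scale* conditions are worth knowing. First, the
class decline distributions genuinely overlap near the $-70$ mL/year
threshold, so percentile labels disagree with the generating classes for a
few boundary participants; planted-signal recovery is measured against
generator truth and is correspondingly attenuated on unlucky seeds. Second,
because the elastic-net ranking is computed on the full dataset before
cross-validation (there is no nested CV, matching the published design),
the step-forward CV accuracy is optimistic: on label-exchangeable data the
discovered "signature" still cross-validates far above random same-size
signatures. This selection optimism is intrinsic to the design and is the
reason the random-signature null should be interpreted as a sanity check on
ranking meaningfulness, not as an unbiased generalization estimate.

## Problem sizes and numerical choices

The test suite exercises the full study dimensions (85 participants, 1305 +
48 analytes, 1322 merged features) with 200 elastic-net iterations, a
step-forward cap of 60 features and 200 random null signatures, five seeds —
sizes chosen so a complete run remains interactive on one CPU; the
function defaults (2000 iterations, 2000 random signatures, cap 100) follow
the published procedure. Other numerical choices: NIPALS tolerance
$10^{-10}$; constant analytes dropped with a warning before autoscaling;
degenerate two-group t-tests (zero variance, equal means) return $p = 1$;
p-value underflow in the screen is reported at the smallest positive double
for volcano plotting; prediction ties go to the larger (lesser) class;
dichotomization ties spanning the percentile boundary resolve by rank with
a warning.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(
  synthetic = cohort_config(seed = 1),
  n_en_iterations = 200, step_max_size = 60, n_random = 200, seed = 1
)
res <- run_pipeline(cfg, out_dir = "declinesig_run")
res$search$optimal          # optimal signature metrics
res$null$p_empirical        # random-signature null p
res$clustering$sensitivity  # Spearman-distance clustering recall
```

Every output is delimited text plus a JSON manifest recording the seed and
configuration, and round-trips through the package's own readers. The master
seed spawns independent per-stage substreams, so changing one stage's
workload does not perturb another's randomness.

## Known limitations

No nested cross-validation (see above); no mixed-model slopes over more than
two visits; no multiclass PLSDA or variable-importance scores; no assay-
specific normalization or batch correction; ontology enrichment of signature
members is out of scope (signature lists export as plain text for external
tools). The Hanley–McNeil correlation mapping and the reduced-T² limit are
the package's documented equivalents for conventions the source analysis
names but does not define.
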