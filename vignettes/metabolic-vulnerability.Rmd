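---
title: "Vulnerability-index scoring and covariate-adjusted association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vulnerability-index scoring and covariate-adjusted association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metavulx)
```

## The indices and their scoring model

Serum proton-NMR profiling yields, besides the lipoprotein sub-class
spectrum, quantitative concentrations (µmol/L) of several small-molecule
metabolites — the branched-chain amino acids (BCAA) valine, leucine and
isoleucine, alanine, citrate — together with GlycA, a composite inflammation
signal from the glycan residues of circulating acute-phase glycoproteins,
and the concentration of small HDL particles (sHDLP, diameter < 9 nm).
Three composite indices summarize the malnutrition–inflammation axis of
this panel:

* **IVX** (inflammatory vulnerability) is bilinear in GlycA and sHDLP:
  $\mathrm{IVX} = 9 - 0.0027\,G - 0.46079\,S + 0.0006325\,G S$.
* **MMX** (metabolic malnutrition) is a weighted sum of quadratics in
  leucine, valine and citrate plus a linear isoleucine term.
* **MVX** (metabolic vulnerability) combines the two on the raw scale,
  $\mathrm{MVX} = 2.72923\,\mathrm{IVX} + 11.96062\ln \mathrm{MMX}
  - 1.12749\,\mathrm{IVX}\ln\mathrm{MMX}$, the interaction capturing the
  synergy of malnutrition–inflammation syndromes.

The polynomial coefficients descend from a Cox proportional-hazards fit to
3-year all-cause mortality in a catheterization cohort; this package treats
them as fixed constants and does not re-derive them.

Each index is reported on a 1–100 score scale. Only two endpoint
correspondences per index are published (raw value ↦ score 1, raw value ↦
score 100: IVX 2.0/8.3, MMX 1.281/2.0, MVX 20.3/28.0), so `anchor_score()`
uses the simplest mapping consistent with both — linear interpolation
clamped to $[1, 100]$:

$$\text{score} = \min\!\left(100,\ \max\!\left(1,\ 1 + 99\,
\frac{\text{raw} - \text{raw}_{\min}}{\text{raw}_{\max} - \text{raw}_{\min}}
\right)\right).$$

Two deliberate choices here:

* **Floor of 1, not 0.** One published figure caption describes the scores
  as ranging 0–100, while the formula block pins the minimum anchor to
  score 1; the explicit anchor correspondence wins.
* **MVX is evaluated on raw inputs.** The MVX formula's symbols match the
  raw IVX/MMX formulas, so the raw values feed it; anchors apply only at
  the final score step.

### The anchor inconsistency, and why anchors are configuration

At physiological serum concentrations the printed raw-MMX formula evaluates
to roughly 4–6, far above the published MMX anchor window (1.281–2.0), and
substituting the raw IVX/MMX anchor values into the MVX formula does not
reproduce the published MVX anchors either. The published anchors evidently
presuppose some intermediate standardization that is not documented. We do
not guess one: the formulas are implemented exactly as printed, the
published anchors are the defaults, and `default_anchors()` accepts
replacement pairs for any recalibrated scale. The practical consequence on
synthetic (and presumably real) data is that the clamped **MMX score
saturates at 100**; the raw MMX remains fully informative and all outputs
carry both raw and scored columns. Downstream, a saturated (constant)
outcome yields zero sums of squares and an NA p-value rather than
round-off noise — see the numerical notes below.

## The synthetic cohort generator

No patient-level data accompany the source study, so the package ships a
seeded generator whose defaults emulate the study conditions: 153 healthy
controls (HC), 187 relapsing–remitting (RR) and 91 progressive (PMS) MS
patients, per-group age/BMI normal distributions, female and heart-problem
fractions, and disease duration matching the published baseline table.

* **EDSS** (ordinal 0–10 in 0.5 steps) is drawn from a beta distribution
  scaled to $[0, 10]$ whose shape parameters are fitted by quantile matching
  (`optim`, Nelder–Mead on the quartiles) to the published median/IQR — RR
  2.5 [1.5–3.5], PMS 6.0 [5–6.5] — then discretized to the half-point grid
  and clipped. A bounded, skewable family is the natural choice for a
  bounded ordinal scale; discretization can shift the realized median by up
  to half a step, which the tests allow for.
* **Timed 25-foot walk** is log-normal with group-specific location
  (medians ≈ 6 s RR, 12 s PMS; implementation choices at clinically
  plausible scale).
* **Metabolites** follow
  $x = \mu_{HC} + \beta_{RR}\mathbf{1}[\text{RR}] +
  \beta_{PMS}\mathbf{1}[\text{PMS}] + \varepsilon$,
  $\varepsilon \sim N(0, \sigma^2)$ independent of age, sex and BMI. The
  shifts default to the published adjusted regression coefficients; because
  the residuals are independent of the covariates, the covariate-adjusted
  OLS group coefficient is an unbiased estimator of the configured shift,
  which is what makes parameter recovery a well-defined check without
  knowing the study's covariate–group confounding. HC baselines
  (valine 230, leucine 130, isoleucine 60, alanine 350, citrate 120,
  GlycA 400, sHDLP 15 µmol/L) and residual SDs (40, 25, 12, 60, 25, 60, 4)
  are implementation defaults at physiological scale — the study reports
  contrasts, not baselines — and recovery tests depend only on the shifts.
  Draws below zero are floored at 0 and counted, never silently altered;
  with the default baselines the floor is effectively never hit.
* **MRI volumetrics** (T2/T1 lesion volumes; whole-brain, gray-matter,
  deep-gray-matter, cortical and lateral-ventricle volumes, mL) are drawn
  per group for the MS subjects only (imaging is acquired in patients),
  with optional linear couplings to any biomarker column for sign-recovery
  experiments.
* **Outcome-coupled scores** (`generate_outcome_coupled_scores()`) simulate
  an index score affine in EDSS or log10 walk time plus Gaussian noise.
  Draws outside $[1, 100]$ are *counted but not truncated*: truncation
  would bias exactly the slope whose recovery the simulation is meant to
  check, so the calibration burden (choose intercept/noise so the count is
  negligible) is left visible to the user instead.

All stages draw from child streams derived deterministically from one root
seed (Mersenne–Twister), so identical config + seed reproduces a cohort
bit-for-bit and adding a stage never perturbs another stage's draws.

What the generator does **not** emulate: covariate–biomarker confounding,
between-analyte correlation (each analyte's residual is independent),
longitudinal dynamics, relapse activity, and NMR measurement error
structure. Passing recovery tests therefore demonstrates the correctness of
the estimation machinery under the stated generative model — not that the
published patient-data coefficients would re-emerge from a new clinical
cohort.

## The association machinery

`fit_adjusted_ols()` fits `biomarker ~ predictor + age + sex + bmi`
(optionally + heart-problem status) by QR least squares on complete cases
(dropped-row counts always reported; no imputation). Effect sizes are
generalized eta-squared per term,
$\eta^2_g = SS_{\text{term}} / (SS_{\text{term}} + SS_{\text{error}})$,
with Type II sums of squares: each term's SS is the increase in residual SS
when that term alone is dropped from the full (interaction-free) model. For
the three-level group factor the term is the joint 2-df effect — the
published table does not say whether its group η² is joint or per-dummy;
we report the joint effect, and the per-dummy coefficients $\beta_{RR}$,
$\beta_{PMS}$ (treatment coding, HC reference) alongside. Labels follow the
conventional inclusive thresholds: small ≥ 0.01, medium ≥ 0.06,
large ≥ 0.14. EDSS is treated as continuous in regression, as the source
analyses implicitly do; its ordinal nature means the slope is a linear
approximation over the grid. p-values are unadjusted, matching the source's
reporting; no multiplicity correction is applied by default.

Baseline tables use Welch's t-test for continuous variables, the two-sided
Fisher exact test for binaries, and the chi-square test for multi-level
categoricals; the default contrast is HC vs RR (as in the published
baseline table's footnote) with an omnibus three-group option.
`assign_tertiles()` implements rank-based n-tiling with
earlier-blocks-take-extras semantics and first-occurrence tie-breaking, so
assignments are deterministic.

## Numerical choices

* Sums of squares below $10^{-12}$ of the outcome's total variation (or of
  its squared magnitude times machine epsilon, whichever is larger) are
  treated as exact zeros, so noise-free designs give η² of exactly 0 or 1
  and a constant outcome gives NA p-values rather than ratios of round-off.
* Rank-deficient designs are rejected up front with the collinear columns
  named (QR pivot diagnosis), and models require at least
  $\max(10, p + 1)$ complete cases.
* Truncated-normal draws (age ≥ 18, BMI ≥ 12, duration ≥ 0.5) use
  resampling; the truncation points sit ≥ 2 SD in the tail for every
  default, so the induced mean shift is the analytic
  $\sigma\varphi(z)/(1-\Phi(z))$ and resampling terminates immediately in
  practice.
* The strict CSV contract (comma, UTF-8, `.` decimal, empty cell = missing,
  no sentinel numbers) exists for bit-exact reproducibility across locales;
  out-of-range concentrations warn and are counted, never modified.

## Problem sizes

The test suite and the acceptance analyses use the study-sized cohort
(153/187/91) throughout: 200 replicates for each Monte-Carlo recovery
(group shifts and disability slopes, tolerance three Monte-Carlo standard
errors), 2,000 zero-shift replicates for the type-I calibration check
(Kolmogorov–Smirnov uniformity of the group-term p-value), exhaustive
enumeration of all 2×2 Fisher tables up to total 30, and 100-fixture
oracle sweeps for the OLS and η² identities. The narrative scripts under
`analysis/` use 100 replicates for their recovery tables.

## A worked pass

```{r worked, eval = FALSE}
cfg <- cohort_config()
cohort <- simulate_cohort(cfg, seed = 101)
res <- run_full_association_suite(cohort)
res$group                      # group-status table: eta^2, p, beta_RR, beta_PMS
ms <- cohort[cohort$group != "HC", ]
tapply(ms$edss, assign_tertiles(ms$mvx_raw), mean)   # disability by MVX tertile
```

The same pass, with its printed output, is the README's worked example; the
four scripts under `analysis/` run it end-to-end and write the result
tables under `results/`.

## Known limitations

* The published MMX/MVX anchor scales cannot be reconciled with the printed
  raw formulas (above); until the intermediate standardization is
  documented, MMX scores from physiological panels saturate.
* The published patient-data table values are not reproducible in
  principle — the study deposited no data — so the package's empirical
  claims are limited to parameter recovery under its own generative model
  and to property-based equivalences of the analysis machinery.
* Single-visit, cross-sectional design only: no longitudinal or survival
  structure.
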