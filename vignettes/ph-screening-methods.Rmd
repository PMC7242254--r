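---
title: "Methods: deriving a PH screening score in ILD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving a PH screening score in ILD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phscreen)
```

## The screening problem and the model

Pulmonary hypertension complicates interstitial lung disease and is
assessed non-invasively by echocardiography, which grades PH probability
from the tricuspid regurgitant jet velocity (TRV), the estimated pulmonary
arterial systolic pressure (PASP) and supporting signs. `phscreen`
implements the analysis chain that turns routinely collected clinical
measurements into a screening rule for that echocardiographic label:

1. classify each patient's echo into `unlikely` / `possible` / `likely`
   and dichotomize into stratum A (low probability) vs B (increased
   probability, the positive class everywhere in this package);
2. compare candidate markers between strata;
3. derive per-marker operating points by Youden's method on empirical ROC
   curves, with DeLong intervals on the AUC;
4. quantify risk with univariate logistic regression and 2×2 odds ratios;
5. combine the four strongest markers into an integer score (age > 53 and
   TLC/DLCO > 1.67 at 3 points each; 6MWD < 507.5 m and sat6 < 93 % at 2
   points; positive at ≥ 6 of 10).

All cutoffs are strict inequalities: a value exactly at a cutoff is never
at-risk. This follows the source wording ("exceeding", ">", "<") and
makes the boundary behaviour testable rather than implicit.

### The echo classifier

TRV bands ≤ 2.8 / (2.8, 3.4] / > 3.4 m/s and PASP bands ≤ 36 / (36, 50] /
> 50 mmHg map to `unlikely` / `possible` / `likely`; additional echo signs
upgrade the bottom band to `possible`. Two gaps in the published table are
closed explicitly: (i) values in the unprinted intervals (2.8, 2.9) m/s
and (36, 37) mmHg are assigned to the middle band via half-open intervals,
because the classifier must be total; (ii) the bottom-band-with-signs row
carries no printed label in the source rendering, and we assign `possible`
as the 2009 guideline it cites does. When TRV and PASP disagree, the
higher category wins — in a screening context the asymmetric cost of a
missed PH argues for sensitivity, and the criteria are printed as parallel
alternatives.

## The synthetic cohort: a stated world

No patient-level data accompany the study, so the generator emulates the
published *group-level* structure: two strata (n = 52 and n = 41) with the
printed mean ± SD for age, pack-years, 6MWD, baseline saturation, walk
desaturation, FEV1/FVC, FVC, TLC, DLCO and NT-proBNP. Those printed
moments **are** the generator defaults; nothing was tuned.

Choices the published numbers forced or left open:

- **Families.** All variables are truncated normal (lower bound 0; 18 for
  age matching the study's exclusion criterion; upper bound 100 for
  saturations and FEV1/FVC) except NT-proBNP, which is lognormal with
  method-of-moments parameters: its printed group-B SD (300.7 pg/ml)
  exceeds the mean (150.7 pg/ml), which no near-normal nonnegative
  variable can do. The moment match is exact
  (`fit_lognormal_moments()`), so the *population* mean/SD equal the
  printed values. Truncation shifts means slightly where a bound sits
  close to the mean (notably desaturation, bounded at 0 less than one SD
  below the group-A mean); parameter-recovery tests therefore only bind
  where the bound is ≥ 2 SD away.
- **sat6 is derived, not sampled.** The three printed saturation rows are
  jointly inconsistent under independent sampling (group A: 96.6 − 93.4 =
  3.2 against a printed desaturation of 3.3; group B is self-consistent at
  95.8 − 89.1 = 6.7). The generator trusts `sat0` and `desaturation` and
  sets `sat6 = sat0 − desaturation`, guaranteeing the record invariant
  `sat6 ≤ sat0`.
- **Dependence.** The study reports no correlations. TLC and DLCO are
  coupled through a Gaussian copula with rank correlation 0.5 —
  physiologically both shrink with restrictive severity, and a moderate
  positive value is what field data typically show — and this is a
  documented free parameter, not a claim about the study. All other pairs
  are independent; no causal structure (e.g. age→6MWD decline) is
  attempted.
- **The ratio dilemma.** With TLC and DLCO sampled as correlated
  marginals, the TLC/DLCO ratio *emerges*, and its cohort mean approaches
  the ratio of means (≈ 1.68 in group B), not the printed mean-of-ratios
  (1.86 ± 0.6) — Jensen's inequality, not a bug. Because the emergent
  ratio is also much noisier than the printed one, ROC experiments on the
  ratio itself should use `default_params(ratio_mode = TRUE)`, which
  samples the ratio directly with the printed per-group moments and backs
  DLCO out as `tlc_pct / ratio`. At seed 1 that mode reproduces the
  study's regime for the ratio (AUC ≈ 0.77).
- **Invented pieces, labelled as such.** VC (% predicted) has no printed
  per-group row but VC/DLCO does; VC is synthesized as FVC times a
  truncated-normal(1.02, 0.03) factor. Sex and diagnosis are drawn with
  the whole-cohort frequencies (65 M/28 F; 42/22/21/8). Both are
  plumbing, not emulation.

**What a green test establishes.** The generator matches marginal moments
and hard physical constraints under a fixed seed. It does *not* reproduce
the study's joint distribution, so cohort-dependent statistics — the
printed p-values, per-marker AUCs, odds ratios and the composite AUC
0.867 — are not reproduction targets; the pipeline's correctness on those
stages is established by oracle-equivalence and coverage properties
instead. The default synthetic cohort yields a composite-score AUC ≈ 0.81
at seed 1: the right direction and magnitude, asserted only as > 0.5.

## Statistical machinery and numerical choices

- **Test selection** mirrors the published rule: Shapiro–Wilk normality in
  both groups and an F test of variance homogeneity (both at α = 0.05, a
  level the source does not state) gate a pooled-variance Student t; any
  failure falls back to Mann–Whitney U. The normality gate is a pluggable
  function (the default delegates to the Royston approximation); the
  pipeline's behaviour is specified only through the p-value contract.
- **Mann–Whitney U** uses the rank formula (equal by construction to the
  concordant-pair count with half-ties) with exact enumeration of all
  group assignments when both n ≤ 8, and a tie-corrected,
  continuity-corrected normal approximation above that. The chi-square
  test applies Yates' correction by default exactly when an expected
  count falls below 5.
- **ROC curves** enumerate every attainable operating point: candidate
  cutoffs are midpoints between adjacent distinct values plus ±∞
  sentinels. Midpoints (rather than observed values) are consistent with
  the published cutpoints (507.5 m, 1.67); either convention yields the
  same operating points, midpoints are symmetric under label reversal.
- **AUC** is trapezoidal over that staircase, which equals the
  Mann–Whitney estimator exactly (a frozen test property). The **DeLong**
  variance uses the structural components `var(V10)/n_pos +
  var(V01)/n_neg`; the 95 % interval is formed on the logit scale and
  back-transformed, keeping it in (0, 1). Perfect separation has zero
  DeLong variance: the interval collapses to the point estimate with a
  warning rather than a fabricated width. The published AUC intervals
  (whose upper bounds equal the point estimates) are malformed and are
  deliberately not reproduced.
- **Youden ties** are broken towards higher specificity — matching the
  emphasis that TLC/DLCO was the *most specific* indicator — then towards
  the cutoff farthest from the pooled median, a deterministic stability
  rule. PPV/NPV are evaluated at the study prevalence 41/93; this
  convention is validated by the reconstruction targets below.
- **Logistic regression** is Newton/IRLS with step damping (steps capped
  at 10 on the log-odds scale), convergence declared at score norm
  < 1e−8 within 50 iterations. For a univariate fit, complete separation
  is decided exactly (disjoint class-wise covariate ranges) and flagged
  `converged = FALSE` — damping can flatten the score numerically long
  before the slope visibly diverges, so the geometric test is the honest
  one. Intervals are Wald (not profile likelihood), matching common
  practice for this analysis vintage; a documented limitation for small
  cells. The 2×2 odds ratio uses the closed form with log-scale SE
  `sqrt(1/a + 1/b + 1/c + 1/d)` and the Haldane–Anscombe +0.5 correction
  only on request, flagged.
- **Score decision rule**: the source gives an "optimal cut off score" of
  6 without stating inclusivity; we use ≥ 6, the only reading under which
  the optimum itself is in the positive class. Both per-unit and
  dichotomized odds ratios are reported for every variable, because the
  published risk table mixes the two flavours without labelling them.
- **Confusion reconstruction.** Printed sensitivity/specificity are
  rounded; with known strata sizes the integer counts are recoverable by
  nearest-integer rounding (half away from zero). Sens 0.66/spec 0.94 on
  41/52 gives tp=27, fp=3, fn=14, tn=49, hence PPV 90 % and NPV 77.8 %
  (printed 78 %) — confirming both the prevalence convention and the
  printed composite operating point. The printed composite sensitivity
  66 % vs the TLC/DLCO-alone 0.65 differ only in the third digit of
  27/41 = 0.659; reconstruction uses the printed values as given.

## Known limitations

- Marginal emulation only: no causal inter-variable structure, so joint
  statistics (and therefore any cohort-dependent published number) are
  out of reach by design.
- The copula strength and the VC synthesis factor are invented defaults,
  clearly flagged; conclusions sensitive to them should vary them.
- Wald intervals and the normal-approximation Mann–Whitney p are
  asymptotic; at the study's n they are adequate but not exact.
- The echo classifier implements the 2009 banding; later guidelines
  changed both bands and terminology.
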