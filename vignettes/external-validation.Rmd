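---
title: "Validating external survival predictions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating external survival predictions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progval)
```

## The problem

A prognostic tool hands a clinician a probability — say, a 10-year
survival probability for a woman with early breast cancer, computed by an
external web tool from age, ER status, tumour size, grade and nodal
status. Before such a number is allowed to influence treatment, two
questions must be answered on local data:

1. **Agreement** — do the predicted probabilities match the survival
   actually observed in this population, overall and within clinically
   meaningful subgroups?
2. **Added value** — do markers the external tool ignores (HER2 status,
   mitotic index, Ki67, a genomic signature) carry prognostic
   information beyond its prediction?

`progval` implements this two-stage validation for any external model
that outputs individual outcome probabilities, treating the external
model strictly as a black box: only its predicted probability per
patient enters the analysis. Censoring is deliberately out of scope —
the data model is a known binary status at a fixed horizon, with
patients of unknown status excluded upstream (and counted).

## Stage 1: calibration

With binary outcomes \(Y_i\) (1 = alive at the horizon) and external
predictions \(p_i \in (0,1)\), the recalibration model is

\[
\operatorname{logit} P(Y_i = 1) = \alpha + \beta \,\operatorname{logit}(p_i),
\]

and perfect calibration is the joint null \((\alpha, \beta) = (0, 1)\).
This regression-based test is the appropriate tool at the few-hundred
patient scale of typical single-centre validation cohorts, where
grouping patients into near-constant-risk sets would leave the sets too
small to compare observed proportions against predictions.

Choices the literature leaves open, and what this package does:

* **Test statistic.** The hypothesis names the null, not the statistic.
  The default is the 2-df likelihood-ratio test against the fully
  constrained model (prediction logit as a pure offset, zero free
  parameters), which is better behaved than Wald at subgroup sizes of a
  few dozen; `test = "wald"` is available. A 1-df
  "calibration-in-the-large" variant (`hypothesis = "intercept"`) frees
  only \(\alpha\), holding \(\beta = 1\).
* **Subgroup p-values.** The same joint test is applied within each
  subgroup of the agreement table. Published tables of this kind do not
  always state which test produced their per-subgroup p-values, so no
  claim is made that these reproduce any specific printed p-value;
  the predicted/observed means and their difference, however, are exact
  arithmetic.
* **Boundary predictions.** External tools sometimes round predictions
  to 0 or 1, where the logit is undefined. Predictions are clipped to
  \([10^{-6}, 1-10^{-6}]\) before any logit; the margin is far inside
  the resolution of any actuarial tool.
* **Degenerate subgroups.** A subgroup with a single outcome class, or
  a fit with separation (detected via non-convergence or coefficient
  standard errors above 25 on the logit scale), is flagged non-estimable
  and its p-value reported missing — never fabricated. Structurally
  empty subgroups appear as \(n = 0\) rows so the table layout is stable
  across cohorts.

For figures, `bin_predictions()` tiles \([0,1]\) with half-open
intervals of width 0.05 (final interval closed at 1) and returns mean
predicted versus observed survival per bin — the data behind the
classic calibration scatter around the identity line.

## Stage 2: added value via offset logistic regression

For a covariate \(X_i\), the model

\[
\operatorname{logit} P(Y_i = 1) = \alpha + \beta X_i + \operatorname{logit}(p_i)
\]

enters the prediction logit with its coefficient *fixed at 1* (an
offset), so the external model's prognostic content is taken as given
and \(\beta\) measures only the departure from it. Two modes map onto
two different questions:

* **Multivariate** (all predictors the external model already uses,
  together): a significant \(\beta\) means the predictor's association
  with outcome in the validation population differs from the population
  the external model was developed on.
* **Univariate** (each candidate marker separately): a significant
  \(\beta\) means the marker adds prognostic information the external
  model does not capture.

Reports label the two modes accordingly, because the same number means
different things in the two designs. Each factor gets a single
likelihood-ratio p-value on its full level set (reference-coded; the
reference is the first schema level), rather than per-level Wald p's —
one p per variable regardless of how many levels it has. Wald intervals
\(\exp(\hat\beta \pm 1.96\,\mathrm{SE})\) are reported for the odds
ratios. Empty levels are dropped and recorded; a variable with a single
observed level is refused by the fitting functions and skipped, with a
warning, by the pipeline (an all-node-negative cohort simply cannot
inform a nodal coefficient).

## Accuracy gains: predictive inaccuracy, explained variation, AUC

The clinical worth of an added marker is summarised by three
quantities, computed on the fitted probabilities \(\hat\pi_i\) of each
offset model:

* **Predictive inaccuracy** \( \mathrm{PI} = \tfrac1n \sum_i |Y_i - \hat\pi_i| \),
  the mean absolute prediction error; a constant predictor at the
  outcome mean \(m\) attains \(2m(1-m)\).
* **Explained variation**
  \( \mathrm{EV} = 100\,(\mathrm{PI}_0 - \mathrm{PI}_M)/\mathrm{PI}_0 \),
  the proportional PI reduction of model \(M\) against the offset-only
  reference — an \(R^2\)-like measure for binary outcomes that can go
  negative when a marker adds noise. The proportional-reduction form is
  the one consistent with published PI/EV pairs of this analysis style
  (to within their 3-decimal rounding), and is documented here as an
  inferred, not quoted, formula.
* **AUC**, computed by midranks (ties count one half) and therefore
  exactly equal to the mean over all survivor/non-survivor pairs; its
  confidence interval uses the DeLong asymptotic variance from
  placement values. A bootstrap CI was considered and rejected as the
  default because the symmetric bracketed intervals typical of this
  literature indicate an asymptotic method.

Standard errors for PI and EV come from a case bootstrap: patients are
resampled with replacement \(B = 200\) times, every model (including
the offset-only reference) is *refit* on each resample, and the SE is
the SD across resamples. Refitting, rather than re-scoring frozen
models, is the statistically defensible reading of a bootstrap of model
performance. All models in one accuracy table share one resample set,
so EV contrasts are within-resample. Failed resamples are dropped and
counted; above 20% failures the SE is flagged unreliable. Evaluation is
in-sample (apparent performance) by design — the validation itself is
the out-of-sample act; no optimism correction is applied, and the
documentation says so rather than pretending otherwise.

## The synthetic cohort generator

Patient-level records behind published validation studies are
generally unavailable, so the package ships a generator whose output
has exactly the statistical structure the pipeline is built to detect.
Per patient: covariates are drawn independently from per-level
frequencies; a latent score \(s_i \sim N(\mu, \sigma)\) on the logit
scale is reported as the prediction \(p_i = \operatorname{expit}(s_i)\);
and the outcome is Bernoulli with

\[
\pi_i = \operatorname{expit}\big(\alpha^* + \beta^* s_i + \textstyle\sum \gamma X_i + \sum \delta\, 1[\text{subgroup}]\big).
\]

\((\alpha^*, \beta^*)\) is the *true* calibration (the recalibration
module should recover it), \(\delta\) injects subgroup-confined
miscalibration (the agreement table should localise it), and \(\gamma\)
injects prognostic signal beyond the prediction (the offset models
should detect it). Identical seeds give byte-identical cohorts, and all
randomness is locally scoped — no global RNG state is touched.

Two built-in profiles emulate the published French (n = 435,
node-negative, ~12.6% 10-year mortality) and Dutch (n = 247, younger
and more aggressive, ~33.6% mortality) breast-cancer cohorts:
covariate marginals are the published baseline counts; \(\mu\) and
\(\alpha^*\) are *solved by quadrature root-finding* so the expected
mean prediction and expected survival equal the published values (85.1%
and 87.4% French; 78.6% and 66.4% Dutch) — fixed conditions, not tuned
dials. The latent-score SD is set to 0.9, giving a prediction spread
(roughly 0.5–0.98 for the French profile) matching the published
calibration figures. Default shifts and effects are taken from the
published tables: a −1.3 logit shift for Dutch patients under 40 (the
headline over-optimism of that cohort), −1.0 and −0.5 for French
under-40 and grade-3 patients, and covariate effects equal to the log
of the published univariate odds ratios (e.g. \(\log 8.21\) for the
70-gene signature).

What the generator deliberately does **not** emulate: covariates are
sampled independently (published baseline tables give only marginals),
and the prediction is independent of the covariates given the latent
score. In real data the external tool computes its prediction *from*
those covariates, so subgroup mean predictions vary (e.g. lower
predicted survival in grade-3 patients) in a way synthetic cohorts will
not reproduce. Passing tests therefore demonstrate that the estimators
recover known truth under the model's own assumptions — not that any
real tool is well or poorly calibrated. A user-supplied joint sampler
can replace the independent draws when correlated scenarios matter.

## Numerical choices

* Logistic fits use iteratively reweighted least squares
  (`stats::glm`), convergence on the deviance at its default `1e-8`
  tolerance, 25 iterations.
* Likelihood-ratio statistics are floored at 0 to absorb rounding in
  saturated fits.
* The profile-calibration solves use `integrate` (relative tolerance
  `1e-10`) inside `uniroot` (tolerance `1e-9`) on \(\mu \in [-8, 8]\)
  and \(\alpha^* \in [-12, 12]\).
* Ties in AUC are handled by midranks; the pairwise definition with
  half-weight ties is the reference implementation used in tests.
* Percentages are carried unrounded internally; rendering rounds to one
  decimal.

## Problem sizes used in the test suite

The simulation suites were sized to give stable Monte-Carlo verdicts at
interactive runtimes: test size of the joint calibration test from
2000 cohorts of n = 435; estimator bias over a
\(\{-1,0,1\} \times \{0.5,1,2\}\) grid of true \((\alpha^*, \beta^*)\)
with 500 replicates at n = 2000 (bias bounded by 4 Monte-Carlo SEs,
covering the 18 simultaneous comparisons); offset-effect recovery
averaged over 10 replicates at n = 5000; factor-test size from 1500
null replicates at n = 300; AUC checked against the brute-force
pairwise oracle on 1000 random tied instances up to n = 200.

## Known limitations

* No survival-time modelling: a cohort is a snapshot at one horizon;
  patients lost before the horizon must be resolved upstream.
* In-sample accuracy metrics, as discussed above.
* The subgroup p-values answer "is the prediction calibrated within
  this subgroup", which is related to but not identical with "does
  predicted minus observed differ from zero"; both readings exist in
  the literature and the package makes its choice explicit.
* Between-cohort comparison tests (the P column of a typical baseline
  table) are intentionally not part of the default report: published
  tables of that kind rarely state their tests, and the comparison is
  orthogonal to validation.
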