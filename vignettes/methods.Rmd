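---
title: "Doubly robust analysis of web-CBT trials with a predicted-compliance specifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly robust analysis of web-CBT trials with a predicted-compliance specifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Three-arm randomized trials of web-based cognitive behavioral therapy
(wb-CBT) compare a *guided* modality (the program plus weekly written
feedback from a human coach), a *self-guided* modality (identical content,
no human support), and treatment as usual (TAU). Two features make the
analysis of such trials harder than a textbook RCT:

1. **Attrition.** Follow-up questionnaires at 3 and 12 months are missed by
   a third or more of participants, non-randomly: completion differs by
   arm, country, and recruitment source. Complete-case rates are therefore
   biased estimates of the per-arm outcomes.
2. **Compliance is post-randomization.** The hypothesis that self-guided
   wb-CBT works for the subset of people who would keep using it cannot be
   tested by conditioning on *observed* usage (a post-treatment variable).
   Instead, a *predicted* compliance score is built from baseline
   covariates only — trained on observed usage in the self-guided arm with
   nested cross-validation — and used as a baseline specifier for subgroup
   effect estimation in all arms.

`predcomply` implements this full analytic pipeline, together with a
synthetic trial generator with known ground truth so that every stage is
testable without access to restricted trial data.

## Outcomes and scales

Anxiety is measured by the GAD-7 (0–21), depression by the PHQ-9 (0–27);
their sum is the PHQ-ADS (0–48). The primary outcome is *joint remission*:
scoring 0–4 on both scales at a follow-up wave. The secondary outcome is
the mean PHQ-ADS. Trial eligibility at baseline is GAD-7 ≥ 10 or
PHQ-9 ≥ 10. Severity bands (used for randomization strata and descriptive
tables) are 0–9 / 10–14 / ≥15 for the GAD-7 and 0–9 / 10–14 / 15–19 / ≥20
for the PHQ-9; the five-level comorbidity cross-classification pools
PHQ-9 ≥ 15 into "severe". The comorbidity function is total on the whole
score grid; a sixth "mild/none on both" level exists mathematically but
cannot occur among eligible participants.

## Adjusted per-arm estimates under attrition

For an arm $a$ and wave $w$, the estimand is the mean potential outcome
$\psi_a = E[Y_a]$ (remission probability, reported in percent, or PHQ-ADS
mean). Randomization gives known assignment probabilities (1/3); the
problem is missing outcomes. Two nuisance functions are fit:

* an **outcome regression** $\bar Q_a(W) = E[Y \mid W, A=a, C=1]$, a
  quasibinomial logistic regression of the $[0,1]$-rescaled outcome on
  baseline covariates $W$ among completers of the wave in arm $a$;
* a **response propensity** $g_C(W, A) = P(C=1 \mid W, A)$, a logistic
  regression of completion on arm and covariates, truncated below at a
  configurable bound (default 0.01) as a positivity guard.

The default estimator is targeted (TMLE-style): $\bar Q_a$ is updated by a
one-dimensional logistic fluctuation with the inverse-probability "clever
covariate" $H_a = \mathbf 1\{A=a, C=1\}/(g_a\, g_C)$, and
$\hat\psi_a = \frac1n \sum_i \bar Q_a^*(W_i)$. Standard errors come from
the empirical variance of the efficient influence curve
$H_a (Y - \bar Q^*_a) + \bar Q^*_a - \psi_a$; covariances between arms
(participants contribute to one arm but share nuisance fits) come from
cross-products of influence contributions. An augmented-IPW mode
(`estimator = "aipw"`) is provided as a cross-check. Because the outcome is
rescaled to $[0,1]$ and the update is logistic, remission estimates cannot
leave $[0, 100]$ even under extreme weights.

Either nuisance being correctly specified suffices for consistency (double
robustness); the test suite verifies both directions by simulation, and
verifies 95% CI coverage within [92%, 98%] at $n = 2000$.

**Arm-assignment probabilities.** By default $g_a$ is the realized arm
share $n_a/n$ rather than the theoretical 1/3 (`g_mode = "known"` switches
to 1/3). Conditioning on the realized allocation makes the no-missingness
collapse exact: with full follow-up and intercept-only nuisances, every
estimator returns the raw arm mean to numerical precision. With covariates
the adjusted estimate is an efficiency-adjusted version of the arm mean,
equal to it only asymptotically — the collapse identity is therefore
stated, and tested, for the intercept-only configuration.

**Contrasts.** Pairwise adjusted risk differences (ARD) and mean
differences (AMD) use 1-df Wald chi-squares $(\Delta/\mathrm{SE})^2$; the
overall 3-arm test is the 2-df quadratic form of any two independent
contrasts (invariant to the choice). Descriptive tables use plain Pearson
chi-squares without continuity correction. Two-sided $\alpha = .05$
throughout, no multiplicity correction.

## Twelve months: partial follow-up and imputation

Some participants respond at 3 months but not 12. The longitudinal
(sequential-regression) estimator uses them: among double completers the
12-month outcome is regressed on baseline covariates plus 3-month data and
targeted with the cumulative weight $1/(g_a g_{C_1} g_{C_2})$; the targeted
predictions are then regressed on baseline covariates among 3-month
completers and targeted again with $1/(g_a g_{C_1})$. When no participant
has partial follow-up the sequential stage carries no information and the
implementation delegates exactly to the single-wave estimator.

Participants with 12-month but no 3-month data cannot enter the sequential
form directly. Following standard practice their 3-month scores are first
multiply imputed by predictive mean matching (linear model of the 3-month
PHQ-ADS on baseline covariates and 12-month scores among double
completers; each recipient takes the observed scores of one of its $k=5$
nearest donors by predicted mean; $m = 20$ completed datasets by default),
and per-dataset estimates are pooled by Rubin's rules. The trial that
motivated this design did not state $m$ or $k$; the defaults are the
common choices for this amount of missingness.

## The synthetic trial generator

The generator is first-class, tested code: it defines the study conditions
under which the estimators are validated.

* **Cohort.** Demographics emulate a two-country university sample
  (~79% female, seven universities, three recruitment strata, four
  sexual-orientation and age-group levels), plus a fixed 30-covariate
  baseline battery spanning eleven domains (see `covariate_codebook()`),
  with stable names so attribution output is reproducible. Baseline
  GAD-7/PHQ-9 scores are drawn from a correlated bivariate model and
  rejection-sampled to eligibility; the marginal severity-band mix
  approximates a clinically enrolled sample (baseline PHQ-ADS mean ≈ 29).
* **Randomization.** Permuted blocks (default size 3) within
  sex × GAD-7 band × PHQ-9 band strata. The source trial reported
  stratification "by sex and severity" without stating granularity or
  block size; both are configuration parameters.
* **Usage.** Weekly minutes are zero-inflated log-normal: each
  participant-week is active with an arm × period probability shifted by a
  latent per-participant compliance propensity, and active weeks draw
  log-normal minutes. Default marginal means are calibrated to a guided
  arm that uses ~12.5 min/week in weeks 1–12 against ~5.9 for self-guided,
  reversing to ~0.2 vs ~0.4 min/week in weeks 13–52 — large SD/mean ratios
  as observed in real platform metadata. Intercept corrections keep these
  marginal means invariant to the signal strength.
* **Compliance signal.** The latent propensity mixes a fixed linear index
  of the codebook covariates with independent noise.
  `compliance_signal_r2` targets the *out-of-fold* CV R² a shrinkage
  learner attains at the trial's self-guided arm size (~440): weak-signal
  prediction at that scale is attenuated by estimation noise, and the
  population covariate share is calibrated (constant factor, measured
  once) so the realized nested-CV R² matches the configured value. The
  default 0.05 emulates a statistically significant but substantively weak
  signal.
* **Outcomes.** Follow-up PHQ-ADS is autoregressive in baseline severity
  plus a usage-mediated improvement — weeks 1–12 minutes drive the 3-month
  wave, weeks 13–52 minutes the 12-month wave — plus direct arm effects
  and noise with a shared participant-level component across waves
  (residual correlation 0.5), rounded and clipped to instrument ranges and
  split into GAD-7/PHQ-9 in proportion to the baseline mix. Defaults
  produce the qualitative pattern of interest: guided best at 3 months,
  self-guided best at 12 months, the latter mediated by post-guidance
  usage — hence genuine effect modification by the latent compliance
  propensity.
* **Missingness.** Wave-1 completion is logistic in arm, country,
  recruitment source and baseline severity; wave-2 completion additionally
  depends on wave-1 completion and (only then) the observed 3-month score.
  This is missing-at-random by construction, so estimator bias in
  simulations is attributable to the estimator, not to an untestable
  assumption. All four completion patterns occur; TAU has the highest
  joint completion.
* **Ground truth.** Potential usage and outcomes under every arm are
  generated with common random numbers and stored in a truth record that
  estimation code never sees; true ARDs/AMDs follow directly.

What the generator does **not** emulate: item-level questionnaires,
pandemic-era time trends, university-level clustering beyond categorical
covariates, non-adherence within TAU, or skewed/ordinal measurement error
in the scales. Passing tests therefore demonstrate correctness of the
estimators under a faithful MAR structure, not robustness to violations
the real trial might contain.

## Predicted compliance: the stacking ensemble

The compliance target is `log1p` of total minutes in weeks 13–52 (flags
allow raw totals or per-week means; the transform tames the extreme
zero-inflated skew). The prediction model is a cross-validated stacking
ensemble ("super learner"): out-of-fold predictions of each base learner
are combined with non-negative weights summing to one, chosen to minimize
cross-validated squared error (Lawson–Hanson NNLS, normalized, polished by
projected gradient on the simplex, and guarded so the ensemble's CV risk
never exceeds the best single learner's). The default library is mean-only
(a guard against negative-signal overfitting), ordinary least squares,
ridge and lasso-type penalized regression, shallow gradient-boosted trees,
and k-nearest-neighbors; the source trial named the ensemble method but
not its library.

Nested 10×10 cross-validation produces the out-of-sample scores: outer
folds are held out of base-learner fitting *and* weight estimation, so a
participant's score never comes from a model that saw them. The reported
CV R² is `1 - SSE/SST` over out-of-fold scores, with a
leave-one-fold-out jackknife SE. Self-guided participants receive their
out-of-fold scores; all other participants are scored by the full
ensemble — a counterfactual "how much would this person have used the
self-guided program". A temporal firewall (static column-name check plus
runtime assertion) guarantees the model's design matrix contains baseline
fields only.

## Specifier subgroup analysis

Predicted compliance scores are dichotomized at the top 40% (ties broken
by stable participant-id order; `ceiling(n × fraction)` in the high
group). Within each stratum the doubly robust machinery is re-run; the
arm-by-specifier interaction is a contrast-of-contrasts Wald test
$((\Delta_{high}-\Delta_{low})/\sqrt{SE^2_{high}+SE^2_{low}})^2$ on 1 df,
where $\Delta_s$ contrasts the self-guided arm against the pooled guided +
TAU comparator (a flag selects self-guided vs guided only). Under the
null-modification generator the test's type-I error is nominal
(verified at 1000 replicates); under a usage-mediated modification of
roughly a dozen remission percentage points at $n = 1319$ its power
exceeds 50% (a property of this calibration, not a claim about any real
trial). Because the 40% cut was exploratory in the motivating study,
`search_dichotomization()` implements the grid search over top fractions
with a permutation-adjusted p-value that accounts for the selection; the
default pipeline uses the fixed 0.40.

Attrition tables report, per baseline predictor, completion counts and
percentages under three definitions (both waves / 3-month / 12-month),
a Pearson main-effect chi-square, and a heterogeneity test comparing
logistic models of completion on predictor + arm versus predictor × arm
(likelihood ratio, df = (levels − 1) × 2). The heterogeneity construction
was unstated in the motivating study; the likelihood-ratio form was chosen
over stratified Pearson sums for its behavior in sparse cells.

## Attribution: kernel SHAP and proportional SHAP

Two constructions are deliberately kept side by side, because the
motivating study describes a mean-substitution computation while citing
the kernel SHAP method:

* `kernel_shap()` computes Shapley values with the coalition-weighted
  least-squares formulation — exact enumeration of all $2^p$ coalitions
  for $p \le 12$ (verified against brute-force permutation averaging),
  weighted coalition sampling beyond. The reference point is the sample
  covariate mean. Local accuracy ($\sum_j \phi_{ij} = f(x_i) - f(\bar x)$)
  holds to 1e-6 under enumeration. Dominant directions are the sign of the
  correlation between feature values and attributions (the numeric
  analogue of reading a beeswarm plot), flagged indeterminate when the
  correlation is near zero, e.g. for symmetric U-shaped dependence.
* `mean_substitution_shap()` is the verbatim substitution statistic: the
  mean absolute change in prediction when one feature is reset to its
  sample mean. `shap_p()` divides it by the whole-model statistic (all
  features reset at once) — these percentages can sum above 100% because
  participants sit above the mean on some features and below on others,
  and the statistic is scale-invariant in the model.

Ranked reports keep, per covariate domain, the top five features with mean
absolute value ≥ 0.01, ties alphabetical.

## Numerical choices and degenerate inputs

* Outcome rescaling bounds: (0, 1) for remission, (0, 48) for PHQ-ADS;
  predictions clipped away from {0, 1} before the logit.
* Fluctuation GLMs run with tightened IRLS tolerance (1e-12) so collapse
  identities hold to ~1e-9; a non-finite fluctuation coefficient falls
  back to no update.
* Separation or non-finite coefficients in any nuisance model fall back
  to intercept-only fits with a recorded flag.
* Zero completers in an arm is an error naming the arm; an empty specifier
  stratum is an error; fewer PMM donors than $k$ uses all donors with a
  warning.
* All randomness is seeded; per-stage child seeds derive deterministically
  from the master seed, so stages can be rerun in isolation and full runs
  are reproducible bit for bit.

## Problem sizes used in the test suite

The validation suite runs on a single CPU: the double-robustness bias
scenarios use 500 replicates at $n = 4000$ (designed to be exactly
unbiased by construction — the generator's true dropout propensities
supplied as the correct propensity model in one direction, a saturated
two-cell outcome regression in the other — so the two-Monte-Carlo-SE bar
tests implementation correctness rather than asymptotic approximation
quality); CI coverage uses 500 replicates at $n = 2000$ against the
population contrast measured at $n = 10^5$; ensemble signal recovery uses
20 seeds per signal level with 5×5 nested folds and a lean library on the
~440-participant self-guided arm; the interaction type-I error uses 1000
replicates at the full trial size.

## Known limitations

* The longitudinal estimator treats 12-month-only responders as censored
  unless their 3-month scores are imputed first; the pipeline does this
  automatically, standalone calls warn. The imputation bridge recovers
  those participants' information at the cost of a small finite-sample
  bias (on the order of half a remission percentage point in simulations,
  from treating imputed 3-month responses as observed in the censoring
  model); analyses where that trade-off matters can censor instead.
* The compliance model's CV R² is intentionally weak at the default
  configuration; single-seed estimates at arm size ~440 scatter roughly
  ±0.05 around the target, so inference about the signal should use the
  jackknife SE, not the point value alone.
* SHAP sampling beyond 12 features satisfies local accuracy only
  approximately (budget-dependent); exact enumeration is used everywhere
  it is affordable.
* Printed-scale reproduction of any specific trial's point estimates is
  out of scope: the generator emulates structure, not a particular
  dataset.
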