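# predcomply

Doubly robust analysis of three-arm web-based CBT trials with a
predicted-compliance specifier.

## The problem

Randomized trials of web-based cognitive behavioral therapy (wb-CBT)
compare a **guided** modality (program content plus weekly written coach
feedback), a **self-guided** modality (same content, no human support) and
**treatment as usual** (TAU), with GAD-7/PHQ-9 symptom questionnaires at 3
and 12 months. Two obstacles dominate the analysis:

* **Attrition.** A third or more of participants miss a follow-up wave,
  non-randomly (completion differs by arm, country and recruitment
  source), so complete-case arm means are biased.
* **Compliance is post-randomization.** Whether self-guided wb-CBT works
  *for people who would keep using it* cannot be answered by conditioning
  on observed usage. It can be answered with a baseline-only **predicted
  compliance** score: a nested cross-validated stacking ensemble (super
  learner) trained on observed post-guidance usage (minutes/week in weeks
  13–52) in the self-guided arm, then scored counterfactually for every
  participant and used as a subgroup specifier.

`predcomply` implements the whole pipeline for biostatisticians working on
digital mental-health trials:

* GAD-7 (0–21), PHQ-9 (0–27) and PHQ-ADS (0–48) scoring; joint remission
  (0–4 on both scales); severity and comorbidity categories; eligibility.
* A synthetic trial generator with known ground truth: block randomization
  stratified by sex and symptom severity, zero-inflated log-normal weekly
  usage with a configurable baseline-covariate compliance signal,
  usage-mediated outcomes and missing-at-random wave-specific dropout.
* Targeted minimum loss-based (and augmented-IPW) per-arm estimates of
  remission rates and PHQ-ADS means under attrition, with influence-curve
  SEs, pairwise adjusted risk/mean differences (ARD/AMD), 2-df overall
  tests, a longitudinal variant using partial follow-up, and predictive
  mean matching multiple imputation with Rubin pooling.
* Top-fraction dichotomization of predicted compliance, the
  arm-by-specifier Wald interaction test, stratified effect tables and
  attrition-pattern tables.
* Kernel SHAP (exact coalition enumeration for ≤12 features) and the
  proportional mean-substitution SHAP (SHAP_P) attribution of the
  compliance model.

The core model: for arm *a*, the per-arm estimand E[Y_a] is estimated as
the mean of a targeted outcome regression, ψ̂_a = (1/n) Σ Q̄*_a(W_i), where
Q̄*_a is a logistic fluctuation of E[Y | W, A=a, C=1] along the clever
covariate 1{A=a, C=1}/(g_a · P(C=1 | W, A)); consistency requires only one
of the two nuisance models to be correct.

## Worked example

```r
library(predcomply)

cfg   <- generator_config(n = 1319, seed = 2026)
trial <- generate_trial(cfg)
trial
#> Synthetic three-arm wb-CBT trial: 1319 participants
#>   arms: guided=441, self_guided=437, tau=441
#>   completion: 3mo 67.9%, 12mo 66.8%, both 52.8%

data <- analysis_frame(trial)
fit3 <- dr_estimate(data, "remission_3", "c3",
                    covars = c("country_mexico", "clinic_waitlist",
                               "clinic_campus", "severe_baseline"))
fit3
#> Doubly robust per-arm estimates (tmle), outcome 'remission_3', n=1319
#>          arm value    se n_arm
#>       guided 26.99 2.600   441
#>  self_guided 17.96 2.397   437
#>          tau 16.82 2.009   441

contrasts_from(fit3)$contrasts
#>                   pair difference   se  chi2 df       p
#>  guided vs self_guided       9.03 3.52 6.577  1 0.01033
#>          guided vs tau      10.17 3.27 9.662  1 0.00188
#>     self_guided vs tau       1.14 3.11 0.133  1 0.71489
```

The adjusted 3-month joint remission rate is 27.0% (SE 2.6) under guided
wb-CBT versus 18.0% under self-guided and 16.8% under TAU: a 9.0
percentage-point ARD for guided vs self-guided (χ²₁ = 6.6, p = .01),
reproducing the short-term guided advantage this generator builds in. The
full pipeline adds the compliance model and specifier analysis:

```r
res <- run_pipeline(run_config(
  generator = cfg, seed = 7, mi_m = 5,
  learner_names = c("mean", "lm", "ridge", "lasso"),
  covars = c("country_mexico", "clinic_waitlist", "clinic_campus",
             "severe_baseline", "gad7_0", "phq9_0")))
res
#> predcomply pipeline result
#>   n=1319; cv R^2 of predicted compliance: 0.055 (SE 0.024)
#>   12-month joint remission (adjusted):
#>          arm value   se n_arm
#>       guided  10.9 1.73   441
#>  self_guided  11.7 1.76   437
#>          tau  11.0 1.73   441
#>   arm x specifier interaction: chi2(1)=0.39, p=0.533
```

The nested-CV R² of 0.055 (SE 0.024) says baseline covariates predict
post-guidance compliance weakly but detectably — the generator's default
calibration. At a single trial of this size such a weak specifier often
fails to resolve the 12-month subgroup effect, as here (interaction
χ²₁ = 0.4); the test suite verifies the test's size and power across many
replicates rather than one draw. `res$shap$ranked` lists the top
predictors per covariate domain behind the compliance score.

## Package layout

* `R/scales.R` — instrument scoring, remission, severity/comorbidity
* `R/generator.R`, `R/codebook.R` — synthetic trial generator + covariate
  schema
* `R/estimation.R` — nuisance fits, TMLE/AIPW, longitudinal variant, PMM,
  Rubin pooling, contrasts and tests
* `R/compliance.R` — usage summaries and the compliance target
* `R/superlearner.R` — stacking ensemble, nested CV, counterfactual
  scoring
* `R/heterogeneity.R` — dichotomization, interaction test, stratified
  tables, attrition tables
* `R/shap.R` — kernel SHAP, mean-substitution SHAP_P, rankings
* `R/pipeline.R` — orchestration, validation, CSV/JSON I/O
* `vignettes/methods.Rmd` — the model, assumptions, calibration and
  limitations
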