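# Shared fixtures and independent oracles, built in code at load time.

# Nuisance covariate sets: the default dropout model is logistic in exactly
# these baseline fields (plus arm), so the propensity model is correctly
# specified when it uses them.
PROP_COVARS <- c("country_mexico", "clinic_waitlist", "clinic_campus",
                 "severe_baseline")
RICH_COVARS <- c(PROP_COVARS, "gad7_0", "phq9_0")

# One small default trial reused across test files.
small_trial <- local({
  tr <- generate_trial(generator_config(n = 600, seed = 314))
  function() tr
})

small_frame <- local({
  d <- analysis_frame(small_trial())
  function() d
})

# Fully observed trial (no dropout), for collapse identities.
full_trial <- local({
  tr <- generate_trial(generator_config(n = 450, seed = 271,
                                        dropout_model = "none"))
  function() tr
})

# Generator configuration with no compliance signal and no effect
# modification pathway: the interaction test's null.
null_modification_config <- function(seed, n = 1319) {
  prof <- default_usage_profiles()
  prof$signal <- c(early = 0, late = 0, mlog_slope = 0)
  generator_config(n = n, seed = seed, compliance_signal_r2 = 0,
                   arm_usage_profiles = prof)
}

# Generator configuration with a strong usage-mediated 12-month effect
# modification (roughly a dozen remission percentage points between the
# high and low predicted-compliance strata at the default 40% cut).
strong_modification_config <- function(seed, n = 1319) {
  prof <- default_usage_profiles()
  prof$signal <- c(early = 0.8, late = 3.5, mlog_slope = 1.2)
  prof$self_guided$late[["p"]] <- 0.04
  em <- default_effect_map()
  em$wave12$beta_usage <- -2.3
  generator_config(n = n, seed = seed, compliance_signal_r2 = 0.25,
                   arm_usage_profiles = prof, effect_map = em)
}

# Oracle split on the generator's true covariate index (the signal the
# compliance model tries to recover), for by-construction subgroup checks.
oracle_split <- function(trial, top_fraction = 0.4) {
  dichotomize(data.frame(participant_id = trial$cohort$participant_id,
                         score = attr(trial$cohort, "covariate_index")),
              top_fraction)
}

# Brute-force Shapley values by averaging marginal contributions over all
# feature orderings; the independent oracle for kernel_shap on small p.
brute_shapley <- function(predict_fun, X, reference = colMeans(X)) {
  X <- as.matrix(X)
  p <- ncol(X)
  perms <- .permutations(p)
  vfun <- function(S, xrow) {
    z <- reference
    z[S] <- xrow[S]
    as.numeric(predict_fun(matrix(z, 1, p, dimnames = list(NULL,
                                                           colnames(X)))))
  }
  t(apply(X, 1, function(xrow) {
    phi <- numeric(p)
    for (pi in seq_len(nrow(perms))) {
      ord <- perms[pi, ]
      S <- integer(0)
      v_prev <- vfun(S, xrow)
      for (j in ord) {
        S <- c(S, j)
        v_new <- vfun(S, xrow)
        phi[j] <- phi[j] + (v_new - v_prev)
        v_prev <- v_new
      }
    }
    phi / nrow(perms)
  }))
}

.permutations <- function(p) {
  if (p == 1) return(matrix(1))
  sub <- .permutations(p - 1)
  do.call(rbind, lapply(seq_len(p), function(k) {
    cbind(k, matrix(c(seq_len(p)[-k])[sub], nrow(sub)))
  }))
}
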