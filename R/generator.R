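#' Configuration for the synthetic trial generator
#'
#' Builds the parameter set for a synthetic three-arm web-CBT trial: cohort
#' size and composition, block-randomization settings, per-arm weekly usage
#' profiles, the strength of the baseline-covariate signal in post-guidance
#' compliance, the outcome effect map, and the wave-specific dropout model.
#' Defaults emulate the structure of a two-country university trial:
#' 1:1:1 allocation stratified by sex and symptom severity, ~79% female,
#' guided-arm platform usage concentrated in weeks 1-12 and self-guided usage
#' persisting in weeks 13-52, compliance weakly predictable from baseline
#' covariates, 12-month benefit mediated by weeks-13-52 usage, and
#' missing-at-random dropout depending on arm, country and recruitment
#' source.
#'
#' @param n number of participants.
#' @param seed integer master seed; every downstream draw derives from it.
#' @param female_fraction expected proportion female.
#' @param compliance_signal_r2 target share of variance in the (log1p)
#'   weeks-13-52 compliance target explained by baseline covariates.
#' @param block_size randomization block size (multiple of 3).
#' @param arm_usage_profiles per-arm, per-period zero-inflated log-normal
#'   usage parameters; see Details.
#' @param effect_map coefficients mapping baseline severity, usage and arm to
#'   follow-up symptom change; see Details.
#' @param dropout_model per-wave logistic completion coefficients, or
#'   \code{"none"} for full follow-up.
#'
#' @details
#' \code{arm_usage_profiles} is a list with elements \code{guided} and
#' \code{self_guided}, each holding \code{early}/\code{late} vectors
#' \code{c(p, mlog, sdlog)}: the weekly probability of logging on and the
#' log-normal parameters of positive minutes. \code{signal} gives the slopes
#' with which the latent compliance propensity shifts the log-odds of
#' logging on (\code{early}, \code{late}) and the log-minutes mean
#' (\code{mlog_slope}). Treatment-as-usual rows have no platform access and
#' are always zero.
#'
#' \code{effect_map} holds, per wave, an intercept, an autoregressive loading
#' on baseline PHQ-ADS, a usage coefficient (on log1p total minutes in the
#' wave's period), direct arm effects, and a residual SD. Setting all usage
#' and arm coefficients to zero yields identical outcome distributions in
#' all arms.
#'
#' @return An object of class \code{generator_config}.
#' @export
generator_config <- function(n = 1319,
                             seed = 20260101,
                             female_fraction = 0.787,
                             compliance_signal_r2 = 0.05,
                             block_size = 3L,
                             arm_usage_profiles = default_usage_profiles(),
                             effect_map = default_effect_map(),
                             dropout_model = default_dropout_model()) {
  stopifnot(n >= 0, n == round(n))
  if (female_fraction < 0 || female_fraction > 1)
    stopf("female_fraction must be in [0,1]")
  if (compliance_signal_r2 < 0 || compliance_signal_r2 > 1)
    stopf("compliance_signal_r2 must be in [0,1]")
  if (block_size %% 3 != 0 || block_size < 3)
    stopf("block_size must be a positive multiple of 3")
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              female_fraction = female_fraction,
              compliance_signal_r2 = compliance_signal_r2,
              block_size = as.integer(block_size),
              arm_usage_profiles = arm_usage_profiles,
              effect_map = effect_map,
              dropout_model = dropout_model)
  class(cfg) <- "generator_config"
  cfg
}

#' @rdname generator_config
#' @export
default_usage_profiles <- function() {
  list(
    guided      = list(early = c(p = 0.35,  mlog = 2.86, sdlog = 1.2),
                       late  = c(p = 0.010, mlog = 2.28, sdlog = 1.2)),
    self_guided = list(early = c(p = 0.22,  mlog = 2.57, sdlog = 1.2),
                       late  = c(p = 0.018, mlog = 2.28, sdlog = 1.3)),
    signal = c(early = 0.8, late = 2.0, mlog_slope = 0.6)
  )
}

#' @rdname generator_config
#' @export
default_effect_map <- function() {
  list(
    wave3  = list(intercept = 2.7, lambda = 0.45, beta_usage = -0.20,
                  tau = c(guided = -1.5, self_guided = 0.45, tau = 0),
                  sd = 8),
    wave12 = list(intercept = 3.5, lambda = 0.50, beta_usage = -1.7,
                  tau = c(guided = 1.6, self_guided = 0, tau = 0),
                  sd = 8),
    # correlation of the two waves' residuals through a stable
    # participant-level severity component (beyond what baseline explains)
    rho = 0.5
  )
}

#' @rdname generator_config
#' @export
null_effect_map <- function() {
  em <- default_effect_map()
  for (w in c("wave3", "wave12")) {
    em[[w]]$beta_usage <- 0
    em[[w]]$tau[] <- 0
  }
  em
}

#' @rdname generator_config
#' @export
default_dropout_model <- function() {
  list(
    wave1 = c(intercept = -0.18, guided = 0, self_guided = -0.15, tau = 0.65,
              mexico = 0.95, waitlist = 0.85, clinic_campus = 0.40,
              severe = -0.10),
    wave2 = c(intercept = -0.55, guided = 0, self_guided = -0.08, tau = 0.30,
              mexico = -0.05, waitlist = 0.10, clinic_campus = 0.15,
              severe = 0, prev_complete = 1.60, ads3 = -0.015)
  )
}

ARM_LEVELS <- c("guided", "self_guided", "tau")

# Empirical ceiling on the R^2 of the log1p weeks-13-52 compliance target on
# the latent propensity, under the default signal slopes (measured once on a
# large simulated population).
.LATENT_R2_CEILING <- 0.42
# The configured compliance_signal_r2 targets the *out-of-fold* CV R^2 a
# shrinkage learner attains at the trial's self-guided arm size (~440),
# which is attenuated relative to the population covariate share by
# estimation noise over ~30 covariates. Population share per unit of
# configured CV R^2, calibrated once against the nested-CV recovery curve.
.SIGNAL_CALIBRATION <- 2.2

#' Generate a synthetic baseline cohort
#'
#' Draws demographics, the baseline covariate battery defined by
#' \code{\link{covariate_codebook}}, and baseline GAD-7/PHQ-9 scores. All
#' generated participants satisfy the trial eligibility rule
#' (GAD-7 >= 10 or PHQ-9 >= 10), enforced by bounded rejection sampling.
#'
#' @param config a \code{\link{generator_config}}.
#' @return A data.frame with one row per participant: identifiers,
#'   demographic factors, the numeric codebook covariates, and baseline
#'   scores \code{gad7_0}, \code{phq9_0}, \code{phq_ads_0}. The latent
#'   compliance propensity used by downstream simulation stages is attached
#'   as attribute \code{"latent"} (never visible to estimation code).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  with_seed(derive_seed(config$seed, "cohort"), {
    cohort <- .draw_cohort(n, config)
  })
}

.draw_cohort <- function(n, config) {
  cb <- covariate_codebook()
  if (n == 0) {
    out <- .empty_cohort(cb)
    return(out)
  }
  id <- sprintf("P%05d", seq_len(n))
  female <- stats::rbinom(n, 1, config$female_fraction)
  country <- sample(c("Colombia", "Mexico"), n, TRUE, prob = c(0.45, 0.55))
  # 7 universities; unam only exists in Mexico
  univ <- ifelse(country == "Mexico",
                 sample(paste0("univ_m", 1:4), n, TRUE,
                        prob = c(0.35, 0.25, 0.25, 0.15)),
                 sample(paste0("univ_c", 1:3), n, TRUE,
                        prob = c(0.4, 0.35, 0.25)))
  univ[country == "Mexico" & univ == "univ_m1"] <- "unam"
  clinic_status <- sample(c("waitlist", "clinic_campus", "no_clinic"), n, TRUE,
                          prob = c(0.22, 0.46, 0.32))
  sexor <- sample(c("heterosexual", "gay_lesbian", "bisexual", "other"),
                  n, TRUE, prob = c(0.695, 0.046, 0.148, 0.111))
  age_group <- sample(c("18-19", "20", "21-22", ">=23"), n, TRUE,
                      prob = c(0.268, 0.190, 0.301, 0.241))

  ord <- function(max, shape1 = 2, shape2 = 3)
    round(max * stats::rbeta(n, shape1, shape2))
  covs <- data.frame(
    employed = stats::rbinom(n, 1, 0.35),
    first_generation = stats::rbinom(n, 1, 0.56),
    female = female,
    age_20 = as.integer(age_group == "20"),
    age_21_22 = as.integer(age_group == "21-22"),
    age_23_plus = as.integer(age_group == ">=23"),
    country_mexico = as.integer(country == "Mexico"),
    univ_unam = as.integer(univ == "unam"),
    clinic_waitlist = as.integer(clinic_status == "waitlist"),
    clinic_campus = as.integer(clinic_status == "clinic_campus"),
    covid_stress = ord(10, 3, 3),
    chronic_stress = ord(10, 2, 3),
    sexual_assault = stats::rbinom(n, 1, 0.08),
    mde_months = ord(12, 1.2, 3),
    high_baseline = 0L,           # derived from baseline scores below
    work_impairment = ord(10, 2, 2.5),
    sad_situational = ord(16, 2, 3),
    phobia_history = stats::rbinom(n, 1, 0.30),
    prior_treatment = stats::rbinom(n, 1, 0.25),
    role_home = ord(10, 2, 3),
    role_relationships = ord(10, 2, 3),
    underweight = stats::rbinom(n, 1, 0.07),
    loneliness = ord(16, 3, 2.5),
    confidants = ord(10, 2, 3),
    irritability = ord(10, 2.5, 2.5),
    resilience = ord(10, 3, 2.5),
    helpful_reminders = ord(3, 2, 2),
    helpful_texting = ord(3, 2, 2),
    desire_stress = ord(3, 3, 2),
    desire_sleep = ord(3, 3, 2)
  )

  # Baseline symptom scores, rejection-sampled to eligibility
  draw_scores <- function(m) {
    v <- stats::rnorm(m)
    g <- round(clip(12.0 + 5.4 * (0.72 * v + 0.69 * stats::rnorm(m)), 0, 21))
    p <- round(clip(15.8 + 6.2 * (0.72 * v + 0.69 * stats::rnorm(m)), 0, 27))
    cbind(g, p)
  }
  sc <- draw_scores(n)
  for (attempt in seq_len(200)) {
    bad <- !(sc[, 1] >= 10 | sc[, 2] >= 10)
    if (!any(bad)) break
    sc[bad, ] <- draw_scores(sum(bad))
  }
  if (any(!(sc[, 1] >= 10 | sc[, 2] >= 10)))
    stopf("eligibility unreachable under configured score distribution")
  gad7_0 <- as.integer(sc[, 1]); phq9_0 <- as.integer(sc[, 2])
  ads0 <- gad7_0 + phq9_0
  covs$high_baseline <- as.integer(ads0 >= 20 & phq9_0 >= 10)

  cohort <- data.frame(
    participant_id = id, country = country, university = univ,
    clinic_status = clinic_status,
    sex = ifelse(female == 1, "female", "male"),
    sexual_orientation = sexor, age_group = age_group,
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, covs)
  cohort$gad7_0 <- gad7_0
  cohort$phq9_0 <- phq9_0
  cohort$phq_ads_0 <- as.integer(ads0)

  # Latent compliance propensity: standardized covariate index mixed with
  # independent noise so that the covariate share equals the configured
  # target on the latent scale.
  w <- cb$compliance_weight
  X <- as.matrix(cohort[, cb$name])
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  s <- drop(Xs %*% w)
  s[!is.finite(s)] <- 0
  s_sd <- if (n >= 2) stats::sd(s) else 0
  s <- if (is.finite(s_sd) && s_sd > 0) (s - mean(s)) / s_sd else s * 0
  r2l <- min(1, config$compliance_signal_r2 * .SIGNAL_CALIBRATION /
               .LATENT_R2_CEILING)
  u <- sqrt(r2l) * s + sqrt(1 - r2l) * stats::rnorm(n)
  attr(cohort, "latent") <- u
  attr(cohort, "covariate_index") <- s
  cohort
}

.empty_cohort <- function(cb) {
  base <- data.frame(participant_id = character(), country = character(),
                     university = character(), clinic_status = character(),
                     sex = character(), sexual_orientation = character(),
                     age_group = character(), stringsAsFactors = FALSE)
  for (nm in cb$name) base[[nm]] <- integer()
  base$gad7_0 <- integer(); base$phq9_0 <- integer()
  base$phq_ads_0 <- integer()
  attr(base, "latent") <- numeric()
  base
}

#' Stratified block randomization
#'
#' Assigns each participant to one of the three arms using permuted blocks
#' within strata defined by sex and the severity bands of baseline anxiety
#' (GAD-7) and depression (PHQ-9). Within every complete block the arm
#' counts are exactly equal; within every stratum they differ by at most
#' the imbalance of one incomplete block.
#'
#' @param cohort output of \code{\link{generate_cohort}}.
#' @param config a \code{\link{generator_config}}.
#' @return A data.frame \code{participant_id}, \code{arm}, \code{stratum}.
#' @export
block_randomize <- function(cohort, config) {
  n <- nrow(cohort)
  stratum <- interaction(
    cohort$sex,
    severity_category("GAD-7", cohort$gad7_0),
    severity_category("PHQ-9", cohort$phq9_0),
    drop = FALSE, sep = ":")
  arm <- character(n)
  with_seed(derive_seed(config$seed, "randomize"), {
    for (st in levels(stratum)) {
      idx <- which(stratum == st)
      if (!length(idx)) next
      nb <- ceiling(length(idx) / config$block_size)
      per_arm <- config$block_size / 3L
      blocks <- unlist(lapply(seq_len(nb), function(b)
        sample(rep(ARM_LEVELS, per_arm))))
      arm[idx] <- blocks[seq_along(idx)]
    }
  })
  data.frame(participant_id = cohort$participant_id,
             arm = factor(arm, levels = ARM_LEVELS),
             stratum = as.character(stratum),
             stringsAsFactors = FALSE)
}

#' Simulate weekly platform usage
#'
#' Weekly minutes logged on over weeks 1-52 follow a zero-inflated
#' log-normal model: each participant-week is active with a probability that
#' depends on arm, period (weeks 1-12 vs 13-52) and the participant's latent
#' compliance propensity; active weeks draw log-normal positive minutes.
#' Treatment-as-usual rows are identically zero. Intercepts are adjusted so
#' the configured marginal means are preserved at any signal strength.
#'
#' @param cohort,config as in \code{\link{block_randomize}}.
#' @param arms arm-assignment data.frame (\code{participant_id}, \code{arm}).
#' @return A data.frame \code{participant_id}, \code{week_1} .. \code{week_52}.
#' @export
simulate_usage <- function(cohort, arms, config) {
  n <- nrow(cohort)
  u <- attr(cohort, "latent") %||% numeric(n)
  out <- matrix(0, n, 52)
  if (n > 0) {
    with_seed(derive_seed(config$seed, "usage"), {
      U <- matrix(stats::runif(n * 52), n, 52)
      Z <- matrix(stats::rnorm(n * 52), n, 52)
      out <- .usage_from_draws(arms$arm, u, U, Z, config$arm_usage_profiles)
    })
  }
  colnames(out) <- paste0("week_", 1:52)
  cbind(data.frame(participant_id = cohort$participant_id,
                   stringsAsFactors = FALSE),
        as.data.frame(out))
}

# Shared-draw usage construction (common random numbers across
# counterfactual arm assignments).
.usage_from_draws <- function(arm, u, U, Z, prof) {
  n <- length(arm)
  out <- matrix(0, n, 52)
  sig <- prof$signal
  periods <- list(early = 1:12, late = 13:52)
  for (a in c("guided", "self_guided")) {
    rows <- which(arm == a)
    if (!length(rows)) next
    for (p in names(periods)) {
      pp <- prof[[a]][[p]]
      slope <- unname(sig[[p]])
      b <- sig[["mlog_slope"]]
      # intercept correction so E[plogis(c + slope*u)] = p over u ~ N(0,1)
      c0 <- .match_marginal_logit(pp[["p"]], slope)
      pa <- expit(c0 + slope * u[rows])
      # mean-log correction so the marginal participant-week mean equals
      # p * exp(mlog + sdlog^2/2) at any signal strength (activity and
      # intensity are both increasing in u, which would otherwise inflate
      # the mean through their covariance)
      gh <- seq(-6, 6, length.out = 201)
      gw <- stats::dnorm(gh); gw <- gw / sum(gw)
      infl <- sum(gw * expit(c0 + slope * gh) * exp(b * gh)) / pp[["p"]]
      ml <- pp[["mlog"]] + b * u[rows] - log(infl)
      for (wk in periods[[p]]) {
        act <- U[rows, wk] < pa
        out[rows[act], wk] <- exp(ml[act] + pp[["sdlog"]] * Z[rows[act], wk])
      }
    }
  }
  out
}

# Solve E[plogis(c + b*U)] = p for c, U ~ N(0,1), by Gauss-Legendre grid.
.match_marginal_logit <- function(p, b) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (b == 0) return(logit(p))
  gh <- seq(-6, 6, length.out = 201)
  wts <- stats::dnorm(gh); wts <- wts / sum(wts)
  f <- function(c0) sum(wts * expit(c0 + b * gh)) - p
  stats::uniroot(f, c(-30, 30))$root
}

#' Simulate follow-up symptom scores (pre-dropout)
#'
#' Potential follow-up PHQ-ADS scores at 3 and 12 months: an autoregressive
#' pull from baseline plus a usage-mediated improvement (weeks-1-12 minutes
#' drive the 3-month wave, weeks-13-52 minutes the 12-month wave), direct
#' arm effects, and Gaussian noise; scores are rounded and clipped to the
#' instrument ranges and split into GAD-7/PHQ-9 components in proportion to
#' the baseline mix.
#'
#' @param cohort,arms,config as above.
#' @param usage output of \code{\link{simulate_usage}}.
#' @return A data.frame \code{participant_id}, \code{gad7_3}, \code{phq9_3},
#'   \code{phq_ads_3}, \code{gad7_12}, \code{phq9_12}, \code{phq_ads_12}.
#' @export
simulate_outcomes <- function(cohort, arms, usage, config) {
  n <- nrow(cohort)
  if (n == 0) {
    return(data.frame(participant_id = character(),
                      gad7_3 = integer(), phq9_3 = integer(),
                      phq_ads_3 = integer(), gad7_12 = integer(),
                      phq9_12 = integer(), phq_ads_12 = integer()))
  }
  with_seed(derive_seed(config$seed, "outcomes"), {
    e3 <- stats::rnorm(n); e12 <- stats::rnorm(n)
    b <- stats::rnorm(n)
    rjit <- stats::rnorm(n, 0, 0.05)
    .outcomes_from_draws(cohort, arms$arm, usage, config$effect_map,
                         e3, e12, rjit, b)
  })
}

.outcomes_from_draws <- function(cohort, arm, usage, em, e3, e12, rjit,
                                 b = numeric(length(e3))) {
  rho <- em$rho %||% 0
  e3 <- rho * b + sqrt(1 - rho^2) * e3
  e12 <- rho * b + sqrt(1 - rho^2) * e12
  wk <- as.matrix(usage[, paste0("week_", 1:52)])
  early <- rowSums(wk[, 1:12, drop = FALSE])
  late <- rowSums(wk[, 13:52, drop = FALSE])
  ads0 <- cohort$phq_ads_0
  mk <- function(p, mins, eps) {
    mu <- p$intercept + p$lambda * ads0 + p$beta_usage * log1p(mins) +
      unname(p$tau[as.character(arm)])
    round(clip(mu + p$sd * eps, 0, 48))
  }
  ads3 <- mk(em$wave3, early, e3)
  ads12 <- mk(em$wave12, late, e12)
  ratio <- clip(cohort$gad7_0 / pmax(cohort$phq_ads_0, 1) + rjit, 0.05, 0.95)
  split <- function(ads) {
    g <- as.integer(clip(round(ads * ratio), 0, 21))
    p <- as.integer(clip(ads - g, 0, 27))
    list(g = g, p = p)
  }
  s3 <- split(ads3); s12 <- split(ads12)
  data.frame(participant_id = cohort$participant_id,
             gad7_3 = s3$g, phq9_3 = s3$p, phq_ads_3 = s3$g + s3$p,
             gad7_12 = s12$g, phq9_12 = s12$p,
             phq_ads_12 = s12$g + s12$p,
             stringsAsFactors = FALSE)
}

#' Simulate wave-specific completion (dropout)
#'
#' Completion of the 3-month questionnaire is logistic in baseline
#' covariates and arm; completion of the 12-month questionnaire additionally
#' depends on whether the 3-month wave was completed and (only then) on the
#' observed 3-month score, keeping the mechanism missing at random by
#' construction. All four observable patterns (both waves, 3-month only,
#' 12-month only, neither) can occur.
#'
#' @param cohort,arms,config as above.
#' @param outcomes output of \code{\link{simulate_outcomes}}.
#' @return A data.frame \code{participant_id}, \code{c3}, \code{c12}
#'   (0/1 completion flags).
#' @export
simulate_missingness <- function(cohort, arms, outcomes, config) {
  n <- nrow(cohort)
  dm <- config$dropout_model
  if (identical(dm, "none") || n == 0) {
    return(data.frame(participant_id = cohort$participant_id,
                      c3 = rep(1L, n), c12 = rep(1L, n)))
  }
  severe <- as.integer(cohort$gad7_0 >= 15 | cohort$phq9_0 >= 20)
  armc <- as.character(arms$arm)
  lin <- function(co, extra = 0) {
    co[["intercept"]] +
      unname(co[armc]) +
      co[["mexico"]] * cohort$country_mexico +
      co[["waitlist"]] * cohort$clinic_waitlist +
      co[["clinic_campus"]] * cohort$clinic_campus +
      co[["severe"]] * severe + extra
  }
  with_seed(derive_seed(config$seed, "missingness"), {
    eta1 <- lin(dm$wave1)
    c3 <- as.integer(stats::runif(n) < expit(eta1))
    extra <- dm$wave2[["prev_complete"]] * c3 +
      dm$wave2[["ads3"]] * c3 * (outcomes$phq_ads_3 - 15)
    eta2 <- lin(dm$wave2, extra)
    c12 <- as.integer(stats::runif(n) < expit(eta2))
  })
  data.frame(participant_id = cohort$participant_id, c3 = c3, c12 = c12)
}

#' Generate a complete synthetic trial with ground truth
#'
#' Composes the cohort, randomization, usage, outcome and missingness stages
#' under a single master seed, and records per-participant potential
#' outcomes under every arm (via common random numbers) so the true
#' adjusted risk and mean differences implied by the configuration are
#' known exactly.
#'
#' @param config a \code{\link{generator_config}}.
#' @return An object of class \code{synthetic_trial}: list with elements
#'   \code{cohort}, \code{arms}, \code{usage}, \code{outcomes},
#'   \code{completion}, \code{followup} (long format with completion flags
#'   and observed scores), \code{truth} (potential outcomes per arm and the
#'   implied true contrasts), and \code{config}.
#' @export
generate_trial <- function(config) {
  cohort <- generate_cohort(config)
  arms <- block_randomize(cohort, config)
  n <- nrow(cohort)
  u <- attr(cohort, "latent") %||% numeric(n)

  # Potential usage and outcomes under each arm share the week-level and
  # participant-level draws (common random numbers).
  draws <- with_seed(derive_seed(config$seed, "usage"), {
    list(U = matrix(stats::runif(n * 52), n, 52),
         Z = matrix(stats::rnorm(n * 52), n, 52))
  })
  odraws <- with_seed(derive_seed(config$seed, "outcomes"), {
    list(e3 = stats::rnorm(n), e12 = stats::rnorm(n),
         b = stats::rnorm(n), rjit = stats::rnorm(n, 0, 0.05))
  })

  po <- lapply(ARM_LEVELS, function(a) {
    arm_a <- factor(rep(a, n), levels = ARM_LEVELS)
    wk <- .usage_from_draws(arm_a, u, draws$U, draws$Z,
                            config$arm_usage_profiles)
    usage_a <- cbind(data.frame(participant_id = cohort$participant_id),
                     as.data.frame(`colnames<-`(wk, paste0("week_", 1:52))))
    oc <- .outcomes_from_draws(cohort, arm_a, usage_a, config$effect_map,
                               odraws$e3, odraws$e12, odraws$rjit,
                               odraws$b)
    list(usage = wk, outcomes = oc)
  })
  names(po) <- ARM_LEVELS

  # Observed data: pick the assigned arm's potential values
  ai <- as.integer(arms$arm)
  usage_mat <- matrix(0, n, 52)
  outcomes <- po[[1]]$outcomes
  for (k in seq_along(ARM_LEVELS)) {
    rows <- which(ai == k)
    usage_mat[rows, ] <- po[[k]]$usage[rows, , drop = FALSE]
    outcomes[rows, ] <- po[[k]]$outcomes[rows, , drop = FALSE]
  }
  colnames(usage_mat) <- paste0("week_", 1:52)
  usage <- cbind(data.frame(participant_id = cohort$participant_id,
                            stringsAsFactors = FALSE),
                 as.data.frame(usage_mat))
  completion <- simulate_missingness(cohort, arms, outcomes, config)

  truth <- .build_truth(cohort, po)
  followup <- .build_followup(outcomes, completion)

  structure(list(cohort = cohort, arms = arms, usage = usage,
                 outcomes = outcomes, completion = completion,
                 followup = followup, truth = truth, config = config),
            class = "synthetic_trial")
}

.build_truth <- function(cohort, po) {
  n <- nrow(cohort)
  tr <- data.frame(participant_id = cohort$participant_id,
                   stringsAsFactors = FALSE)
  for (a in ARM_LEVELS) {
    oc <- po[[a]]$outcomes
    tr[[paste0("ads3_", a)]] <- oc$phq_ads_3
    tr[[paste0("ads12_", a)]] <- oc$phq_ads_12
    tr[[paste0("rem3_", a)]] <-
      as.integer(oc$gad7_3 <= 4 & oc$phq9_3 <= 4)
    tr[[paste0("rem12_", a)]] <-
      as.integer(oc$gad7_12 <= 4 & oc$phq9_12 <= 4)
    tr[[paste0("late_minutes_", a)]] <-
      rowSums(po[[a]]$usage[, 13:52, drop = FALSE])
  }
  contrasts <- NULL
  if (n > 0) {
    pairs <- utils::combn(ARM_LEVELS, 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      data.frame(
        pair = paste(a, "vs", b),
        ard_3mo = 100 * mean(tr[[paste0("rem3_", a)]] -
                               tr[[paste0("rem3_", b)]]),
        ard_12mo = 100 * mean(tr[[paste0("rem12_", a)]] -
                                tr[[paste0("rem12_", b)]]),
        amd_3mo = mean(tr[[paste0("ads3_", a)]] - tr[[paste0("ads3_", b)]]),
        amd_12mo = mean(tr[[paste0("ads12_", a)]] -
                          tr[[paste0("ads12_", b)]]),
        stringsAsFactors = FALSE)
    }))
  }
  list(potential = tr, contrasts = contrasts,
       arm_means = if (n > 0) {
         do.call(rbind, lapply(ARM_LEVELS, function(a) data.frame(
           arm = a,
           rem3 = 100 * mean(tr[[paste0("rem3_", a)]]),
           rem12 = 100 * mean(tr[[paste0("rem12_", a)]]),
           ads3 = mean(tr[[paste0("ads3_", a)]]),
           ads12 = mean(tr[[paste0("ads12_", a)]]),
           stringsAsFactors = FALSE)))
       } else NULL)
}

.build_followup <- function(outcomes, completion) {
  n <- nrow(outcomes)
  mk <- function(wave, g, p, c) {
    data.frame(participant_id = outcomes$participant_id,
               wave = wave, completed = c,
               gad7 = ifelse(c == 1L, g, NA_integer_),
               phq9 = ifelse(c == 1L, p, NA_integer_),
               stringsAsFactors = FALSE)
  }
  rbind(mk(3L, outcomes$gad7_3, outcomes$phq9_3, completion$c3),
        mk(12L, outcomes$gad7_12, outcomes$phq9_12, completion$c12))
}

#' True response propensities implied by a trial's dropout model
#'
#' Evaluates the generator's own missingness mechanism for each
#' participant: the probability of completing the 3-month wave given
#' baseline covariates and arm, and the probability of completing the
#' 12-month wave given additionally the wave-1 completion status and the
#' 3-month score. Ground-truth plumbing for estimator simulations; never
#' used by the estimation module itself.
#'
#' @param trial a \code{synthetic_trial} generated with a parametric
#'   dropout model (not \code{"none"}).
#' @return data.frame \code{participant_id}, \code{g1}, \code{g2}
#'   (\code{g2} conditions on the realized wave-1 completion).
#' @export
true_completion_propensities <- function(trial) {
  dm <- trial$config$dropout_model
  if (identical(dm, "none"))
    stopf("trial was generated without dropout")
  cohort <- trial$cohort
  armc <- as.character(trial$arms$arm)
  severe <- as.integer(cohort$gad7_0 >= 15 | cohort$phq9_0 >= 20)
  lin <- function(co, extra = 0) {
    co[["intercept"]] + unname(co[armc]) +
      co[["mexico"]] * cohort$country_mexico +
      co[["waitlist"]] * cohort$clinic_waitlist +
      co[["clinic_campus"]] * cohort$clinic_campus +
      co[["severe"]] * severe + extra
  }
  c3 <- trial$completion$c3
  extra <- dm$wave2[["prev_complete"]] * c3 +
    dm$wave2[["ads3"]] * c3 * (trial$outcomes$phq_ads_3 - 15)
  data.frame(participant_id = cohort$participant_id,
             g1 = expit(lin(dm$wave1)),
             g2 = expit(lin(dm$wave2, extra)))
}

#' @export
print.synthetic_trial <- function(x, ...) {
  n <- nrow(x$cohort)
  cat(sprintf("Synthetic three-arm wb-CBT trial: %d participants\n", n))
  if (n > 0) {
    cat("  arms:", paste(sprintf("%s=%d", levels(x$arms$arm),
                                 table(x$arms$arm)), collapse = ", "), "\n")
    cat(sprintf("  completion: 3mo %.1f%%, 12mo %.1f%%, both %.1f%%\n",
                100 * mean(x$completion$c3), 100 * mean(x$completion$c12),
                100 * mean(x$completion$c3 & x$completion$c12)))
  }
  invisible(x)
}
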