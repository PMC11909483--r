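#' Doubly robust estimation of per-arm outcomes under attrition
#'
#' Per-arm adjusted estimates of joint remission rates and mean PHQ-ADS
#' combine an outcome regression (predicting the follow-up outcome from
#' baseline covariates within arm) with a response-propensity model
#' (probability of completing the wave given covariates and arm). The
#' default estimator is targeted minimum loss-based: the outcome regression
#' is rescaled to [0,1], updated by a one-dimensional logistic fluctuation
#' with the inverse-probability "clever covariate", and averaged over the
#' whole randomized sample; standard errors come from the empirical variance
#' of the efficient influence curve. An augmented-IPW mode is provided as a
#' cross-check. Either nuisance model being correctly specified is enough
#' for consistency (double robustness).
#'
#' @name estimation
NULL

#' Fit nuisance models for a single wave
#'
#' @param data data.frame with columns \code{arm} (factor with levels
#'   guided/self_guided/tau), the outcome column and the completion column.
#' @param outcome_col name of the numeric outcome column (NA allowed where
#'   not completed).
#' @param completed_col name of the 0/1 completion column.
#' @param covars character vector of baseline covariate column names
#'   (possibly empty for unadjusted estimation).
#' @param covars_propensity,covars_outcome covariates for the
#'   response-propensity and outcome-regression models; default to
#'   \code{covars}. Separate sets allow deliberate misspecification of one
#'   nuisance (e.g. in double-robustness simulations).
#' @param bound lower truncation bound for completion propensities.
#' @return A list of class \code{nuisance_fits}: \code{pc} (bounded
#'   completion propensities), \code{Q} (n x 3 outcome-regression prediction
#'   matrix on the rescaled [0,1] outcome, one column per arm),
#'   \code{y_range} used for rescaling, and \code{flags} recording
#'   truncation and any intercept-only fallback.
#' @export
fit_nuisances <- function(data, outcome_col, completed_col,
                          covars = character(), bound = 0.01,
                          y_range = NULL, covars_propensity = covars,
                          covars_outcome = covars) {
  comp <- data[[completed_col]]
  y <- data[[outcome_col]]
  if (is.null(y_range)) y_range <- .guess_range(y)
  ys <- .rescale01(y, y_range)
  flags <- list(truncated = FALSE, fallback_propensity = FALSE,
                fallback_outcome = character())

  # response-propensity model
  if (all(comp == 1)) {
    pc <- rep(1, nrow(data))
  } else {
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        stats::reformulate(c("arm", covars_propensity),
                           response = completed_col),
        data = data, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(stats::coef(fit)))) {
      flags$fallback_propensity <- TRUE
      pc <- rep(mean(comp), nrow(data))
    } else {
      pc <- stats::fitted(fit)
    }
  }
  if (any(pc < bound)) flags$truncated <- TRUE
  pc <- clip(pc, bound, 1)

  # outcome regression per arm on completers, predicted for everyone
  n <- nrow(data)
  Q <- matrix(NA_real_, n, length(ARM_LEVELS),
              dimnames = list(NULL, ARM_LEVELS))
  for (a in ARM_LEVELS) {
    sub <- data$arm == a & comp == 1
    if (!any(sub)) stopf("no completers in arm '%s'", a)
    q <- .fit_outcome_regression(ys, data, sub, covars_outcome)
    if (q$fallback) flags$fallback_outcome <- c(flags$fallback_outcome, a)
    Q[, a] <- q$pred
  }
  structure(list(pc = pc, Q = Q, y_range = y_range, bound = bound,
                 covars = covars, flags = flags),
            class = "nuisance_fits")
}

.guess_range <- function(y) {
  obs <- y[!is.na(y)]
  if (all(obs %in% c(0, 1))) c(0, 1) else c(0, 48)
}

.rescale01 <- function(y, y_range) {
  ys <- (y - y_range[1]) / diff(y_range)
  clip(ys, 0, 1)
}

.fit_outcome_regression <- function(ys, data, sub, covars) {
  n <- nrow(data)
  if (!length(covars) || stats::var(ys[sub]) == 0) {
    return(list(pred = rep(mean(ys[sub]), n), fallback = !length(covars)))
  }
  df <- data[, covars, drop = FALSE]
  df$.ys <- ys
  fit <- tryCatch(
    suppressWarnings(stats::glm(
      stats::reformulate(covars, response = ".ys"),
      data = df[sub, , drop = FALSE], family = stats::quasibinomial())),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(stats::coef(fit)))) {
    warning("outcome regression degenerate; falling back to intercept-only",
            call. = FALSE)
    return(list(pred = rep(mean(ys[sub]), n), fallback = TRUE))
  }
  list(pred = clip(stats::predict(fit, newdata = df, type = "response"),
                   1e-6, 1 - 1e-6),
       fallback = FALSE)
}

#' Doubly robust per-arm estimate at a single wave
#'
#' @param data as in \code{\link{fit_nuisances}}.
#' @param outcome_col,completed_col column names.
#' @param nuisances a \code{nuisance_fits} object (fitted if omitted).
#' @param estimator \code{"tmle"} (targeted, the default) or \code{"aipw"}.
#' @param g_mode arm-assignment probabilities: \code{"empirical"} uses the
#'   realized arm shares (conditional-on-sample allocation, which makes the
#'   no-missingness collapse to the arm sample mean exact); \code{"known"}
#'   uses 1/3.
#' @param scale reporting scale multiplier: remission estimates are reported
#'   in percent by default when the outcome is binary.
#' @inheritParams fit_nuisances
#' @return An object of class \code{dr_result}: data.frame of per-arm
#'   estimates and SEs on the reporting scale, the influence-curve matrix,
#'   and the estimate covariance matrix.
#' @export
dr_estimate <- function(data, outcome_col, completed_col,
                        covars = character(), nuisances = NULL,
                        estimator = c("tmle", "aipw"),
                        g_mode = c("empirical", "known"),
                        bound = 0.01, y_range = NULL, scale = NULL,
                        covars_propensity = covars,
                        covars_outcome = covars) {
  estimator <- match.arg(estimator)
  g_mode <- match.arg(g_mode)
  if (is.null(nuisances)) {
    nuisances <- fit_nuisances(data, outcome_col, completed_col, covars,
                               bound, y_range,
                               covars_propensity = covars_propensity,
                               covars_outcome = covars_outcome)
  }
  comp <- data[[completed_col]]
  y_range <- nuisances$y_range
  ys <- .rescale01(data[[outcome_col]], y_range)
  ys0 <- ifelse(is.na(ys), 0, ys)
  n <- nrow(data)
  if (is.null(scale)) {
    scale <- if (all(y_range == c(0, 1))) 100 else 1
  }
  width <- diff(y_range) * scale

  psi <- se <- numeric(length(ARM_LEVELS))
  IC <- matrix(0, n, length(ARM_LEVELS), dimnames = list(NULL, ARM_LEVELS))
  for (k in seq_along(ARM_LEVELS)) {
    a <- ARM_LEVELS[k]
    in_arm <- data$arm == a
    if (!any(in_arm & comp == 1)) stopf("no completers in arm '%s'", a)
    g_a <- if (g_mode == "empirical") mean(in_arm) else 1 / 3
    H <- ifelse(in_arm & comp == 1, 1 / (g_a * nuisances$pc), 0)
    Qa <- clip(nuisances$Q[, a], 1e-6, 1 - 1e-6)
    if (estimator == "tmle") {
      sub <- which(H > 0)
      eps <- tryCatch(
        suppressWarnings(stats::coef(stats::glm(
          ys[sub] ~ 1, offset = logit(Qa[sub]), weights = H[sub],
          family = stats::quasibinomial(),
          control = stats::glm.control(epsilon = 1e-12, maxit = 100)))),
        error = function(e) 0)
      if (!is.finite(eps)) eps <- 0
      Qstar <- expit(logit(Qa) + eps)
      psi[k] <- mean(Qstar)
      IC[, k] <- H * (ys0 - Qstar) + Qstar - psi[k]
    } else {
      psi[k] <- mean(Qa + H * (ys0 - Qa))
      IC[, k] <- H * (ys0 - Qa) + Qa - psi[k]
    }
    se[k] <- stats::sd(IC[, k]) / sqrt(n)
  }
  V <- crossprod(IC) / n^2 * width^2
  est <- data.frame(arm = ARM_LEVELS,
                    value = psi * width + y_range[1] * scale,
                    se = se * width,
                    n_arm = as.vector(table(data$arm)[ARM_LEVELS]),
                    stringsAsFactors = FALSE)
  structure(list(estimates = est, vcov = V, ic = IC * width,
                 estimator = estimator, outcome = outcome_col, n = n,
                 y_range = y_range, scale = scale,
                 flags = nuisances$flags),
            class = "dr_result")
}

#' Longitudinal doubly robust estimate at 12 months using partial follow-up
#'
#' Sequential-regression (iterated expectation) form: the 12-month outcome
#' is first regressed on baseline covariates plus 3-month data among
#' participants observed at both waves and targeted with the cumulative
#' inverse-probability weight; the targeted predictions are then regressed
#' on baseline covariates among 3-month completers and targeted again. This
#' recovers information from participants with a 3-month but no 12-month
#' response. When no participant has partial follow-up the sequential form
#' carries no extra information and the estimator collapses exactly to the
#' single-wave \code{\link{dr_estimate}}.
#'
#' @param data data.frame with \code{arm}, baseline covariates, a wave-1
#'   completion column, a wave-2 completion column, 3-month data columns and
#'   the 12-month outcome column.
#' @param outcome_col 12-month outcome column name.
#' @param l1_cols 3-month data column names used in the stage-2 regression
#'   and wave-2 propensity (must be observed whenever the wave-1 flag is 1).
#' @param c1_col,c2_col completion flag column names.
#' @param g1,g2 optional known response propensities per wave (e.g. from a
#'   designed missingness mechanism); when supplied they replace the fitted
#'   models.
#' @inheritParams dr_estimate
#' @return A \code{dr_result}.
#' @export
longitudinal_dr_estimate <- function(data, outcome_col, l1_cols,
                                     c1_col = "c3", c2_col = "c12",
                                     covars = character(),
                                     estimator = c("tmle", "aipw"),
                                     g_mode = c("empirical", "known"),
                                     bound = 0.01, y_range = NULL,
                                     scale = NULL,
                                     covars_propensity = covars,
                                     covars_outcome = covars,
                                     g1 = NULL, g2 = NULL) {
  estimator <- match.arg(estimator)
  g_mode <- match.arg(g_mode)
  c1 <- data[[c1_col]]
  c2 <- data[[c2_col]]

  # 12-month-only rows carry no usable 3-month data; they are handled
  # upstream by multiple imputation. If any remain, they cannot enter the
  # sequential form and are treated as censored at wave 1.
  twelve_only <- c2 == 1 & c1 == 0
  if (any(twelve_only)) {
    warning(sprintf(
      "%d participants have 12-month data without 3-month data; impute 3-month values first to use them",
      sum(twelve_only)), call. = FALSE)
    c2 <- ifelse(twelve_only, 0L, c2)
  }
  if (!any(c1 == 1 & c2 == 0)) {
    # no partial follow-up: structural collapse to the single-wave estimator
    dat <- data
    dat$.cboth <- as.integer(c1 == 1 & c2 == 1)
    return(dr_estimate(dat, outcome_col, ".cboth", covars,
                       estimator = estimator, g_mode = g_mode,
                       bound = bound, y_range = y_range, scale = scale,
                       covars_propensity = covars_propensity,
                       covars_outcome = covars_outcome))
  }

  y <- data[[outcome_col]]
  if (is.null(y_range)) y_range <- .guess_range(y)
  ys <- .rescale01(y, y_range)
  ys0 <- ifelse(is.na(ys), 0, ys)
  n <- nrow(data)
  if (is.null(scale)) scale <- if (all(y_range == c(0, 1))) 100 else 1
  width <- diff(y_range) * scale

  # cumulative response propensities (fitted unless supplied)
  if (is.null(g1)) {
    g1 <- .completion_propensity(data, c1, rep(TRUE, n),
                                 c("arm", covars_propensity), bound)
  } else g1 <- clip(g1, bound, 1)
  if (is.null(g2)) {
    g2 <- .completion_propensity(data, c2, c1 == 1,
                                 c("arm", covars_propensity, l1_cols),
                                 bound)
  } else g2 <- clip(g2, bound, 1)

  psi <- se <- numeric(length(ARM_LEVELS))
  IC <- matrix(0, n, length(ARM_LEVELS), dimnames = list(NULL, ARM_LEVELS))
  for (k in seq_along(ARM_LEVELS)) {
    a <- ARM_LEVELS[k]
    in_arm <- data$arm == a
    g_a <- if (g_mode == "empirical") mean(in_arm) else 1 / 3
    H2 <- ifelse(in_arm & c1 == 1 & c2 == 1, 1 / (g_a * g1 * g2), 0)
    H1 <- ifelse(in_arm & c1 == 1, 1 / (g_a * g1), 0)

    # stage 2: E[Y12 | W, L1, A=a] among double completers
    sub2 <- in_arm & c1 == 1 & c2 == 1
    if (!any(sub2)) stopf("no completers in arm '%s'", a)
    q2 <- .fit_outcome_regression(ys, data, sub2, c(covars_outcome, l1_cols))
    Q2 <- clip(q2$pred, 1e-6, 1 - 1e-6)   # defined wherever L1 observed
    if (estimator == "tmle") {
      i2 <- which(H2 > 0)
      eps2 <- tryCatch(suppressWarnings(stats::coef(stats::glm(
        ys[i2] ~ 1, offset = logit(Q2[i2]), weights = H2[i2],
        family = stats::quasibinomial(),
        control = stats::glm.control(epsilon = 1e-12, maxit = 100)))),
        error = function(e) 0)
      if (!is.finite(eps2)) eps2 <- 0
      Q2 <- expit(logit(Q2) + eps2)
    }
    # stage 1: regress targeted stage-2 predictions on baseline covariates
    # among wave-1 completers in the arm
    sub1 <- in_arm & c1 == 1
    q1 <- .fit_outcome_regression(Q2, data, sub1, covars_outcome)
    Q1 <- clip(q1$pred, 1e-6, 1 - 1e-6)
    if (estimator == "tmle") {
      i1 <- which(H1 > 0)
      eps1 <- tryCatch(suppressWarnings(stats::coef(stats::glm(
        Q2[i1] ~ 1, offset = logit(Q1[i1]), weights = H1[i1],
        family = stats::quasibinomial(),
        control = stats::glm.control(epsilon = 1e-12, maxit = 100)))),
        error = function(e) 0)
      if (!is.finite(eps1)) eps1 <- 0
      Q1 <- expit(logit(Q1) + eps1)
      psi[k] <- mean(Q1)
    } else {
      psi[k] <- mean(Q1 + H1 * (ifelse(c1 == 1, Q2, 0) - Q1) +
                       H2 * (ys0 - ifelse(c1 == 1, Q2, 0)))
    }
    Q2pad <- ifelse(c1 == 1, Q2, 0)
    IC[, k] <- H2 * (ys0 - Q2pad) + H1 * (Q2pad - Q1) + Q1 - psi[k]
    se[k] <- stats::sd(IC[, k]) / sqrt(n)
  }
  V <- crossprod(IC) / n^2 * width^2
  est <- data.frame(arm = ARM_LEVELS,
                    value = psi * width + y_range[1] * scale,
                    se = se * width,
                    n_arm = as.vector(table(data$arm)[ARM_LEVELS]),
                    stringsAsFactors = FALSE)
  structure(list(estimates = est, vcov = V, ic = IC * width,
                 estimator = paste0("longitudinal-", estimator),
                 outcome = outcome_col, n = n, y_range = y_range,
                 scale = scale, flags = NULL),
            class = "dr_result")
}

.completion_propensity <- function(data, cflag, at_risk, rhs, bound) {
  n <- nrow(data)
  if (all(cflag[at_risk] == 1)) return(rep(1, n))
  df <- data
  df$.c <- cflag
  rhs <- rhs[rhs %in% c("arm", names(data))]
  fit <- tryCatch(suppressWarnings(stats::glm(
    stats::reformulate(rhs, response = ".c"),
    data = df[at_risk, , drop = FALSE], family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(stats::coef(fit)))) {
    p <- rep(mean(cflag[at_risk]), n)
  } else {
    p <- rep(NA_real_, n)
    p[at_risk] <- stats::fitted(fit)
    # out-of-risk rows never contribute (their H is 0); fill neutrally
    p[!at_risk] <- mean(cflag[at_risk])
  }
  clip(p, bound, 1)
}

#' @export
print.dr_result <- function(x, ...) {
  cat(sprintf("Doubly robust per-arm estimates (%s), outcome '%s', n=%d\n",
              x$estimator, x$outcome, x$n))
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Construct an adjusted per-arm estimate
#'
#' Light-weight container for a single arm's adjusted outcome estimate, as
#' used by \code{\link{contrast}} and \code{\link{pool_rubin}}.
#'
#' @param arm arm label.
#' @param value estimate (percent for remission, scale points for PHQ-ADS).
#' @param se standard error.
#' @param wave,outcome,n_arm optional metadata.
#' @export
adjusted_estimate <- function(arm, value, se, wave = NA, outcome = NA,
                              n_arm = NA) {
  structure(list(arm = arm, value = value, se = se, wave = wave,
                 outcome = outcome, n_arm = n_arm),
            class = "adjusted_estimate")
}

#' Pairwise contrast between two adjusted estimates
#'
#' Adjusted risk difference (remission, percentage points) or adjusted mean
#' difference (PHQ-ADS points) with a 1-df Wald chi-square.
#'
#' @param a,b \code{\link{adjusted_estimate}} objects (or lists with
#'   \code{value} and \code{se}).
#' @param cov covariance between the two estimates (0 if independent).
#' @return A list of class \code{contrast_result}: \code{pair},
#'   \code{difference}, \code{se}, \code{chi2}, \code{df}, \code{p}.
#' @export
contrast <- function(a, b, cov = 0) {
  if (!is.na(a$wave) && !is.na(b$wave) && !identical(a$wave, b$wave))
    stopf("contrast requires estimates of the same wave")
  d <- a$value - b$value
  v <- a$se^2 + b$se^2 - 2 * cov
  if (v <= 0) {
    if (abs(d) > 1e-12) stopf("zero contrast variance with nonzero difference")
    v <- 0
  }
  se <- sqrt(v)
  chi2 <- if (se > 0) (d / se)^2 else 0
  structure(list(pair = paste(a$arm, "vs", b$arm), difference = d, se = se,
                 chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, 1, lower.tail = FALSE)),
            class = "contrast_result")
}

#' All pairwise contrasts and the 2-df overall test from a dr_result
#'
#' @param x a \code{dr_result}.
#' @return list with \code{contrasts} (data.frame of the three ordered
#'   pairs) and \code{overall} (the 2-df Wald test).
#' @export
contrasts_from <- function(x) {
  stopifnot(inherits(x, "dr_result"))
  est <- x$estimates
  mk <- function(i, j) {
    a <- adjusted_estimate(est$arm[i], est$value[i], est$se[i])
    b <- adjusted_estimate(est$arm[j], est$value[j], est$se[j])
    cr <- contrast(a, b, cov = x$vcov[i, j])
    data.frame(pair = cr$pair, difference = cr$difference, se = cr$se,
               chi2 = cr$chi2, df = cr$df, p = cr$p,
               stringsAsFactors = FALSE)
  }
  ct <- rbind(mk(1, 2), mk(1, 3), mk(2, 3))
  ov <- overall_test(est$value, x$vcov)
  list(contrasts = ct, overall = ov)
}

#' Overall 2-df Wald test of variation across the three arms
#'
#' Quadratic form of two independent pairwise contrasts in their estimated
#' covariance; invariant to which two contrasts are chosen.
#'
#' @param values numeric vector of the 3 per-arm estimates.
#' @param V 3x3 covariance matrix of the estimates.
#' @return list of class \code{overall_test}: \code{chi2}, \code{df = 2},
#'   \code{p}.
#' @export
overall_test <- function(values, V) {
  stopifnot(length(values) == 3, all(dim(V) == c(3, 3)))
  D <- rbind(c(1, -1, 0), c(1, 0, -1))
  dv <- D %*% values
  S <- D %*% V %*% t(D)
  if (abs(det(S)) < 1e-300) stopf("singular contrast covariance")
  chi2 <- drop(t(dv) %*% solve(S, dv))
  structure(list(chi2 = chi2, df = 2L,
                 p = stats::pchisq(chi2, 2, lower.tail = FALSE)),
            class = "overall_test")
}

#' Pearson chi-square test of a contingency table
#'
#' Plain Pearson statistic without continuity correction, as used for the
#' descriptive completion-by-arm and predictor-by-completion tables.
#'
#' @param tab matrix of nonnegative integer counts with positive margins.
#' @return list \code{chi2}, \code{df}, \code{p}.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("all table margins must be positive")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Multiple imputation of 3-month scores by predictive mean matching
#'
#' For participants with 12-month but no 3-month data, 3-month GAD-7/PHQ-9
#' scores are imputed by predictive mean matching: a linear model of the
#' 3-month PHQ-ADS score on baseline covariates and 12-month scores is fit
#' among participants observed at both waves; each recipient receives the
#' observed 3-month scores of one of its k nearest donors by predicted
#' mean. Imputed values are therefore always observed donor values.
#'
#' @param data analysis frame with completion flags \code{c3}, \code{c12},
#'   score columns \code{gad7_3}, \code{phq9_3}, \code{phq_ads_3},
#'   \code{gad7_12}, \code{phq9_12} and baseline covariates.
#' @param covars baseline covariate columns used in the matching model.
#' @param m number of completed datasets.
#' @param k donor pool size.
#' @param seed integer seed.
#' @return A list of class \code{mi_list} with \code{m} completed
#'   data.frames differing only in the imputed 3-month cells.
#' @export
impute_3mo_pmm <- function(data, covars = character(), m = 20, k = 5,
                           seed = 1) {
  stopifnot(m >= 2, k >= 1)
  targets <- which(data$c3 == 0 & data$c12 == 1)
  if (!length(targets)) {
    out <- replicate(m, data, simplify = FALSE)
    class(out) <- "mi_list"
    return(out)
  }
  donors <- which(data$c3 == 1 & data$c12 == 1)
  if (length(donors) < k) {
    warning(sprintf("only %d donors available; using all of them",
                    length(donors)), call. = FALSE)
    k <- length(donors)
  }
  if (!length(donors)) stopf("no donors with both waves observed")

  rhs <- c(covars, "gad7_12", "phq9_12")
  df <- data
  fit <- stats::lm(stats::reformulate(rhs, response = "phq_ads_3"),
                   data = df[donors, , drop = FALSE])
  pred <- stats::predict(fit, newdata = df)

  out <- with_seed(seed, {
    lapply(seq_len(m), function(j) {
      d <- data
      for (t in targets) {
        dist <- abs(pred[donors] - pred[t])
        pool <- donors[order(dist, donors)][seq_len(k)]
        don <- if (k == 1) pool else pool[sample.int(k, 1)]
        d$gad7_3[t] <- data$gad7_3[don]
        d$phq9_3[t] <- data$phq9_3[don]
        d$phq_ads_3[t] <- data$phq_ads_3[don]
        d$c3[t] <- 1L   # completed-by-imputation for downstream stages
      }
      d
    })
  })
  attr(out, "imputed_rows") <- targets
  class(out) <- "mi_list"
  out
}

#' Pool estimates across multiply imputed datasets (Rubin's rules)
#'
#' @param estimates list of \code{\link{adjusted_estimate}} objects for the
#'   same estimand, one per completed dataset.
#' @return A pooled \code{adjusted_estimate}: value = mean of the estimates;
#'   variance = mean within-imputation variance + (1 + 1/m) times the
#'   between-imputation variance.
#' @export
pool_rubin <- function(estimates) {
  m <- length(estimates)
  if (m < 2) stopf("pooling requires at least 2 estimates")
  arms <- unique(vapply(estimates, function(e) as.character(e$arm), ""))
  waves <- unique(vapply(estimates, function(e) as.character(e$wave), ""))
  if (length(arms) != 1 || length(waves) != 1)
    stopf("estimates refer to different estimands")
  vals <- vapply(estimates, function(e) e$value, 0)
  wvar <- vapply(estimates, function(e) e$se^2, 0)
  qbar <- mean(vals)
  B <- if (m > 1) stats::var(vals) else 0
  Tvar <- mean(wvar) + (1 + 1 / m) * B
  adjusted_estimate(estimates[[1]]$arm, qbar, sqrt(Tvar),
                    wave = estimates[[1]]$wave,
                    outcome = estimates[[1]]$outcome,
                    n_arm = estimates[[1]]$n_arm)
}

#' Build the flat analysis frame from a synthetic trial
#'
#' One row per participant: arm, baseline covariates, completion flags and
#' wave-specific scores plus derived outcomes (joint remission indicator and
#' PHQ-ADS) at each wave.
#'
#' @param trial a \code{synthetic_trial}.
#' @return data.frame.
#' @export
analysis_frame <- function(trial) {
  stopifnot(inherits(trial, "synthetic_trial"))
  oc <- trial$outcomes
  comp <- trial$completion
  df <- trial$cohort
  df$arm <- trial$arms$arm
  df$c3 <- comp$c3
  df$c12 <- comp$c12
  df$severe_baseline <- as.integer(df$gad7_0 >= 15 | df$phq9_0 >= 20)
  for (w in c("3", "12")) {
    cc <- comp[[paste0("c", w)]] == 1
    g <- ifelse(cc, oc[[paste0("gad7_", w)]], NA_integer_)
    p <- ifelse(cc, oc[[paste0("phq9_", w)]], NA_integer_)
    df[[paste0("gad7_", w)]] <- g
    df[[paste0("phq9_", w)]] <- p
    df[[paste0("phq_ads_", w)]] <- g + p
    df[[paste0("remission_", w)]] <-
      ifelse(cc, as.integer(g <= 4 & p <= 4), NA_integer_)
  }
  attr(df, "latent") <- NULL
  df
}
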