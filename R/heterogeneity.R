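#' Specifier-based subgroup analysis
#'
#' The predicted-compliance score is used as a specifier: the cohort is
#' dichotomized at the top fraction of scores, arm effects are re-estimated
#' within each stratum, and a 1-df Wald contrast-of-contrasts tests whether
#' the self-guided advantage differs between strata.
#'
#' @name heterogeneity
NULL

#' Dichotomize predicted compliance at a top fraction
#'
#' The high group contains the \code{ceiling(n * top_fraction)} largest
#' scores; ties at the threshold are broken by stable participant-id order.
#'
#' @param scores a \code{predicted_compliance} data.frame (or named numeric
#'   vector of scores).
#' @param top_fraction proportion labeled high (default 0.40).
#' @return Object of class \code{specifier_split}: data.frame
#'   \code{participant_id}, \code{score}, \code{label} plus attributes
#'   \code{threshold} and \code{top_fraction}.
#' @export
dichotomize <- function(scores, top_fraction = 0.40) {
  if (top_fraction <= 0 || top_fraction >= 1)
    stopf("top_fraction must be strictly between 0 and 1")
  if (is.data.frame(scores)) {
    ids <- scores$participant_id
    sc <- scores$score
  } else {
    ids <- names(scores) %||% as.character(seq_along(scores))
    sc <- as.numeric(scores)
  }
  n <- length(sc)
  n_high <- as.integer(ceiling(n * top_fraction))
  ord <- order(-xtfrm(sc), ids)
  label <- rep("low", n)
  label[ord[seq_len(n_high)]] <- "high"
  out <- data.frame(participant_id = ids, score = sc,
                    label = factor(label, levels = c("high", "low")),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- sc[ord[n_high]]
  attr(out, "top_fraction") <- top_fraction
  class(out) <- c("specifier_split", "data.frame")
  out
}

#' Wald interaction statistic from stratum-specific contrasts
#'
#' @param delta_high,delta_low stratum-specific contrasts (e.g. the
#'   self-guided vs comparator adjusted risk difference).
#' @param se_high,se_low their standard errors.
#' @return list of class \code{interaction_result}: \code{chi2},
#'   \code{df = 1}, \code{p}.
#' @export
interaction_stat <- function(delta_high, se_high, delta_low, se_low) {
  se <- sqrt(se_high^2 + se_low^2)
  if (se == 0) stopf("zero pooled SE in interaction statistic")
  chi2 <- ((delta_high - delta_low) / se)^2
  structure(list(chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 delta_high = delta_high, delta_low = delta_low),
            class = "interaction_result")
}

#' Arm-by-specifier interaction test
#'
#' Within each specifier stratum the doubly robust per-arm estimates are
#' computed and the self-guided arm is contrasted against the comparator
#' (the guided and TAU arms pooled by default, or the guided arm alone).
#' The test statistic is the squared difference of the two stratum
#' contrasts over its pooled SE.
#'
#' @param data analysis frame (\code{\link{analysis_frame}}).
#' @param split a \code{\link{dichotomize}} result.
#' @param outcome_col,completed_col outcome and completion columns for the
#'   wave being tested (12-month joint remission by default).
#' @param covars baseline covariates for the nuisance models.
#' @param comparator \code{"pooled"} (guided + TAU) or \code{"guided"}.
#' @param ... passed to \code{\link{dr_estimate}}.
#' @return An \code{interaction_result} with the stratum estimates attached.
#' @export
interaction_test <- function(data, split, outcome_col = "remission_12",
                             completed_col = "c12", covars = character(),
                             comparator = c("pooled", "guided"), ...) {
  comparator <- match.arg(comparator)
  lab <- split$label[match(data$participant_id, split$participant_id)]
  if (anyNA(lab)) stopf("split does not cover all participants")
  deltas <- lapply(c("high", "low"), function(s) {
    d <- data[lab == s, , drop = FALSE]
    if (!nrow(d)) stopf("empty specifier stratum '%s'", s)
    fit <- dr_estimate(d, outcome_col, completed_col, covars, ...)
    .self_vs_comparator(fit, comparator)
  })
  res <- interaction_stat(deltas[[1]]$delta, deltas[[1]]$se,
                          deltas[[2]]$delta, deltas[[2]]$se)
  res$strata <- deltas
  res$comparator <- comparator
  res
}

# Self-guided minus comparator contrast with IC-based variance.
.self_vs_comparator <- function(fit, comparator) {
  est <- fit$estimates
  v <- fit$vcov
  i_self <- which(est$arm == "self_guided")
  if (comparator == "guided") {
    i_g <- which(est$arm == "guided")
    delta <- est$value[i_self] - est$value[i_g]
    var_d <- v[i_self, i_self] + v[i_g, i_g] - 2 * v[i_self, i_g]
  } else {
    w <- ifelse(est$arm == "self_guided", 1, -0.5)
    delta <- sum(w * est$value)
    var_d <- drop(t(w) %*% v %*% w)
  }
  list(delta = delta, se = sqrt(var_d), estimates = est)
}

#' Stratified adjusted-effect tables
#'
#' Re-runs the doubly robust estimation within each specifier stratum for
#' both outcomes (joint remission, PHQ-ADS mean) and both follow-up waves,
#' with pairwise contrasts and the 2-df overall test.
#'
#' @param data analysis frame.
#' @param split a \code{\link{dichotomize}} result.
#' @param covars baseline covariates.
#' @param outcomes,waves which outcome/wave combinations to compute.
#' @param ... passed to \code{\link{dr_estimate}}.
#' @return Nested list of class \code{stratified_ate}:
#'   \code{[[stratum]][[outcome_wave]]} each holding \code{estimates},
#'   \code{contrasts}, \code{overall}.
#' @export
stratified_ate <- function(data, split, covars = character(),
                           outcomes = c("remission", "phq_ads"),
                           waves = c("3", "12"), ...) {
  lab <- split$label[match(data$participant_id, split$participant_id)]
  out <- list()
  for (s in levels(lab)) {
    d <- data[lab == s, , drop = FALSE]
    if (!nrow(d)) next
    res_s <- list()
    for (oc in outcomes) for (w in waves) {
      ocol <- paste0(oc, "_", w)
      if (!ocol %in% names(d)) next
      fit <- dr_estimate(d, ocol, paste0("c", w), covars, ...)
      cf <- contrasts_from(fit)
      res_s[[paste0(oc, "_", w, "mo")]] <-
        list(estimates = fit$estimates, vcov = fit$vcov,
             contrasts = cf$contrasts, overall = cf$overall,
             n = nrow(d))
    }
    out[[s]] <- res_s
  }
  class(out) <- "stratified_ate"
  out
}

#' Search for the best dichotomization of the specifier
#'
#' Exploratory grid over top fractions maximizing the arm-by-specifier
#' interaction statistic, with a permutation-adjusted p-value that accounts
#' for the selection over the grid.
#'
#' @param data analysis frame.
#' @param scores predicted compliance scores.
#' @param grid candidate top fractions.
#' @param n_perm permutations for the adjusted p-value (0 to skip).
#' @param seed integer seed for the permutations.
#' @param ... passed to \code{\link{interaction_test}}.
#' @return list: \code{best_fraction}, \code{chi2}, grid results, and
#'   \code{p_adjusted} when permutations were run.
#' @export
search_dichotomization <- function(data, scores, grid = seq(0.2, 0.8, 0.1),
                                   n_perm = 0, seed = 1, ...) {
  stat_for <- function(sc) {
    max(vapply(grid, function(f) {
      sp <- dichotomize(sc, f)
      tryCatch(interaction_test(data, sp, ...)$chi2,
               error = function(e) NA_real_)
    }, 0), na.rm = TRUE)
  }
  per_f <- vapply(grid, function(f) {
    sp <- dichotomize(scores, f)
    tryCatch(interaction_test(data, sp, ...)$chi2, error = function(e) NA_real_)
  }, 0)
  best <- which.max(per_f)
  out <- list(best_fraction = grid[best], chi2 = per_f[best],
              grid = data.frame(top_fraction = grid, chi2 = per_f))
  if (n_perm > 0) {
    obs <- out$chi2
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      sc <- scores
      if (is.data.frame(sc)) sc$score <- sample(sc$score)
      else sc[] <- sample(as.numeric(sc))
      stat_for(sc)
    }, 0))
    out$p_adjusted <- (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  out
}

#' Attrition-pattern predictor table
#'
#' For each baseline predictor: completion counts and percentages by level
#' under the three completion definitions (both waves, 3-month, 12-month),
#' the Pearson main-effect chi-square, and a heterogeneity test comparing
#' logistic models of completion on predictor + arm vs predictor x arm
#' (likelihood ratio, df = (levels - 1) x 2).
#'
#' @param data analysis frame with \code{arm}, \code{c3}, \code{c12} and the
#'   predictor columns (character or factor).
#' @param predictors character vector of predictor column names.
#' @return Object of class \code{attrition_table}: \code{counts} (long
#'   data.frame) and \code{tests} (per predictor and definition).
#' @export
attrition_analysis <- function(data, predictors) {
  defs <- list(both = data$c3 == 1 & data$c12 == 1,
               `3mo` = data$c3 == 1,
               `12mo` = data$c12 == 1)
  counts <- NULL
  tests <- NULL
  for (pr in predictors) {
    x <- data[[pr]]
    if (is.null(x)) stopf("predictor '%s' not found", pr)
    x <- factor(x)
    empty <- levels(x)[tabulate(x, nbins = nlevels(x)) == 0]
    if (length(empty)) {
      message(sprintf("dropping empty level(s) of '%s': %s", pr,
                      paste(empty, collapse = ", ")))
      x <- droplevels(x)
    }
    for (dn in names(defs)) {
      comp <- as.integer(defs[[dn]])
      tab <- table(x, comp)
      counts <- rbind(counts, data.frame(
        predictor = pr, definition = dn, level = levels(x),
        n = as.vector(table(x)),
        completed = as.vector(tapply(comp, x, sum)),
        pct = 100 * as.vector(tapply(comp, x, mean)),
        stringsAsFactors = FALSE))
      main <- if (nlevels(x) > 1 && all(rowSums(tab) > 0) &&
                  all(colSums(tab) > 0)) {
        pearson_chi2(tab)
      } else list(chi2 = NA, df = NA, p = NA)
      het <- .heterogeneity_lrt(comp, x, data$arm)
      tests <- rbind(tests, data.frame(
        predictor = pr, definition = dn,
        main_chi2 = main$chi2, main_df = main$df, main_p = main$p,
        het_chi2 = het$chi2, het_df = het$df, het_p = het$p,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(counts = counts, tests = tests),
            class = "attrition_table")
}

.heterogeneity_lrt <- function(comp, x, arm) {
  if (nlevels(x) < 2) return(list(chi2 = NA, df = NA, p = NA))
  df0 <- data.frame(comp = comp, x = x, arm = arm)
  m_add <- suppressWarnings(stats::glm(comp ~ x + arm, df0,
                                       family = stats::binomial()))
  m_int <- suppressWarnings(stats::glm(comp ~ x * arm, df0,
                                       family = stats::binomial()))
  chi2 <- m_add$deviance - m_int$deviance
  df <- m_add$df.residual - m_int$df.residual
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
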