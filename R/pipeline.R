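#' End-to-end analysis pipeline
#'
#' Orchestrates the full analysis on either a synthetic trial or four input
#' CSV tables: score compliance with the nested cross-validated ensemble in
#' the self-guided arm and counterfactually score everyone, estimate
#' adjusted per-arm effects at 3 months (single-wave) and 12 months
#' (longitudinal, with multiple imputation of 3-month scores for
#' 12-month-only responders), dichotomize predicted compliance and test the
#' arm-by-specifier interaction, tabulate attrition patterns, summarize
#' usage per period, and attribute the compliance model. Stage ordering
#' guarantees that the compliance model never sees follow-up outcomes.
#'
#' @name cli_pipeline
NULL

#' Pipeline run configuration
#'
#' Exactly one of \code{generator} (a \code{\link{generator_config}}) or
#' \code{paths} (named list with elements \code{baseline}, \code{arms},
#' \code{usage}, \code{followup} pointing to CSV files) must be supplied.
#'
#' @param generator synthetic-data configuration.
#' @param paths input CSV paths.
#' @param seed master seed for all analysis stages.
#' @param covars covariates used in nuisance models (default: a compact
#'   subset of the codebook).
#' @param estimator \code{"tmle"} or \code{"aipw"}.
#' @param bound propensity truncation bound.
#' @param mi_m,mi_k multiple-imputation settings.
#' @param folds outer/inner fold count of the nested cross-validation.
#' @param top_fraction specifier dichotomization fraction.
#' @param learner_names base learner library subset.
#' @param shap_budget coalition budget for sampled kernel SHAP.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(generator = NULL, paths = NULL, seed = 1,
                       covars = default_adjustment_covars(),
                       estimator = "tmle", bound = 0.01,
                       mi_m = 20, mi_k = 5, folds = 10,
                       top_fraction = 0.40,
                       learner_names = c("mean", "lm", "ridge", "lasso"),
                       shap_budget = 1024) {
  if (is.null(generator) == is.null(paths))
    stopf("exactly one of 'generator' or 'paths' must be given")
  if (top_fraction <= 0 || top_fraction >= 1)
    stopf("top_fraction must be in (0,1)")
  structure(list(generator = generator, paths = paths, seed = seed,
                 covars = covars, estimator = estimator, bound = bound,
                 mi_m = mi_m, mi_k = mi_k, folds = folds,
                 top_fraction = top_fraction,
                 learner_names = learner_names,
                 shap_budget = shap_budget),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_adjustment_covars <- function() {
  c("gad7_0", "phq9_0", "country_mexico", "clinic_waitlist",
    "clinic_campus", "female", "employed", "first_generation")
}

# Baseline fields permitted in the compliance model design matrix; the
# temporal firewall rejects anything else (notably follow-up scores).
.firewall_check <- function(feature_names) {
  banned <- grepl("_3$|_12$|^remission|^c3$|^c12$|^gad7_3|^phq9_3", feature_names)
  if (any(banned))
    stopf("temporal firewall violation: follow-up fields in compliance model: %s",
          paste(feature_names[banned], collapse = ", "))
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' @param config a \code{\link{run_config}}.
#' @return Object of class \code{pipeline_result}: trial data, predicted
#'   compliance scores and cv R-squared, ATE tables at both waves,
#'   stratified tables, interaction test, attrition table, usage summaries,
#'   SHAP report and a reproducibility manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()

  # stage 1: data
  if (!is.null(config$generator)) {
    trial <- generate_trial(config$generator)
  } else {
    trial <- read_trial(config$paths)
    issues <- validate_inputs(config$paths)
    if (nrow(issues)) {
      stopf("input validation failed (%d issues); first: %s",
            nrow(issues), issues$issue[1])
    }
  }
  data <- analysis_frame(trial)

  # stage 2: compliance scores (baseline covariates only)
  cb_names <- codebook_names()
  X <- as.matrix(data[, cb_names])
  .firewall_check(colnames(X))
  y <- compliance_target(trial$usage)
  sg <- data$arm == "self_guided"
  learners <- default_learners(config$learner_names)
  oof <- nested_cv_score(X[sg, , drop = FALSE], y[sg], learners,
                         outer_folds = config$folds,
                         inner_folds = config$folds,
                         seed = derive_seed(config$seed, "nested"),
                         ids = data$participant_id[sg])
  full_model <- fit_superlearner(X[sg, , drop = FALSE], y[sg], learners,
                                 folds = config$folds,
                                 seed = derive_seed(config$seed, "full"))
  scores <- score_all(full_model, X, data$participant_id, oof)

  # stage 3: ATE at 3 months (single wave)
  ate3 <- lapply(c(remission = "remission_3", phq_ads = "phq_ads_3"),
                 function(oc) {
                   fit <- dr_estimate(data, oc, "c3", config$covars,
                                      estimator = config$estimator,
                                      bound = config$bound)
                   c(list(estimates = fit$estimates, vcov = fit$vcov),
                     contrasts_from(fit))
                 })

  # stage 4: ATE at 12 months (longitudinal over MI datasets)
  ate12 <- .ate12_mi(data, config)

  # stage 5: specifier analyses
  split <- dichotomize(scores, config$top_fraction)
  inter <- interaction_test(data, split, "remission_12", "c12",
                            config$covars, estimator = config$estimator,
                            bound = config$bound)
  strat <- stratified_ate(data, split, config$covars,
                          estimator = config$estimator,
                          bound = config$bound)

  # stage 6: attrition table
  attr_tab <- attrition_analysis(
    data, c("country", "sex", "clinic_status", "sexual_orientation",
            "age_group"))

  # stage 7: usage summaries
  usage_sum <- list(`1-12` = summarize_usage(trial$usage, trial$arms, "1-12"),
                    `13-52` = summarize_usage(trial$usage, trial$arms,
                                              "13-52"))

  # stage 8: attribution of the compliance model
  shap_rep <- .shap_report(full_model, X[sg, , drop = FALSE],
                           config$shap_budget,
                           derive_seed(config$seed, "shap"))

  manifest <- list(
    seed = config$seed,
    n = nrow(data),
    package_version = as.character(utils::packageVersion("predcomply")),
    codebook_version = attr(covariate_codebook(), "codebook_version"),
    stages = c("data", "compliance", "ate3", "ate12", "specifier",
               "attrition", "usage", "shap"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(trial = trial, data = data, scores = scores,
                 cv_r2 = oof$cv_r2, cv_r2_se = oof$se,
                 ate_3mo = ate3, ate_12mo = ate12, split = split,
                 interaction = inter, stratified = strat,
                 attrition = attr_tab, usage = usage_sum,
                 shap = shap_rep, manifest = manifest,
                 config = config),
            class = "pipeline_result")
}

.ate12_mi <- function(data, config) {
  has_12only <- any(data$c3 == 0 & data$c12 == 1)
  run_one <- function(d, oc) {
    longitudinal_dr_estimate(
      d, oc, l1_cols = c("phq_ads_3"), c1_col = "c3", c2_col = "c12",
      covars = config$covars, estimator = config$estimator,
      bound = config$bound)
  }
  outcomes <- c(remission = "remission_12", phq_ads = "phq_ads_12")
  if (!has_12only) {
    return(lapply(outcomes, function(oc) {
      fit <- run_one(data, oc)
      c(list(estimates = fit$estimates, vcov = fit$vcov),
        contrasts_from(fit))
    }))
  }
  imp <- impute_3mo_pmm(data, config$covars, m = config$mi_m,
                        k = config$mi_k,
                        seed = derive_seed(config$seed, "pmm"))
  lapply(outcomes, function(oc) {
    fits <- lapply(imp, run_one, oc = oc)
    pooled <- do.call(rbind, lapply(ARM_LEVELS, function(a) {
      ests <- lapply(fits, function(f) {
        r <- f$estimates[f$estimates$arm == a, ]
        adjusted_estimate(a, r$value, r$se, wave = "12mo")
      })
      pe <- pool_rubin(ests)
      data.frame(arm = a, value = pe$value, se = pe$se,
                 n_arm = fits[[1]]$estimates$n_arm[
                   fits[[1]]$estimates$arm == a],
                 stringsAsFactors = FALSE)
    }))
    # average the within-imputation covariance across datasets; between-
    # imputation covariance from the estimate vectors
    Vw <- Reduce(`+`, lapply(fits, function(f) f$vcov)) / length(fits)
    vals <- do.call(rbind, lapply(fits, function(f) f$estimates$value))
    Vb <- stats::cov(vals)
    V <- Vw + (1 + 1 / length(fits)) * Vb
    fake <- list(estimates = pooled, vcov = V)
    class(fake) <- "dr_result"
    c(list(estimates = pooled, vcov = V, m = length(fits)),
      contrasts_from(fake))
  })
}

.shap_report <- function(model, X, budget, seed) {
  pf <- function(M) predict(model, M)
  summ <- shap_p(pf, X)
  ks <- kernel_shap(pf, X, coalition_budget = budget, seed = seed)
  dirs <- dominant_direction(ks, X)
  summ$kernel_mean_abs <- colMeans(abs(ks$values))[summ$feature]
  summ$direction <- unname(dirs[summ$feature])
  ranked <- rank_predictors(summ, k = 5, floor = 0.01)
  list(summary = summ, ranked = ranked,
       whole_model = attr(summ, "whole_model"),
       local_accuracy = max(abs(rowSums(ks$values) - (ks$fx - ks$base))))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("predcomply pipeline result\n")
  cat(sprintf("  n=%d; cv R^2 of predicted compliance: %.3f (SE %.3f)\n",
              nrow(x$data), x$cv_r2, x$cv_r2_se))
  cat("  12-month joint remission (adjusted):\n")
  print(x$ate_12mo$remission$estimates, row.names = FALSE, digits = 3)
  cat(sprintf("  arm x specifier interaction: chi2(1)=%.2f, p=%.3g\n",
              x$interaction$chi2, x$interaction$p))
  invisible(x)
}

#' Write trial tables to CSV
#'
#' Writes the four analysis inputs (baseline, arms, usage, follow-up) plus
#' a ground-truth JSON and a run manifest.
#'
#' @param trial a \code{synthetic_trial}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(baseline = file.path(dir, "baseline.csv"),
                arms = file.path(dir, "arms.csv"),
                usage = file.path(dir, "usage.csv"),
                followup = file.path(dir, "followup.csv"))
  baseline <- trial$cohort
  attr(baseline, "latent") <- NULL
  attr(baseline, "covariate_index") <- NULL
  utils::write.csv(baseline, paths$baseline, row.names = FALSE)
  utils::write.csv(trial$arms, paths$arms, row.names = FALSE)
  utils::write.csv(trial$usage, paths$usage, row.names = FALSE)
  fu <- trial$followup
  baseline_rows <- data.frame(participant_id = trial$cohort$participant_id,
                              wave = 0L, completed = 1L,
                              gad7 = trial$cohort$gad7_0,
                              phq9 = trial$cohort$phq9_0)
  utils::write.csv(rbind(baseline_rows, fu), paths$followup,
                   row.names = FALSE)
  jsonlite::write_json(
    list(arm_means = trial$truth$arm_means,
         contrasts = trial$truth$contrasts,
         seed = trial$config$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read trial tables from CSV
#'
#' @param paths named list: \code{baseline}, \code{arms}, \code{usage},
#'   \code{followup}.
#' @return A \code{synthetic_trial}-compatible object (without ground
#'   truth).
#' @export
read_trial <- function(paths) {
  baseline <- utils::read.csv(paths$baseline, stringsAsFactors = FALSE)
  arms <- utils::read.csv(paths$arms, stringsAsFactors = FALSE)
  arms$arm <- factor(arms$arm, levels = ARM_LEVELS)
  usage <- utils::read.csv(paths$usage, stringsAsFactors = FALSE)
  fu <- utils::read.csv(paths$followup, stringsAsFactors = FALSE)
  fu <- fu[fu$wave != 0, , drop = FALSE]
  ord <- match(baseline$participant_id, fu$participant_id)
  mk <- function(w) {
    sub <- fu[fu$wave == w, , drop = FALSE]
    sub[match(baseline$participant_id, sub$participant_id), , drop = FALSE]
  }
  f3 <- mk(3); f12 <- mk(12)
  outcomes <- data.frame(participant_id = baseline$participant_id,
                         gad7_3 = f3$gad7, phq9_3 = f3$phq9,
                         phq_ads_3 = f3$gad7 + f3$phq9,
                         gad7_12 = f12$gad7, phq9_12 = f12$phq9,
                         phq_ads_12 = f12$gad7 + f12$phq9)
  completion <- data.frame(participant_id = baseline$participant_id,
                           c3 = as.integer(f3$completed),
                           c12 = as.integer(f12$completed))
  structure(list(cohort = baseline, arms = arms, usage = usage,
                 outcomes = outcomes, completion = completion,
                 followup = fu, truth = NULL, config = NULL),
            class = "synthetic_trial")
}

#' Validate analysis input tables
#'
#' Schema, range and cross-file referential integrity checks on the four
#' CSV inputs. Estimation never runs on data with outstanding issues.
#'
#' @param paths named list of CSV paths (as in \code{\link{read_trial}}).
#' @return data.frame of issues (\code{file}, \code{row}, \code{issue});
#'   zero rows when the inputs are clean.
#' @export
validate_inputs <- function(paths) {
  issues <- data.frame(file = character(), row = integer(),
                       issue = character(), stringsAsFactors = FALSE)
  add <- function(file, row, issue) {
    issues <<- rbind(issues, data.frame(file = file, row = row,
                                        issue = issue,
                                        stringsAsFactors = FALSE))
  }
  for (f in c("baseline", "arms", "usage", "followup")) {
    if (is.null(paths[[f]]) || !file.exists(paths[[f]])) {
      add(f, NA_integer_, sprintf("file missing: %s", f))
    }
  }
  if (nrow(issues)) return(issues)
  baseline <- utils::read.csv(paths$baseline, stringsAsFactors = FALSE)
  arms <- utils::read.csv(paths$arms, stringsAsFactors = FALSE)
  usage <- utils::read.csv(paths$usage, stringsAsFactors = FALSE)
  fu <- utils::read.csv(paths$followup, stringsAsFactors = FALSE)

  need_b <- c("participant_id", "gad7_0", "phq9_0")
  for (col in setdiff(need_b, names(baseline)))
    add("baseline", NA, sprintf("missing column %s", col))
  if (all(need_b %in% names(baseline))) {
    bad <- which(baseline$gad7_0 < 0 | baseline$gad7_0 > 21)
    for (r in bad) add("baseline", r, "gad7 outside scale range 0-21")
    bad <- which(baseline$phq9_0 < 0 | baseline$phq9_0 > 27)
    for (r in bad) add("baseline", r, "phq9 outside scale range 0-27")
  }
  if (!all(c("participant_id", "arm") %in% names(arms))) {
    add("arms", NA, "missing participant_id/arm column")
  } else {
    bad <- which(!arms$arm %in% ARM_LEVELS)
    for (r in bad) add("arms", r, sprintf("unknown arm '%s'", arms$arm[r]))
    orphan <- which(!arms$participant_id %in% baseline$participant_id)
    for (r in orphan) add("arms", r, "arm row with unknown participant_id")
  }
  wk <- paste0("week_", 1:52)
  if (!all(wk %in% names(usage))) {
    add("usage", NA, "missing week_1..week_52 columns")
  } else {
    neg <- which(apply(usage[, wk] < 0, 1, any))
    for (r in neg) add("usage", r, "negative minutes")
    orphan <- which(!usage$participant_id %in% baseline$participant_id)
    for (r in orphan) add("usage", r, "usage row with unknown participant_id")
  }
  if (!all(c("participant_id", "wave", "completed") %in% names(fu))) {
    add("followup", NA, "missing required columns")
  } else {
    orphan <- which(!fu$participant_id %in% baseline$participant_id)
    for (r in orphan)
      add("followup", r, "follow-up row with unknown participant_id")
    bad <- which(!fu$wave %in% c(0, 3, 12))
    for (r in bad) add("followup", r, "wave must be 0, 3 or 12")
    comp <- which(fu$completed == 1 & fu$wave != 0)
    bad <- comp[!is.na(fu$gad7[comp]) & (fu$gad7[comp] < 0 |
                                           fu$gad7[comp] > 21)]
    for (r in bad) add("followup", r, "gad7 outside scale range 0-21")
    bad <- comp[!is.na(fu$phq9[comp]) & (fu$phq9[comp] < 0 |
                                           fu$phq9[comp] > 27)]
    for (r in bad) add("followup", r, "phq9 outside scale range 0-27")
    miss <- comp[is.na(fu$gad7[comp]) | is.na(fu$phq9[comp])]
    for (r in miss) add("followup", r, "completed wave without scores")
  }
  issues
}

#' Write pipeline outputs to disk
#'
#' Tidy CSV results (estimand, wave, arm/pair, value, se, chi2, df, p),
#' scores, SHAP report and the JSON manifest.
#'
#' @param result a \code{pipeline_result}.
#' @param dir output directory.
#' @return Invisibly, the output directory.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tidy <- NULL
  grab <- function(block, estimand, wave) {
    est <- block$estimates
    rows <- data.frame(estimand = estimand, wave = wave,
                       unit = est$arm, value = est$value, se = est$se,
                       chi2 = NA, df = NA, p = NA,
                       stringsAsFactors = FALSE)
    ct <- block$contrasts
    rows <- rbind(rows, data.frame(
      estimand = estimand, wave = wave, unit = ct$pair,
      value = ct$difference, se = ct$se, chi2 = ct$chi2, df = ct$df,
      p = ct$p, stringsAsFactors = FALSE))
    ov <- block$overall
    rbind(rows, data.frame(estimand = estimand, wave = wave,
                           unit = "overall", value = NA, se = NA,
                           chi2 = ov$chi2, df = ov$df, p = ov$p,
                           stringsAsFactors = FALSE))
  }
  for (oc in names(result$ate_3mo))
    tidy <- rbind(tidy, grab(result$ate_3mo[[oc]], oc, "3mo"))
  for (oc in names(result$ate_12mo))
    tidy <- rbind(tidy, grab(result$ate_12mo[[oc]], oc, "12mo"))
  utils::write.csv(tidy, file.path(dir, "ate_results.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$scores),
                   file.path(dir, "predicted_compliance.csv"),
                   row.names = FALSE)
  utils::write.csv(result$shap$summary, file.path(dir, "shap_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$attrition$counts,
                   file.path(dir, "attrition_counts.csv"), row.names = FALSE)
  utils::write.csv(result$attrition$tests,
                   file.path(dir, "attrition_tests.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
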