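#' Cross-validated stacking ensemble (super learner)
#'
#' Predicts the compliance target from baseline covariates by stacking a
#' small library of base learners: out-of-fold predictions of every learner
#' are combined with non-negative weights summing to one (simplex), chosen
#' to minimize the cross-validated squared error. Nested cross-validation
#' (an outer loop around the whole stacking procedure) yields out-of-sample
#' scores for the training arm that were never touched by the model that
#' produced them.
#'
#' @name superlearner
NULL

#' Base learner library
#'
#' Each learner is a list with \code{name}, \code{fit(X, y)} and
#' \code{predict(fit, X)}. The library always contains the mean-only
#' learner, which guards against negative-signal overfitting: under pure
#' noise it receives the weight.
#'
#' @param names subset of \code{c("mean", "lm", "ridge", "lasso", "xgboost",
#'   "knn")}; the mean learner is always included. The gradient-boosted tree
#'   learner is only included when the xgboost package is installed.
#' @return list of learner specifications.
#' @export
default_learners <- function(names = c("mean", "lm", "ridge", "lasso",
                                       "xgboost", "knn")) {
  lib <- list()
  lib$mean <- list(
    name = "mean",
    fit = function(X, y) mean(y),
    predict = function(fit, X) rep(fit, nrow(X)))
  lib$lm <- list(
    name = "lm",
    fit = function(X, y) {
      Xc <- cbind(1, X)
      qr.coef(qr(Xc), y)
    },
    predict = function(fit, X) {
      b <- fit; b[is.na(b)] <- 0
      drop(cbind(1, X) %*% b)
    })
  glmnet_learner <- function(alpha, lam_scale) list(
    name = if (alpha == 0) "ridge" else "lasso",
    fit = function(X, y) {
      if (stats::var(y) == 0 || ncol(X) < 2) return(list(const = mean(y)))
      glmnet::glmnet(X, y, alpha = alpha,
                     lambda = lam_scale * stats::sd(y))
    },
    predict = function(fit, X) {
      if (!is.null(fit$const)) return(rep(fit$const, nrow(X)))
      drop(stats::predict(fit, newx = X))
    })
  lib$ridge <- glmnet_learner(0, 0.10)
  lib$lasso <- glmnet_learner(1, 0.02)
  lib$xgboost <- list(
    name = "xgboost",
    fit = function(X, y) {
      xgboost::xgb.train(
        params = list(max_depth = 2, eta = 0.1, subsample = 0.8,
                      objective = "reg:squarederror", nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = y), nrounds = 50)
    },
    predict = function(fit, X) stats::predict(fit, xgboost::xgb.DMatrix(X)))
  lib$knn <- list(
    name = "knn",
    fit = function(X, y) {
      mu <- colMeans(X); sd <- apply(X, 2, stats::sd); sd[sd == 0] <- 1
      list(X = sweep(sweep(X, 2, mu), 2, sd, "/"), y = y, mu = mu, sd = sd,
           k = min(20L, length(y)))
    },
    predict = function(fit, X) {
      Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")
      d2 <- outer(rowSums(Xs^2), rowSums(fit$X^2), "+") -
        2 * Xs %*% t(fit$X)
      apply(d2, 1, function(r)
        mean(fit$y[order(r)[seq_len(fit$k)]]))
    })
  names <- union("mean", names)
  if (!requireNamespace("xgboost", quietly = TRUE))
    names <- setdiff(names, "xgboost")
  lib[intersect(c("mean", "lm", "ridge", "lasso", "xgboost", "knn"), names)]
}

# Minimize ||y - Zw||^2 over the simplex {w >= 0, sum w = 1}.
# Non-negative least squares (Lawson-Hanson) followed by normalization,
# then a projected-gradient polish; finally guarded against the simplex
# vertices so the ensemble CV risk never exceeds the best single learner's.
.simplex_weights <- function(Z, y) {
  L <- ncol(Z)
  if (L == 1) return(1)
  w0 <- tryCatch(pracma::lsqnonneg(Z, y)$x, error = function(e) rep(1, L))
  if (sum(w0) <= 0) w0 <- rep(1, L)
  w <- w0 / sum(w0)
  risk <- function(w) mean((y - drop(Z %*% w))^2)
  # projected gradient with Duchi simplex projection
  lip <- 2 * max(colSums(Z^2)) / length(y)
  step <- 1 / lip
  proj <- function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (css[rho] - 1) / rho
    pmax(v - theta, 0)
  }
  for (it in 1:500) {
    g <- -2 * drop(crossprod(Z, y - drop(Z %*% w))) / length(y)
    w_new <- proj(w - step * g)
    if (max(abs(w_new - w)) < 1e-10) { w <- w_new; break }
    w <- w_new
  }
  # vertex guard: never worse than the best single learner
  vertex_risks <- colMeans((y - Z)^2)
  if (risk(w) > min(vertex_risks)) {
    w <- as.numeric(seq_len(L) == which.min(vertex_risks))
  }
  w
}

.make_folds <- function(n, k) {
  if (n < k) stopf("n (%d) must be at least the number of folds (%d)", n, k)
  sample(rep_len(seq_len(k), n))
}

#' Fit the stacking ensemble
#'
#' @param X numeric covariate matrix (no missing values).
#' @param y numeric compliance targets.
#' @param learners learner library (\code{\link{default_learners}}).
#' @param folds number of cross-validation folds for weight estimation.
#' @param seed integer seed (fold assignment).
#' @return Object of class \code{superlearner}: simplex \code{weights}, the
#'   refit base learners, per-learner and ensemble CV risks, and fold
#'   assignments.
#' @export
fit_superlearner <- function(X, y, learners = default_learners(),
                             folds = 10, seed = 1) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stopf("missing values in X or y")
  if (length(learners) < 1) stopf("need at least one learner")
  n <- nrow(X)
  L <- length(learners)
  fold_id <- with_seed(seed, .make_folds(n, folds))

  if (stats::var(y) == 0) {
    # constant target: mean-only carries all the weight
    w <- as.numeric(vapply(learners, function(l) l$name, "") == "mean")
    if (sum(w) == 0) w <- c(1, rep(0, L - 1))
    fits <- lapply(learners, function(l) l$fit(X, y))
    out <- list(learners = learners, weights = w, fits = fits,
                fold_id = fold_id, cv_risks = rep(0, L), ensemble_risk = 0,
                feature_names = colnames(X), seed = seed)
    class(out) <- "superlearner"
    return(out)
  }

  Z <- matrix(NA_real_, n, L)
  for (k in seq_len(max(fold_id))) {
    tr <- fold_id != k
    for (l in seq_len(L)) {
      fit <- learners[[l]]$fit(X[tr, , drop = FALSE], y[tr])
      Z[!tr, l] <- learners[[l]]$predict(fit, X[!tr, , drop = FALSE])
    }
  }
  w <- .simplex_weights(Z, y)
  fits <- lapply(learners, function(l) l$fit(X, y))
  out <- list(learners = learners, weights = w, fits = fits,
              fold_id = fold_id,
              cv_risks = colMeans((y - Z)^2),
              ensemble_risk = mean((y - drop(Z %*% w))^2),
              feature_names = colnames(X), seed = seed)
  class(out) <- "superlearner"
  out
}

#' @export
predict.superlearner <- function(object, newX, ...) {
  newX <- as.matrix(newX)
  if (!is.null(object$feature_names)) {
    missing_cols <- setdiff(object$feature_names, colnames(newX))
    if (length(missing_cols))
      stopf("covariate schema mismatch; missing columns: %s",
            paste(missing_cols, collapse = ", "))
    newX <- newX[, object$feature_names, drop = FALSE]
  }
  P <- vapply(seq_along(object$learners), function(l)
    object$learners[[l]]$predict(object$fits[[l]], newX),
    numeric(nrow(newX)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  drop(P %*% object$weights)
}

#' @export
print.superlearner <- function(x, ...) {
  cat("Stacking ensemble (simplex weights):\n")
  for (l in seq_along(x$learners))
    cat(sprintf("  %-8s weight %.3f  cv risk %.4f\n",
                x$learners[[l]]$name, x$weights[l], x$cv_risks[l]))
  cat(sprintf("  ensemble cv risk %.4f\n", x$ensemble_risk))
  invisible(x)
}

#' Nested cross-validated out-of-sample scores and CV R-squared
#'
#' Outer folds hold participants out of the entire stacking procedure
#' (base-learner fitting and weight estimation both happen inside the inner
#' loop on the remaining folds), so each participant's score comes from a
#' model that never saw them. The out-of-fold R-squared estimates how well
#' compliance can be predicted from baseline covariates; its SE is the
#' leave-one-fold-out jackknife.
#'
#' @param X,y,learners as in \code{\link{fit_superlearner}}.
#' @param outer_folds,inner_folds fold counts of the nested loops.
#' @param seed integer seed.
#' @param ids optional participant identifiers for the score names.
#' @return list of class \code{nested_cv}: \code{scores} (named numeric),
#'   \code{cv_r2}, \code{se}, \code{fold_id}.
#' @export
nested_cv_score <- function(X, y, learners = default_learners(),
                            outer_folds = 10, inner_folds = 10, seed = 1,
                            ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  fold_id <- with_seed(seed, .make_folds(n, outer_folds))
  if (min(table(fold_id)) < 2) stopf("a fold has fewer than 2 observations")
  scores <- numeric(n)
  for (k in seq_len(max(fold_id))) {
    tr <- fold_id != k
    sl <- fit_superlearner(X[tr, , drop = FALSE], y[tr], learners,
                           folds = inner_folds,
                           seed = derive_seed(seed, paste0("inner", k)))
    scores[!tr] <- predict(sl, X[!tr, , drop = FALSE])
  }
  r2_all <- r2(y, scores)
  # fold-wise jackknife of R^2
  K <- max(fold_id)
  r2_loo <- vapply(seq_len(K), function(k)
    r2(y[fold_id != k], scores[fold_id != k]), 0)
  se <- sqrt((K - 1) / K * sum((r2_loo - mean(r2_loo))^2))
  if (!is.null(ids)) names(scores) <- ids
  structure(list(scores = scores, cv_r2 = r2_all, se = se,
                 fold_id = fold_id, outer_folds = outer_folds,
                 inner_folds = inner_folds, seed = seed),
            class = "nested_cv")
}

#' Coefficient of determination
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return 1 - SSE/SST; may be negative for predictions worse than the mean.
#' @export
r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stopf("observed and predicted must have equal length >= 2")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stopf("observed values are constant; R^2 undefined")
  1 - sum((observed - predicted)^2) / sst
}

#' Score every trial participant with predicted compliance
#'
#' Participants in the training (self-guided) arm receive their nested
#' out-of-fold scores; all other participants are scored by the full
#' ensemble fitted on the entire training arm. Every participant is scored
#' exactly once.
#'
#' @param model full-data \code{superlearner} fit on the training arm.
#' @param X covariate matrix for the whole cohort (rows named or paired
#'   with \code{ids}).
#' @param ids participant identifiers for the rows of \code{X}.
#' @param oof a \code{nested_cv} result whose \code{scores} are named with
#'   training-arm participant ids.
#' @return data.frame of class \code{predicted_compliance}:
#'   \code{participant_id}, \code{score}, \code{provenance}.
#' @export
score_all <- function(model, X, ids, oof) {
  X <- as.matrix(X)
  stopifnot(length(ids) == nrow(X))
  if (is.null(names(oof$scores)))
    stopf("out-of-fold scores must be named with participant ids")
  full <- predict(model, X)
  score <- full
  prov <- rep("full-model", length(ids))
  in_arm <- ids %in% names(oof$scores)
  score[in_arm] <- oof$scores[ids[in_arm]]
  prov[in_arm] <- "out-of-fold"
  out <- data.frame(participant_id = ids, score = score,
                    provenance = prov, stringsAsFactors = FALSE)
  class(out) <- c("predicted_compliance", "data.frame")
  out
}
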