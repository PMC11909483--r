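#' Attribution of the compliance prediction model
#'
#' Two complementary attribution constructions are provided. Kernel Shapley
#' values distribute each participant's prediction (relative to the
#' prediction at the covariate-mean reference) across features, exactly for
#' small feature sets by enumerating all coalitions with the Shapley kernel
#' weights. The mean-substitution statistic measures, per feature, the mean
#' absolute change in the prediction when that feature is reset to its
#' sample mean; the proportional SHAP (SHAP_P) expresses it as a percentage
#' of the whole-model statistic (the mean absolute change when all features
#' are reset at once). SHAP_P values can sum above 100% because most
#' participants sit above the mean on some features and below it on others.
#'
#' @name shap_explain
NULL

#' Kernel Shapley values
#'
#' For p <= 12 features all 2^p coalitions are enumerated, which yields the
#' exact Shapley values; for larger p coalitions are sampled with the
#' Shapley kernel weights up to \code{coalition_budget}. The value function
#' of a coalition replaces absent features by the reference (sample mean)
#' values.
#'
#' @param predict_fun function mapping a numeric matrix of covariates to
#'   predictions (e.g. wrapping \code{predict} on a fitted model).
#' @param X numeric covariate matrix (participants x features).
#' @param reference reference covariate vector; defaults to column means.
#' @param coalition_budget maximum coalitions when sampling (p > 12).
#' @param seed integer seed (only used when sampling).
#' @return Object of class \code{shap_matrix}: the attribution matrix
#'   (participants x features), \code{base} (prediction at the reference)
#'   and \code{fx} (per-participant predictions). Local accuracy holds:
#'   rowSums equal \code{fx - base}.
#' @export
kernel_shap <- function(predict_fun, X, reference = NULL,
                        coalition_budget = 2048, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(reference)) reference <- colMeans(X)
  stopifnot(length(reference) == p)
  base <- as.numeric(predict_fun(matrix(reference, 1, p,
                                        dimnames = list(NULL, colnames(X)))))
  fx <- as.numeric(predict_fun(X))

  if (p == 1) {
    phi <- matrix(fx - base, n, 1, dimnames = list(NULL, colnames(X)))
    return(structure(list(values = phi, base = base, fx = fx,
                          exact = TRUE), class = "shap_matrix"))
  }

  if (p <= 12) {
    Zfull <- as.matrix(expand.grid(rep(list(0:1), p)))[, p:1, drop = FALSE]
    sizes <- rowSums(Zfull)
    keep <- sizes > 0 & sizes < p
    Z <- Zfull[keep, , drop = FALSE]
    ks <- rowSums(Z)
    wts <- (p - 1) / (choose(p, ks) * ks * (p - ks))
    exact <- TRUE
  } else {
    # weighted sampling of coalition sizes, then uniform subsets of that size
    ks_all <- 1:(p - 1)
    size_w <- (p - 1) / (ks_all * (p - ks_all))
    n_coal <- min(coalition_budget, 2^p - 2)
    Z <- with_seed(seed, {
      ks <- sample(ks_all, n_coal, TRUE, prob = size_w / sum(size_w))
      t(vapply(ks, function(k) {
        z <- numeric(p); z[sample.int(p, k)] <- 1; z
      }, numeric(p)))
    })
    wts <- rep(1, nrow(Z))
    exact <- FALSE
  }

  # value of each coalition for every participant
  V <- matrix(NA_real_, n, nrow(Z))
  for (j in seq_len(nrow(Z))) {
    on <- Z[j, ] == 1
    Xz <- matrix(reference, n, p, byrow = TRUE)
    Xz[, on] <- X[, on, drop = FALSE]
    colnames(Xz) <- colnames(X)
    V[, j] <- predict_fun(Xz)
  }

  # constrained weighted least squares, shared design across participants:
  # phi = A^{-1} (b - lambda * 1), lambda chosen so sum(phi) = fx - base
  W <- wts
  A <- crossprod(Z * W, Z)
  Ainv <- solve(A)
  B <- crossprod(Z * W, t(V - base))      # p x n
  ones <- rep(1, p)
  Ai1 <- Ainv %*% ones
  denom <- drop(crossprod(ones, Ai1))
  lam <- (drop(crossprod(ones, Ainv %*% B)) - (fx - base)) / denom
  phi <- t(Ainv %*% B - Ai1 %*% t(lam))   # n x p
  colnames(phi) <- colnames(X)
  structure(list(values = phi, base = base, fx = fx, exact = exact),
            class = "shap_matrix")
}

#' @export
print.shap_matrix <- function(x, ...) {
  cat(sprintf("Kernel SHAP values: %d participants x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$exact) "exact enumeration" else "sampled coalitions"))
  cat(sprintf("  base value %.4f; max |local accuracy residual| %.2e\n",
              x$base, max(abs(rowSums(x$values) - (x$fx - x$base)))))
  invisible(x)
}

#' Mean-substitution attribution
#'
#' Per feature, the mean over participants of the absolute change in the
#' prediction when that feature is reset from its observed value to the
#' sample mean.
#'
#' @inheritParams kernel_shap
#' @return Named numeric vector of per-feature values.
#' @export
mean_substitution_shap <- function(predict_fun, X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  f0 <- as.numeric(predict_fun(X))
  vapply(seq_len(ncol(X)), function(j) {
    Xj <- X
    Xj[, j] <- mu[j]
    mean(abs(f0 - as.numeric(predict_fun(Xj))))
  }, 0) -> vals
  names(vals) <- colnames(X)
  vals
}

#' Proportional SHAP (SHAP_P) summary
#'
#' Each feature's mean-substitution value as a percentage of the
#' whole-model value (the mean absolute prediction change when all features
#' are reset to their means at once).
#'
#' @inheritParams kernel_shap
#' @return data.frame of class \code{shap_summary}: \code{feature},
#'   \code{shap_value} (mean-substitution), \code{shap_p} (percent); the
#'   whole-model value is attached as attribute \code{"whole_model"}.
#' @export
shap_p <- function(predict_fun, X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  f0 <- as.numeric(predict_fun(X))
  fbar <- as.numeric(predict_fun(matrix(mu, 1, ncol(X),
                                        dimnames = list(NULL, colnames(X)))))
  whole <- mean(abs(f0 - fbar))
  if (whole == 0) stopf("constant model: whole-model SHAP value is zero")
  vals <- mean_substitution_shap(predict_fun, X)
  out <- data.frame(feature = names(vals), shap_value = unname(vals),
                    shap_p = 100 * unname(vals) / whole,
                    stringsAsFactors = FALSE)
  attr(out, "whole_model") <- whole
  class(out) <- c("shap_summary", "data.frame")
  out
}

#' Dominant direction of association per feature
#'
#' Sign of the Pearson correlation between feature values and their
#' per-participant attributions (the numeric analogue of reading a beeswarm
#' plot). Near-zero correlation, e.g. a symmetric U-shaped dependence, is
#' flagged indeterminate.
#'
#' @param shap a \code{\link{kernel_shap}} result.
#' @param X the covariate matrix the values were computed on.
#' @param tol absolute correlation below which the direction is
#'   indeterminate.
#' @return Character vector per feature: "positive", "negative" or
#'   "indeterminate".
#' @export
dominant_direction <- function(shap, X, tol = 0.05) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]; v <- shap$values[, j]
    if (stats::sd(x) == 0 || stats::sd(v) == 0) return("indeterminate")
    r <- stats::cor(x, v)
    if (!is.finite(r) || abs(r) < tol) "indeterminate"
    else if (r > 0) "positive" else "negative"
  }, "") -> out
  names(out) <- colnames(X)
  out
}

#' Ranked predictor report
#'
#' Per covariate domain, the top-k features by attribution value subject to
#' a floor on the mean absolute value, plus a global ranking. Ties are
#' broken alphabetically (stable).
#'
#' @param summary a data.frame with columns \code{feature} and a value
#'   column (\code{shap_value} by default).
#' @param domain_map named character vector mapping feature to domain
#'   (defaults to the codebook domains).
#' @param k top features per domain.
#' @param floor minimum mean absolute value to report.
#' @param value_col column of \code{summary} to rank on.
#' @return data.frame: \code{feature}, \code{domain}, \code{value},
#'   \code{rank_global}, \code{rank_domain}.
#' @export
rank_predictors <- function(summary, domain_map = NULL, k = 5, floor = 0.01,
                            value_col = "shap_value") {
  if (is.null(domain_map)) {
    cb <- covariate_codebook()
    domain_map <- stats::setNames(cb$domain, cb$name)
  }
  df <- data.frame(feature = summary$feature,
                   value = summary[[value_col]],
                   stringsAsFactors = FALSE)
  df$domain <- unname(domain_map[df$feature])
  df$domain[is.na(df$domain)] <- "other"
  df <- df[df$value >= floor, , drop = FALSE]
  if (!nrow(df)) {
    return(data.frame(feature = character(), domain = character(),
                      value = numeric(), rank_global = integer(),
                      rank_domain = integer(), stringsAsFactors = FALSE))
  }
  ord <- order(-xtfrm(df$value), df$feature)
  df <- df[ord, , drop = FALSE]
  df$rank_global <- seq_len(nrow(df))
  df$rank_domain <- stats::ave(seq_len(nrow(df)), df$domain,
                               FUN = seq_along)
  df <- df[df$rank_domain <= k, , drop = FALSE]
  rownames(df) <- NULL
  df
}
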