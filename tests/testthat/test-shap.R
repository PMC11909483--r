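lin_fun <- function(beta) function(M) drop(as.matrix(M) %*% beta)

test_that("kernel SHAP matches the linear-model closed form exactly", {
  set.seed(3)
  X <- matrix(rnorm(40 * 2), 40, 2, dimnames = list(NULL, c("x1", "x2")))
  f <- lin_fun(c(2, 3))
  ks <- kernel_shap(f, X)
  mu <- colMeans(X)
  expect_equal(ks$values[, "x1"], 2 * (X[, 1] - mu[1]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(ks$values[, "x2"], 3 * (X[, 2] - mu[2]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("exact enumeration equals brute-force permutation Shapley values", {
  set.seed(4)
  X <- matrix(rnorm(15 * 3), 15, 3, dimnames = list(NULL, paste0("x", 1:3)))
  f <- function(M) {
    M <- as.matrix(M)
    M[, 1] * M[, 2] + M[, 3] + 2 * M[, 1]   # interaction model
  }
  ks <- kernel_shap(f, X)
  bf <- brute_shapley(f, X)
  expect_equal(unname(ks$values), unname(bf), tolerance = 1e-8)

  # four features, nonlinear
  X4 <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(NULL, paste0("x", 1:4)))
  f4 <- function(M) {
    M <- as.matrix(M)
    sin(M[, 1]) + M[, 2] * M[, 3]^2 - exp(M[, 4] / 3)
  }
  ks4 <- kernel_shap(f4, X4)
  bf4 <- brute_shapley(f4, X4)
  expect_equal(unname(ks4$values), unname(bf4), tolerance = 1e-8)
})

test_that("local accuracy holds under exact enumeration and constants vanish", {
  set.seed(5)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, paste0("x", 1:6)))
  f <- function(M) {
    M <- as.matrix(M)
    M[, 1]^2 - M[, 2] * M[, 3] + tanh(M[, 4]) + M[, 5] - 0.5 * M[, 6]
  }
  ks <- kernel_shap(f, X)
  expect_lt(max(abs(rowSums(ks$values) - (ks$fx - ks$base))), 1e-6)
  # constant model: all-zero attribution, not an error
  kc <- kernel_shap(function(M) rep(1.5, nrow(as.matrix(M))), X)
  expect_true(all(abs(kc$values) < 1e-10))
})

test_that("mean-substitution values match the linear closed form and ignore unused features", {
  set.seed(6)
  X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, paste0("x", 1:3)))
  f <- lin_fun(c(-1.5, 0, 2))
  vals <- mean_substitution_shap(f, X)
  mu <- colMeans(X)
  expect_equal(vals[["x1"]], 1.5 * mean(abs(X[, 1] - mu[1])),
               tolerance = 1e-10)
  expect_equal(vals[["x2"]], 0)
  expect_equal(vals[["x3"]], 2 * mean(abs(X[, 3] - mu[3])),
               tolerance = 1e-10)

  # worked two-feature step model on a four-row table:
  # f = 1{x1 > 0.5} + 2 * 1{x2 > 0.5}; means are 0.5 so substitution
  # switches each indicator off; |f - f_sub| enumerated by hand
  X2 <- cbind(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1))
  ftree <- function(M) {
    M <- as.matrix(M)
    (M[, 1] > 0.5) + 2 * (M[, 2] > 0.5)
  }
  v2 <- mean_substitution_shap(ftree, X2)
  expect_equal(unname(v2), c(0.5, 1.0))
})

test_that("proportional SHAP is 100% for one feature and can exceed 100% in total", {
  set.seed(7)
  X1 <- matrix(rnorm(20), 20, 1, dimnames = list(NULL, "x1"))
  s1 <- shap_p(lin_fun(2), X1)
  expect_equal(s1$shap_p, 100)
  # symmetric two-feature binary design: each feature's substitution change
  # is 0.5 on every row while the whole-model change is |x1 + x2 - 1|,
  # also 0.5 on average -> each SHAP_P is 100%, summing to 200%
  X2 <- cbind(x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1))
  s2 <- shap_p(lin_fun(c(1, 1)), X2)
  expect_equal(s2$shap_p, c(100, 100))
  expect_gt(sum(s2$shap_p), 100)
  # unused feature scores zero
  X3 <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  s3 <- shap_p(lin_fun(c(1, 0)), X3)
  expect_equal(s3$shap_p[s3$feature == "x2"], 0)
  expect_error(shap_p(function(M) rep(1, nrow(as.matrix(M))), X3),
               "constant model")
})

test_that("SHAP_P is invariant to positive rescaling of the model", {
  set.seed(8)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, paste0("x", 1:3)))
  f <- function(M) { M <- as.matrix(M); M[, 1]^2 + 2 * M[, 2] - M[, 3] }
  s1 <- shap_p(f, X)
  s2 <- shap_p(function(M) 7 * f(M), X)
  expect_equal(s1$shap_p, s2$shap_p, tolerance = 1e-10)
})

test_that("dominant directions read sign from the attribution-feature correlation", {
  set.seed(9)
  X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("x1", "x2")))
  ks <- kernel_shap(lin_fun(c(2, -3)), X)
  dir <- dominant_direction(ks, X)
  expect_equal(unname(dir), c("positive", "negative"))
  # symmetric U-shape about the reference: indeterminate
  Xu <- matrix(seq(-2, 2, length.out = 41), ncol = 1,
               dimnames = list(NULL, "x1"))
  ku <- kernel_shap(function(M) as.matrix(M)[, 1]^2, Xu)
  expect_equal(unname(dominant_direction(ku, Xu)), "indeterminate")
})

test_that("predictor ranking applies the floor, the per-domain cap and the tie rule", {
  dm <- c(a1 = "d1", a2 = "d1", a3 = "d1", a4 = "d1", a5 = "d1", a6 = "d1",
          b1 = "d2", b2 = "d2")
  summ <- data.frame(feature = names(dm),
                     shap_value = c(0.6, 0.5, 0.4, 0.3, 0.2, 0.15,
                                    0.25, 0.005))
  rk <- rank_predictors(summ, dm, k = 5, floor = 0.01)
  # six qualifying features in domain d1: only five reported
  expect_equal(sum(rk$domain == "d1"), 5)
  # sub-floor feature dropped
  expect_false("b2" %in% rk$feature)
  # all values below the floor: empty report
  expect_equal(nrow(rank_predictors(
    data.frame(feature = "a1", shap_value = 0.001), dm)), 0)
  # ties break alphabetically
  summ2 <- data.frame(feature = c("zeta", "alpha", "mid"),
                      shap_value = c(0.3, 0.3, 0.5))
  rk2 <- rank_predictors(summ2, c(zeta = "d", alpha = "d", mid = "d"))
  expect_equal(rk2$feature, c("mid", "alpha", "zeta"))
})
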