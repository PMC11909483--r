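make_xy <- function(n, p = 5, beta = c(3, rep(0, 4)), sd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  list(X = X, y = drop(X %*% beta) + rnorm(n, 0, sd))
}

test_that("ensemble weights live on the simplex and satisfy the oracle inequality", {
  for (s in 1:5) {
    xy <- make_xy(300, seed = s, beta = rnorm(5, 0, s %% 3))
    sl <- fit_superlearner(xy$X, xy$y,
                           default_learners(c("mean", "lm", "ridge")),
                           folds = 5, seed = s)
    expect_true(all(sl$weights >= 0))
    expect_equal(sum(sl$weights), 1, tolerance = 1e-9)
    expect_lte(sl$ensemble_risk, min(sl$cv_risks) + 1e-8)
  }
})

test_that("a lone learner takes all the weight and a constant target goes to the mean", {
  xy <- make_xy(120)
  sl1 <- fit_superlearner(xy$X, xy$y, default_learners("mean")["mean"],
                          folds = 5, seed = 2)
  expect_equal(sl1$weights, 1)
  slc <- fit_superlearner(xy$X, rep(2, 120),
                          default_learners(c("mean", "lm")), folds = 5,
                          seed = 2)
  expect_equal(slc$weights[1], 1)
  expect_equal(unname(predict(slc, xy$X)[1]), 2)
  expect_error(fit_superlearner(xy$X[1:3, ], xy$y[1:3],
                                default_learners(c("mean", "lm")),
                                folds = 10), "folds")
})

test_that("a strong linear signal concentrates weight on the linear learner", {
  xy <- make_xy(2000, seed = 7)
  sl <- fit_superlearner(xy$X, xy$y, default_learners(c("mean", "lm")),
                         folds = 10, seed = 3)
  expect_gt(sl$weights[2], 0.9)
})

test_that("pure noise leaves the mean learner dominant and CV R^2 near zero", {
  set.seed(11)
  X <- matrix(rnorm(2000 * 5), 2000, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- rnorm(2000)
  lean <- default_learners(c("mean", "lm", "ridge"))
  sl <- fit_superlearner(X, y, lean, folds = 10, seed = 4)
  expect_equal(which.max(sl$weights), 1L)   # mean learner
  nc <- nested_cv_score(X, y, lean, 10, 10, seed = 5)
  expect_lt(abs(nc$cv_r2), 0.03)
})

test_that("a leaked copy of the target is caught by near-perfect CV R^2", {
  xy <- make_xy(300, seed = 21)
  Xl <- cbind(xy$X, leak = xy$y)
  nc <- nested_cv_score(Xl, xy$y, default_learners(c("mean", "lm")), 5, 5,
                        seed = 6)
  expect_gt(nc$cv_r2, 0.99)
})

test_that("permuting the target centers the CV R^2 distribution at or below zero", {
  xy <- make_xy(150, seed = 31, beta = c(1, rep(0, 4)))
  lean <- default_learners(c("mean", "lm"))
  set.seed(77)
  perm_r2 <- vapply(1:20, function(b) {
    nested_cv_score(xy$X, sample(xy$y), lean, 5, 5, seed = 100 + b)$cv_r2
  }, 0)
  expect_lt(mean(perm_r2), 0.02)
  expect_lt(stats::median(perm_r2), 0.01)
})

test_that("nested CV recovers the generator's configured weak signal", {
  lean <- default_learners(c("mean", "lm", "ridge"))
  vals <- vapply(1:3, function(s) {
    tr <- generate_trial(generator_config(n = 1319, seed = 300 + s,
                                          compliance_signal_r2 = 0.05))
    d <- analysis_frame(tr)
    sg <- d$arm == "self_guided"
    X <- as.matrix(d[sg, codebook_names()])
    y <- compliance_target(tr$usage)[sg]
    nested_cv_score(X, y, lean, 10, 10, seed = 400 + s)$cv_r2
  }, 0)
  expect_gte(mean(vals), 0.0)
  expect_lte(mean(vals), 0.12)
})

test_that("R^2 follows its definition including the degenerate cases", {
  expect_equal(r2(c(0, 1, 2), c(0, 0, 2)), 0.5)
  expect_equal(r2(1:10, 1:10), 1)
  y <- rnorm(20)
  expect_equal(r2(y, rep(mean(y), 20)), 0)
  expect_lt(r2(1:10, rep(100, 10)), 0)   # may be negative
  expect_error(r2(rep(1, 5), 1:5), "constant")
  expect_error(r2(1:3, 1:4), "equal length")
})

test_that("counterfactual scoring covers the cohort once with correct provenance", {
  tr <- small_trial()
  d <- analysis_frame(tr)
  sg <- d$arm == "self_guided"
  X <- as.matrix(d[, codebook_names()])
  y <- compliance_target(tr$usage)
  lean <- default_learners(c("mean", "lm"))
  oof <- nested_cv_score(X[sg, ], y[sg], lean, 5, 5, seed = 1,
                         ids = d$participant_id[sg])
  full <- fit_superlearner(X[sg, ], y[sg], lean, folds = 5, seed = 2)
  sc <- score_all(full, X, d$participant_id, oof)
  expect_equal(nrow(sc), nrow(d))
  expect_false(anyNA(sc$score))
  expect_false(any(duplicated(sc$participant_id)))
  # training-arm rows carry their out-of-fold scores verbatim
  expect_equal(sc$score[sg], unname(oof$scores[d$participant_id[sg]]))
  expect_true(all(sc$provenance[sg] == "out-of-fold"))
  expect_true(all(sc$provenance[!sg] == "full-model"))
  # identical covariate rows in non-training arms get identical scores
  i2 <- which(!sg)[1:2]
  X2 <- X
  X2[i2[2], ] <- X2[i2[1], ]
  sc2 <- score_all(full, X2, d$participant_id, oof)
  expect_equal(sc2$score[i2[1]], sc2$score[i2[2]])
  # schema mismatch names the offending columns
  expect_error(predict(full, X[, -3]),
               colnames(X)[3])
})
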