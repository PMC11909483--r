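test_that("nuisance fits handle full data, MCAR and positivity violations", {
  d <- small_frame()
  # no missingness: propensities exactly 1
  d1 <- d; d1$c3 <- 1L
  nf <- fit_nuisances(d1, "phq_ads_3", "c3")
  expect_true(all(nf$pc == 1))

  # MCAR 50% with intercept-only model: propensities near 0.5
  set.seed(12)
  d2 <- d
  d2$c3 <- rbinom(nrow(d2), 1, 0.5)
  d2$phq_ads_3 <- ifelse(d2$c3 == 1, small_trial()$outcomes$phq_ads_3, NA)
  nf2 <- fit_nuisances(d2, "phq_ads_3", "c3")
  expect_true(all(abs(nf2$pc - 0.5) < 0.12))

  # rigged near-zero completion cell is clipped at the bound and flagged
  set.seed(13)
  n <- 400
  z <- rep(c(0, 1), each = n / 2)
  comp <- ifelse(z == 1, rbinom(n, 1, 0.005), rbinom(n, 1, 0.9))
  comp[z == 1][1] <- 1   # at least one completer in the rare cell
  d3 <- data.frame(arm = factor(rep(c("guided", "self_guided", "tau"),
                                    length.out = n),
                                levels = c("guided", "self_guided", "tau")),
                   z = z, y = rnorm(n), c = comp)
  d3$y[d3$c == 0] <- NA
  nf3 <- suppressWarnings(
    fit_nuisances(d3, "y", "c", covars = "z", y_range = c(0, 48)))
  expect_true(nf3$flags$truncated)
  expect_true(all(nf3$pc >= nf3$bound))
})

test_that("with full data and intercept-only nuisances every estimator returns the arm mean exactly", {
  d <- analysis_frame(full_trial())
  raw <- 100 * tapply(d$remission_12, d$arm, mean)
  for (est in c("tmle", "aipw")) {
    fit <- dr_estimate(d, "remission_12", "c12", estimator = est)
    expect_equal(fit$estimates$value, as.vector(raw[fit$estimates$arm]),
                 tolerance = 1e-6)
  }
  fitm <- dr_estimate(d, "phq_ads_12", "c12")
  rawm <- tapply(d$phq_ads_12, d$arm, mean)
  expect_equal(fitm$estimates$value, as.vector(rawm[fitm$estimates$arm]),
               tolerance = 1e-6)
})

test_that("the augmented estimator matches a worked hand computation", {
  # eight rows: guided arm has two covariate cells with dropout; the other
  # arms are fully observed. Nuisances are hand-specified. The augmented
  # estimate for the guided arm is
  #   mean(Q) + (1/n) * sum over guided completers of (y - Q)/(g * pc)
  #   = 0.425 + (4 * 0.4 + 2.5 * (-0.2)) / 8 = 0.5625  -> 56.25%
  d <- data.frame(
    arm = factor(c("guided", "guided", "guided", "guided",
                   "self_guided", "self_guided", "tau", "tau"),
                 levels = c("guided", "self_guided", "tau")),
    y = c(1, NA, 0, NA, 1, 0, 1, 0),
    c = c(1L, 0L, 1L, 0L, 1L, 1L, 1L, 1L))
  Q <- cbind(guided = c(0.6, 0.6, 0.2, 0.2, 0.5, 0.5, 0.4, 0.4),
             self_guided = rep(0.5, 8), tau = rep(0.5, 8))
  nui <- structure(list(pc = c(0.5, 0.5, 0.8, 0.8, 1, 1, 1, 1), Q = Q,
                        y_range = c(0, 1), bound = 0.01,
                        covars = character(),
                        flags = list(truncated = FALSE)),
                   class = "nuisance_fits")
  fit <- dr_estimate(d, "y", "c", nuisances = nui, estimator = "aipw",
                     g_mode = "empirical")
  expect_equal(fit$estimates$value[fit$estimates$arm == "guided"], 56.25,
               tolerance = 1e-10)
})

test_that("remission estimates stay in [0,100] even under extreme weights", {
  for (s in 1:10) {
    set.seed(s)
    n <- 150
    d <- data.frame(
      arm = factor(sample(rep(c("guided", "self_guided", "tau"),
                              length.out = n)),
                   levels = c("guided", "self_guided", "tau")),
      w = rnorm(n))
    pr <- plogis(-2.5 + 2 * d$w)
    d$c <- rbinom(n, 1, pmax(pr, 0.02))
    # guarantee completers everywhere
    for (a in levels(d$arm)) {
      i <- which(d$arm == a)[1:2]
      d$c[i] <- 1L
    }
    d$y <- rbinom(n, 1, 0.3)
    d$y[d$c == 0] <- NA
    fit <- dr_estimate(d, "y", "c", covars = "w", bound = 0.01)
    expect_true(all(fit$estimates$value >= 0 & fit$estimates$value <= 100))
  }
})

test_that("the longitudinal estimator collapses exactly without partial follow-up", {
  d <- small_frame()
  # wave-1 completion implies wave-2 completion (and vice versa here)
  d$c12 <- d$c3
  d$phq_ads_12 <- ifelse(d$c12 == 1, small_trial()$outcomes$phq_ads_12, NA)
  d$remission_12 <- ifelse(
    d$c12 == 1,
    as.integer(small_trial()$outcomes$gad7_12 <= 4 &
                 small_trial()$outcomes$phq9_12 <= 4), NA)
  f1 <- dr_estimate(d, "phq_ads_12", "c12", covars = RICH_COVARS)
  f2 <- longitudinal_dr_estimate(d, "phq_ads_12", "phq_ads_3",
                                 covars = RICH_COVARS)
  expect_equal(f1$estimates$value, f2$estimates$value, tolerance = 1e-12)
  expect_equal(f1$estimates$se, f2$estimates$se, tolerance = 1e-12)
})

test_that("using 3-month data removes informative wave-2 dropout bias", {
  dm <- default_dropout_model()
  dm$wave2[["ads3"]] <- -0.10
  reps <- 40
  biases <- t(sapply(seq_len(reps), function(r) {
    tr <- generate_trial(generator_config(n = 2500, seed = 7000 + r,
                                          dropout_model = dm))
    d <- analysis_frame(tr)
    tru <- tr$truth$arm_means
    lvl <- tru$rem12[tru$arm == "self_guided"]
    f1 <- dr_estimate(d, "remission_12", "c12", covars = RICH_COVARS)
    f2 <- suppressWarnings(
      longitudinal_dr_estimate(d, "remission_12", "phq_ads_3",
                               covars = RICH_COVARS))
    c(f1$estimates$value[2] - lvl, f2$estimates$value[2] - lvl)
  }))
  expect_lt(abs(mean(biases[, 2])), abs(mean(biases[, 1])))
  # and the single-wave bias is real (several MC SEs from zero)
  expect_gt(abs(mean(biases[, 1])) /
              (sd(biases[, 1]) / sqrt(reps)), 2)
})

test_that("predictive mean matching imputes observed donor values", {
  # no 12-only rows: m identical copies
  d <- small_frame()
  d0 <- d[!(d$c3 == 0 & d$c12 == 1), ]
  mi0 <- impute_3mo_pmm(d0, m = 3, k = 2, seed = 1)
  expect_length(mi0, 3)
  expect_identical(mi0[[1]], d0)
  expect_identical(mi0[[2]], d0)

  # nearest-donor arithmetic: donor predictions {1, 2, 9, 5}, target 8.5
  mk_row <- function(id, c3, c12, x, a3, g12, p12) {
    data.frame(participant_id = id, c3 = c3, c12 = c12, x = x,
               gad7_3 = if (c3 == 1) round(a3 / 2) else NA,
               phq9_3 = if (c3 == 1) a3 - round(a3 / 2) else NA,
               phq_ads_3 = if (c3 == 1) a3 else NA,
               gad7_12 = g12, phq9_12 = p12)
  }
  dd <- rbind(mk_row("a", 1, 1, 1.0, 1, 3, 4),
              mk_row("b", 1, 1, 2.0, 2, 5, 2),
              mk_row("c", 1, 1, 9.0, 9, 4, 6),
              mk_row("d", 1, 1, 5.0, 5, 2, 3),
              mk_row("e", 0, 1, 8.5, NA, 3, 5))
  dd$gad7_3[dd$participant_id == "e"] <- NA
  mi <- impute_3mo_pmm(dd, covars = "x", m = 2, k = 1, seed = 4)
  for (j in 1:2) {
    expect_equal(mi[[j]]$phq_ads_3[5], 9)   # donor "c"'s observed value
    expect_equal(mi[[j]]$c3[5], 1L)
  }

  # property: imputed values always come from the observed donor set
  d1 <- d[d$c3 == 1 | d$c12 == 1, ]
  mi1 <- impute_3mo_pmm(d1, covars = c("gad7_0", "phq9_0"), m = 3, k = 5,
                        seed = 9)
  obs <- d1$phq_ads_3[d1$c3 == 1 & d1$c12 == 1]
  tgt <- which(d1$c3 == 0 & d1$c12 == 1)
  for (j in seq_along(mi1))
    expect_true(all(mi1[[j]]$phq_ads_3[tgt] %in% obs))
})

test_that("Rubin pooling combines within and between variance", {
  e1 <- adjusted_estimate("guided", 1, 1, wave = "3mo")
  e2 <- adjusted_estimate("guided", 3, 1, wave = "3mo")
  pooled <- pool_rubin(list(e1, e2))
  expect_equal(pooled$value, 2)
  expect_equal(pooled$se^2, 1 + 1.5 * 2)   # W + (1 + 1/m) B, B = var(1,3)
  # identical estimates: zero between-variance
  p2 <- pool_rubin(list(e1, e1))
  expect_equal(p2$value, e1$value)
  expect_equal(p2$se, e1$se)
  expect_error(pool_rubin(list(e1)), "at least 2")
  e3 <- adjusted_estimate("tau", 1, 1, wave = "3mo")
  expect_error(pool_rubin(list(e1, e3)), "estimands")
})

test_that("contrasts have the printed arithmetic, antisymmetry and 1 df", {
  a <- adjusted_estimate("guided", 50.3, 2.9, wave = "3mo")
  b <- adjusted_estimate("self_guided", 37.2, 2.9, wave = "3mo")
  cr <- contrast(a, b)
  expect_equal(cr$difference, 13.1, tolerance = 1e-12)
  expect_equal(cr$df, 1L)
  expect_equal(cr$chi2, (13.1 / sqrt(2 * 2.9^2))^2)
  # antisymmetry
  expect_equal(contrast(b, a)$difference, -cr$difference)
  expect_equal(contrast(b, a)$chi2, cr$chi2)
  # degenerate cases
  expect_equal(contrast(a, a)$chi2, 0)
  z <- adjusted_estimate("tau", 40, 0, wave = "3mo")
  z2 <- adjusted_estimate("guided", 41, 0, wave = "3mo")
  expect_error(contrast(z2, z), "zero contrast variance")
  expect_error(contrast(a, adjusted_estimate("tau", 1, 1, wave = "12mo")),
               "same wave")
})

test_that("the 2-df overall test is invariant to arm ordering", {
  v <- c(1, 0, 0)
  ot <- overall_test(v, diag(3))
  expect_equal(ot$chi2, 2 / 3, tolerance = 1e-12)
  expect_equal(ot$df, 2L)
  expect_equal(overall_test(c(5, 5, 5), diag(3))$chi2, 0)
  # permutations of the arms leave the statistic unchanged
  set.seed(2)
  V <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  x <- c(2, -1, 0.5)
  base_chi2 <- overall_test(x, V)$chi2
  for (pm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(overall_test(x[pm], V[pm, pm])$chi2, base_chi2,
                 tolerance = 1e-10)
  }
  expect_error(overall_test(c(1, 2, 3), matrix(1, 3, 3)), "singular")
})

test_that("Pearson chi-square matches the textbook formula", {
  res <- pearson_chi2(matrix(c(10, 5, 10, 15), 2))
  expect_equal(res$chi2, 8 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_equal(pearson_chi2(matrix(c(7, 7, 3, 3), 2))$chi2, 0)
  # oracle identity on a real completion-by-arm table
  d <- small_frame()
  tab <- table(d$arm, d$c3)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(pearson_chi2(tab)$chi2, sum((tab - E)^2 / E))
  expect_error(pearson_chi2(matrix(c(0, 0, 1, 2), 2)), "margins")
  expect_error(pearson_chi2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})
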