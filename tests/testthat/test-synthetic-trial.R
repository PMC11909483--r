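test_that("generated cohorts are eligible, sized and deterministic", {
  cfg <- generator_config(n = 400, seed = 99)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 400)
  expect_true(all(is_eligible(co$gad7_0, co$phq9_0)))
  expect_true(all(co$phq_ads_0 == co$gad7_0 + co$phq9_0))
  expect_false(any(duplicated(co$participant_id)))
  # female fraction within binomial error of the target
  p_hat <- mean(co$female)
  expect_lt(abs(p_hat - 0.787), 4 * sqrt(0.787 * 0.213 / 400))
  # determinism
  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)
  # empty cohort
  co0 <- generate_cohort(generator_config(n = 0, seed = 1))
  expect_equal(nrow(co0), 0)
})

test_that("block randomization balances arms within every stratum", {
  # complete blocks: 6 identical-stratum participants, block size 3
  mini <- data.frame(participant_id = paste0("P", 1:6),
                     sex = "female", gad7_0 = 12L, phq9_0 = 12L)
  asg <- block_randomize(mini, generator_config(n = 6, seed = 5,
                                                block_size = 3L))
  expect_equal(as.vector(table(asg$arm)), c(2L, 2L, 2L))

  tr <- small_trial()
  tab <- table(tr$arms$stratum, tr$arms$arm)
  # within each stratum arm counts differ by at most one incomplete block
  imbalance <- apply(tab, 1, function(r) diff(range(r)))
  expect_true(all(imbalance <= 1))
  # per-arm totals close to n/3 (bounded by one unit per nonempty stratum)
  tot <- colSums(tab)
  expect_true(all(abs(tot - nrow(tr$cohort) / 3) <= sum(rowSums(tab) > 0)))

  # permuting input order leaves per-stratum arm counts unchanged
  cfg <- generator_config(n = 300, seed = 17)
  co <- generate_cohort(cfg)
  a1 <- block_randomize(co, cfg)
  perm <- rev(seq_len(nrow(co)))
  a2 <- block_randomize(co[perm, ], cfg)
  expect_equal(table(a1$stratum, a1$arm), table(a2$stratum, a2$arm))
})

test_that("usage is zero for TAU, nonnegative, and reverses across periods", {
  tr <- small_trial()
  m <- as.matrix(tr$usage[, paste0("week_", 1:52)])
  expect_true(all(m >= 0))
  expect_true(all(m[tr$arms$arm == "tau", ] == 0))
  g <- tr$arms$arm == "guided"; s <- tr$arms$arm == "self_guided"
  expect_gt(mean(m[g, 1:12]), mean(m[s, 1:12]))
  expect_lt(mean(m[g, 13:52]), mean(m[s, 13:52]))
})

test_that("default usage profiles reproduce the calibration targets", {
  tr <- generate_trial(generator_config(n = 4000, seed = 1234))
  m <- as.matrix(tr$usage[, paste0("week_", 1:52)])
  g <- tr$arms$arm == "guided"; s <- tr$arms$arm == "self_guided"
  expect_lt(abs(mean(m[g, 1:12]) - 12.5) / 12.5, 0.15)
  expect_lt(abs(mean(m[s, 1:12]) - 5.9) / 5.9, 0.15)
  # post-guidance means on the right order (0.2 vs 0.4 minutes/week)
  expect_lt(abs(mean(m[g, 13:52]) - 0.2), 0.1)
  expect_lt(abs(mean(m[s, 13:52]) - 0.4), 0.2)
})

test_that("switching off weekly activity yields an all-zero usage matrix", {
  prof <- default_usage_profiles()
  for (a in c("guided", "self_guided"))
    for (p in c("early", "late")) prof[[a]][[p]]["p"] <- 0
  cfg <- generator_config(n = 100, seed = 3, arm_usage_profiles = prof)
  co <- generate_cohort(cfg)
  arms <- block_randomize(co, cfg)
  u <- simulate_usage(co, arms, cfg)
  expect_true(all(as.matrix(u[, paste0("week_", 1:52)]) == 0))
})

test_that("a null effect map gives identical outcome distributions per arm", {
  em0 <- null_effect_map()
  cfg <- generator_config(n = 3000, seed = 21, effect_map = em0)
  tr <- generate_trial(cfg)
  tru <- tr$truth$arm_means
  # true potential remission rates coincide up to rounding interactions
  expect_lt(diff(range(tru$rem12)), 0.75)
  expect_lt(diff(range(tru$ads12)), 0.25)
  # observed rates equal within Monte-Carlo error
  d <- analysis_frame(tr)
  cc <- d$c12 == 1
  tab <- table(d$arm[cc], d$remission_12[cc])
  expect_gt(pearson_chi2(tab)$p, 0.001)
})

test_that("the trajectory model has the configured closed form when noiseless", {
  em <- default_effect_map()
  em$wave3$sd <- 0; em$wave12$sd <- 0
  em$wave3$beta_usage <- 0; em$wave12$beta_usage <- 0
  em$wave3$tau[] <- 0; em$wave12$tau[] <- 0
  prof <- default_usage_profiles()
  for (a in c("guided", "self_guided"))
    for (p in c("early", "late")) prof[[a]][[p]]["p"] <- 0
  cfg <- generator_config(n = 1, seed = 8, arm_usage_profiles = prof,
                          effect_map = em)
  co <- generate_cohort(cfg)
  arms <- block_randomize(co, cfg)
  u <- simulate_usage(co, arms, cfg)
  oc <- simulate_outcomes(co, arms, u, cfg)
  expect_equal(oc$phq_ads_3,
               round(min(max(2.7 + 0.45 * co$phq_ads_0, 0), 48)))
  expect_equal(oc$phq_ads_12,
               round(min(max(3.5 + 0.50 * co$phq_ads_0, 0), 48)))
})

test_that("missingness patterns behave as constructed", {
  # no dropout
  tr0 <- full_trial()
  expect_true(all(tr0$completion$c3 == 1 & tr0$completion$c12 == 1))

  # all four observable patterns occur and TAU has the highest joint rate
  tr <- generate_trial(generator_config(n = 5000, seed = 55))
  cp <- tr$completion
  pat <- table(paste0(cp$c3, cp$c12))
  expect_setequal(names(pat), c("00", "01", "10", "11"))
  joint <- tapply(cp$c3 & cp$c12, tr$arms$arm, mean)
  expect_true(joint["tau"] > joint["guided"])
  expect_true(joint["tau"] > joint["self_guided"])

  # wave-2-only outcome dependence: wave 1 is MCAR, wave 2 tracks the
  # observed 3-month score
  dm <- list(wave1 = c(intercept = 0.8, guided = 0, self_guided = 0,
                       tau = 0, mexico = 0, waitlist = 0, clinic_campus = 0,
                       severe = 0),
             wave2 = c(intercept = 0.5, guided = 0, self_guided = 0,
                       tau = 0, mexico = 0, waitlist = 0, clinic_campus = 0,
                       severe = 0, prev_complete = 0, ads3 = -0.1))
  tr2 <- generate_trial(generator_config(n = 4000, seed = 66,
                                         dropout_model = dm))
  d2 <- analysis_frame(tr2)
  # wave 1 independent of baseline severity
  expect_gt(pearson_chi2(table(d2$severe_baseline, d2$c3))$p, 0.01)
  # wave 2 depends on the 3-month score among wave-1 completers
  cc <- d2$c3 == 1
  expect_lt(stats::t.test(tr2$outcomes$phq_ads_3[cc] ~ d2$c12[cc])$p.value,
            1e-6)
})

test_that("trial generation is reproducible bit for bit under a fixed seed", {
  cfg <- generator_config(n = 250, seed = 77)
  t1 <- generate_trial(cfg)
  t2 <- generate_trial(cfg)
  expect_identical(t1$usage, t2$usage)
  expect_identical(t1$followup, t2$followup)
  expect_identical(t1$truth$potential, t2$truth$potential)
})

test_that("ground-truth contrasts reflect the configured effect direction", {
  tr <- generate_trial(generator_config(n = 5000, seed = 88))
  tm <- tr$truth$arm_means
  # guidance helps most at 3 months; self-guided persistence wins at 12
  expect_gt(tm$rem3[tm$arm == "guided"], tm$rem3[tm$arm == "self_guided"])
  expect_gt(tm$rem3[tm$arm == "guided"], tm$rem3[tm$arm == "tau"])
  expect_gt(tm$rem12[tm$arm == "self_guided"], tm$rem12[tm$arm == "guided"])
  expect_gt(tm$rem12[tm$arm == "self_guided"], tm$rem12[tm$arm == "tau"])
})
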