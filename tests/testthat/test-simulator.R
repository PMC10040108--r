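test_that("ages are uniform within four equal-probability classes", {
  cfg <- scenario_preset("breast", alpha = 1, n = 1e5)
  set.seed(301)
  age <- sample_ages(cfg)
  expect_true(all(age >= 40 & age < 75))
  br <- cfg$age_breaks
  freq <- table(cut(age, br, right = FALSE)) / length(age)
  expect_true(all(abs(freq - 0.25) < 0.005))
  # determinism
  set.seed(301)
  expect_identical(sample_ages(cfg), age)
})

test_that("censoring mixes uniform draws with the registry horizon", {
  base <- scenario_preset("breast", alpha = 1, n = 1e5)
  none <- scenario_preset("breast", alpha = 1, n = 1000, p_ac = 0, p_lf = 0)
  set.seed(302)
  expect_true(all(sample_censoring_time(none) == 15))
  all_ac <- scenario_preset("breast", alpha = 1, n = 1e5, p_ac = 1, p_lf = 0)
  tc <- sample_censoring_time(all_ac)
  expect_lt(abs(mean(tc) - 7.5), 0.05)
  # P(T_C = horizon) = (1 - p_ac)(1 - p_lf)
  tc2 <- sample_censoring_time(base)
  expect_lt(abs(mean(tc2 == 15) - 0.5 * 0.97), 0.005)
})

test_that("cancer death times invert the mixture by inverse transform", {
  cfg <- scenario_preset("breast", alpha = 1.2, n = 10)
  # a draw below the cure fraction is cured
  expect_identical(sample_cancer_death_time(cfg, 0, u = 0.5), Inf)
  # arithmetic oracle: solve exp(-0.1 t^1.1) = (0.9 - 0.7) / 0.3
  t9 <- sample_cancer_death_time(cfg, 0, u = 0.9)
  expect_equal(t9, (-log(2 / 3) / 0.1)^(1 / 1.1), tolerance = 1e-12)
  expect_equal(round(t9, 3), 3.57)
  expect_equal(exp(-0.1 * t9^1.1), 0.2 / 0.3, tolerance = 1e-12)
  # uncured draws at x = 0 follow S_u (Kolmogorov distance at 1e5)
  set.seed(303)
  tt <- sample_cancer_death_time(cfg, rep(0, 1e5))
  unc <- tt[is.finite(tt)]
  expect_lt(abs(mean(is.infinite(tt)) - 0.7), 3 * sqrt(0.7 * 0.3 / 1e5))
  expect_lt(ks_distance(unc, function(t) uncured_survival(BREAST, t)), 0.01)
  # age convention: delta < 0 means older uncured patients die faster
  cfgl <- scenario_preset("lung", alpha = 2, n = 10)
  u <- 0.95
  t_old <- sample_cancer_death_time(cfgl, 1, u = u)
  t_ref <- sample_cancer_death_time(cfgl, 0, u = u)
  expect_lt(t_old, t_ref)
  # exponentiated-Weibull generation matches its closed-form survival
  cfge <- scenario_preset("lung", alpha = 2, n = 10, theta = 4)
  set.seed(304)
  te <- sample_cancer_death_time(cfge, rep(0, 1e5))
  expect_lt(ks_distance(te[is.finite(te)],
                        function(t) exp_weibull_survival(t, 0.9, 0.8, 4)), 0.01)
})

test_that("age-dependent alpha follows the linear trend and is validated", {
  cfg <- scenario_preset("breast", alpha = 1.2, n = 10, b_alpha = -0.02,
                         age_center = 62.5)
  expect_equal(alpha_for_age(cfg, c(40, 75)), c(1.65, 0.95), tolerance = 1e-12)
  cfg2 <- scenario_preset("lung", alpha = 2, n = 10, b_alpha = -0.08,
                          age_center = 62.5)
  expect_equal(alpha_for_age(cfg2, c(40, 75)), c(3.80, 1.00), tolerance = 1e-12)
  expect_equal(alpha_for_age(scenario_preset("lung", alpha = 2, n = 10), 52), 2)
  expect_error(scenario_preset("lung", alpha = 1, n = 10, b_alpha = -0.1),
               "non-positive")
})

test_that("random alpha is log-uniform with mean-preserving bounds", {
  expect_equal(random_alpha_bounds(1.2, 2), c(0.832, 1.664), tolerance = 1e-3)
  expect_equal(random_alpha_bounds(2, 2), c(1.386, 2.773), tolerance = 1e-3)
  expect_equal(random_alpha_bounds(2, 4), c(0.924, 3.697), tolerance = 1e-3)
  expect_equal(random_alpha_bounds(1.7, 1), c(1.7, 1.7))
  expect_error(random_alpha_bounds(1.2, 0.5), "ratio must be")
  b <- random_alpha_bounds(1.2, 3)
  set.seed(305)
  draws <- exp(runif(1e6, log(b[1]), log(b[2])))
  expect_lt(abs(mean(draws) - 1.2), 0.002)
})

test_that("cohorts are reproducible and carry the designed structure", {
  cfg <- scenario_preset("breast", alpha = 1.2, n = 2000)
  c1 <- generate_cohort(cfg, seed = 306)
  expect_identical(c1, generate_cohort(cfg, seed = 306))
  expect_named(c1, c("id", "age", "x", "time", "event"))
  expect_true(all(c1$time >= 0 & c1$time <= 15))
  expect_true(all(c1$event %in% 0:1))
  expect_equal(c1$x, (c1$age - 60) / 15)
  # null robustness settings reduce exactly to the base generator
  cfg_null <- scenario_preset("breast", alpha = 1.2, n = 2000, theta = 1,
                              b_alpha = 0, alpha_ratio = 1)
  expect_identical(generate_cohort(cfg_null, seed = 306), c1)
  # provenance columns appear only on request
  ct <- generate_cohort(cfg, seed = 306, keep_truth = TRUE)
  expect_true(all(c("true_cured", "cause") %in% names(ct)))
  expect_identical(ct[names(c1)], c1)
})

test_that("the latent cure indicator has probability pi(x)", {
  cfg <- scenario_preset("breast", alpha = 1.2, n = 1e5)
  ct <- generate_cohort(cfg, seed = 307, keep_truth = TRUE)
  near60 <- abs(ct$age - 60) < 2
  p_hat <- mean(ct$true_cured[near60])
  p_the <- mean(cure_fraction(BREAST, ct$x[near60]))
  expect_lt(abs(p_hat - p_the), 3 * sqrt(p_the * (1 - p_the) / sum(near60)))
})

test_that("a huge excess-mortality ratio kills essentially everyone", {
  cfg <- scenario_preset("breast", alpha = 1000, n = 10000, p_ac = 0, p_lf = 0)
  coh <- generate_cohort(cfg, seed = 308)
  expect_gt(mean(coh$event), 0.999)
  expect_lt(mean(coh$time), 2)
})

test_that("the empirical relative-survival plateau matches the closed form", {
  cfg <- scenario_preset("breast", alpha = 1, n = 1e5)
  coh <- generate_cohort(cfg, seed = 309)
  lt <- build_life_table(coh, cfg$pop)
  rs <- relative_survival_table(lt)
  # middle stratum (ages 58-64): Ederer II RS at 15 y vs pi + (1 - pi) S_u
  s2 <- rs[rs$stratum == "[58,65)", ]
  x2 <- lt$x[lt$stratum == "[58,65)"][1]
  p1 <- cure_params(alpha = 1, pi60 = 0.7, beta = -0.15, lambda = 0.1, gamma = 1.1)
  expect_lt(abs(s2$cum_rs[s2$t_end == 15] - net_survival(p1, 15, x2)), 0.02)
})

test_that("shorter analysis horizons truncate the same underlying cohort", {
  cfg15 <- scenario_preset("lung", alpha = 2, n = 3000)
  cfg5 <- scenario_preset("lung", alpha = 2, n = 3000, max_followup = 5)
  c15 <- generate_cohort(cfg15, seed = 310)
  c5 <- generate_cohort(cfg5, seed = 310)
  expect_true(all(c5$time <= 5))
  manual <- c15
  manual$event[manual$time > 5] <- 0L
  manual$time <- pmin(manual$time, 5)
  expect_identical(c5, manual)
})

test_that("conflicting robustness violations are rejected up front", {
  expect_error(scenario_preset("lung", alpha = 2, n = 10, theta = 4,
                               alpha_ratio = 2), "at most one")
  expect_error(scenario_preset("breast", alpha = 1.2, n = 10, b_alpha = 0.01,
                               theta = 2), "at most one")
})
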