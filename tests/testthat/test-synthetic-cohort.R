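test_that("identical configs produce bit-identical cohorts", {
  cfg <- default_config_frele(n_subjects = 400)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 999)
  expect_false(identical(a$exhaustion, c2$exhaustion))
})

test_that("config validation names the offending field", {
  cfg <- default_config_frele(n_subjects = 100)
  bad <- cfg
  bad$mixing <- c(0.5, 0.5)
  expect_error(validate_cohort_config(bad), "mixing")
  bad <- cfg
  bad$residual_variances[2, 3] <- -1
  expect_error(validate_cohort_config(bad), "residual_variances")
  bad <- cfg
  bad$factor_variances <- rep(0, 4)
  expect_error(validate_cohort_config(bad), "factor_variances")
  expect_error(
    cohort_config(n_subjects = 50, K_true = 2, mixing = c(0.4, 0.6),
                  intercepts = matrix(0, 3, 4), loadings = rep(1, 4),
                  factor_means = c(0, 1), factor_variances = c(1, 1),
                  residual_variances = matrix(1, 2, 4),
                  gait_censor_floor = 0,
                  weightloss_occurrence_logit = c(-2, -2),
                  weightloss_magnitude_mean_kg = c(5, 5),
                  weightloss_magnitude_sd_kg = c(2, 2)),
    "intercepts")
})

test_that("noise-free limit reproduces class means and classes exactly", {
  K <- 3
  cfg <- cohort_config(
    n_subjects = 300, K_true = K, mixing = c(0.3, 0.4, 0.3),
    intercepts = matrix(rep(c(10, 50, 90), 4), K, 4),
    loadings = rep(0, 4),
    factor_means = rep(0, K), factor_variances = rep(1e-12, K) + 1e-12,
    residual_variances = matrix(1e-12, K, 4),
    gait_censor_floor = -100,
    weightloss_occurrence_logit = rep(-30, K),
    weightloss_magnitude_mean_kg = rep(5, K),
    weightloss_magnitude_sd_kg = rep(1, K),
    sex_ratio = 0, sex_shift = rep(0, 4), seed = 5)
  cohort <- generate_cohort(cfg)
  for (c in 1:4) {
    comp <- cohort[[c(
      "exhaustion", "physical_activity", "grip_strength", "gait_speed")[c]]]
    expect_equal(comp, cfg$intercepts[cohort$true_class, c], tolerance = 1e-5)
  }
  # modal recovery by nearest class mean is perfect
  recovered <- apply(abs(outer(cohort$exhaustion, c(10, 50, 90), `-`)), 1,
                     which.min)
  expect_identical(recovered, cohort$true_class)
})

test_that("a one-class cohort matches its analytic means within 3 SEs", {
  cfg <- fixture_configs(n_subjects = 4000)$one_class
  cohort <- generate_cohort(cfg, seed = 21)
  mu <- analytic_component_means(cfg)
  comps <- cbind(cohort$exhaustion, cohort$physical_activity,
                 cohort$grip_strength, cohort$gait_speed)
  for (c in 1:4) {
    x <- comps[, c]
    if (c == 4) x <- x[!cohort$gait_censored]
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - mu[1, c]), 3.5 * se + 0.2)
  }
})

test_that("per-class means of the default cohort match the analytic means", {
  cfg <- default_config_frele(n_subjects = 5000)
  cohort <- generate_cohort(cfg, seed = 31)
  mu <- analytic_component_means(cfg)
  for (k in 2:4) {          # class 1 holds only ~2.7% of subjects
    sel <- cohort$true_class == k & !cohort$gait_censored
    for (c in 1:4) {
      x <- switch(c, cohort$exhaustion, cohort$physical_activity,
                  cohort$grip_strength, cohort$gait_speed)[sel]
      se <- stats::sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - mu[k, c]), 4 * se + 0.3)
    }
  }
})

test_that("per-class covariance of components matches F psi F' + Theta", {
  cfg <- default_config_frele(n_subjects = 12000, sex_shift = 0)
  cohort <- generate_cohort(cfg, seed = 41)
  for (k in c(3, 4)) {
    sel <- cohort$true_class == k & !cohort$gait_censored
    Y <- cbind(cohort$exhaustion, cohort$physical_activity,
               cohort$grip_strength, cohort$gait_speed)[sel, ]
    S <- stats::cov(Y)
    Sig <- cfg$factor_variances[k] * outer(cfg$loadings, cfg$loadings) +
      diag(cfg$residual_variances[k, ])
    nk <- sum(sel)
    for (i in 1:4) for (j in 1:4) {
      mc_se <- sqrt((Sig[i, j]^2 + Sig[i, i] * Sig[j, j]) / nk)
      expect_lt(abs(S[i, j] - Sig[i, j]), 5 * mc_se)
    }
  }
})

test_that("gait censoring frequency matches the analytic normal tail", {
  cfg <- default_config_frele(n_subjects = 20000, sex_shift = 0)
  cohort <- generate_cohort(cfg, seed = 51)
  sd_g <- sqrt(cfg$loadings[4]^2 * cfg$factor_variances +
                 cfg$residual_variances[, 4])
  mu_g <- cfg$intercepts[, 4] + cfg$loadings[4] * cfg$factor_means
  p <- sum(cfg$mixing * stats::pnorm((cfg$gait_censor_floor - mu_g) / sd_g))
  obs <- mean(cohort$gait_censored)
  mc_se <- sqrt(p * (1 - p) / nrow(cohort))
  expect_lt(abs(obs - p), 5 * mc_se)
})

test_that("the default configuration encodes the published study conditions", {
  cfg <- default_config_frele()
  expect_equal(cfg$loadings[1], 1.00)
  expect_equal(cfg$loadings, c(1.00, 4.10, 1.21, 2.17))
  expect_equal(cfg$intercepts[1, ], cfg$intercepts[4, ])  # strong invariance
  # no class has expected count below 25 at the study n
  expect_true(all(1643 * cfg$mixing >= 25))
  # marginal weight-loss occurrence is approximately the 13% prevalence
  marg <- sum(cfg$mixing * stats::plogis(cfg$weightloss_occurrence_logit))
  expect_gt(marg, 0.10)
  expect_lt(marg, 0.15)
})

test_that("cohort and config round-trip through their text formats", {
  cfg <- default_config_frele(n_subjects = 60)
  p1 <- tempfile(fileext = ".json")
  write_config(cfg, p1)
  expect_equal(read_config(p1), cfg)
  cohort <- generate_cohort(cfg)
  p2 <- tempfile(fileext = ".csv")
  write_cohort(cohort, p2)
  back <- read_cohort(p2)
  expect_equal(back$exhaustion, cohort$exhaustion)
  expect_equal(back$weight_lost_kg, cohort$weight_lost_kg)
  expect_identical(attr(back, "gait_floor"), attr(cohort, "gait_floor"))
  unlink(c(p1, p2))
})

test_that("fixture configs cover the three study shapes", {
  f <- fixture_configs(n_subjects = 200)
  expect_named(f, c("one_class", "three_class_lca", "four_class_somi"))
  expect_equal(f$one_class$K_true, 1L)
  expect_equal(f$three_class_lca$K_true, 3L)
  expect_true(all(f$three_class_lca$loadings == 0))
  expect_equal(f$four_class_somi$K_true, 4L)
  for (cfg in f) expect_s3_class(generate_cohort(cfg), "frail_cohort")
})
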