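test_that("BIC differences follow the penalty arithmetic", {
  p <- tiny_gaussian_params(K = 2, M = 4, sep = 6)
  it <- gaussian_items(300, p, seed = 1)
  f_ev <- fit_fmm(it, fmm_spec("LCA", 2, "ev", it), n_starts = 4, seed = 2)
  expect_equal(bic_difference(f_ev, f_ev), 0)
  # a model with extra parameters and (essentially) the same loglik is
  # penalized by ln n per parameter
  f_uv <- fit_fmm(it, fmm_spec("LCA", 2, "uv", it), n_starts = 4, seed = 2)
  extra <- f_uv$n_params - f_ev$n_params
  dll <- f_uv$loglik - f_ev$loglik
  expect_equal(bic_difference(f_uv, f_ev),
               extra * log(300) - 2 * dll, tolerance = 1e-8)
  f_small <- fit_fmm(gaussian_items(200, p, seed = 3),
                     fmm_spec("LCA", 2, "ev", it), n_starts = 2, seed = 2)
  expect_error(bic_difference(f_ev, f_small), "different n")
})

test_that("uv is favoured over ev on uv-generated data", {
  p_uv <- fmm_params(pi = c(0.5, 0.5),
                     intercept = rbind(rep(0, 4), rep(5, 4)),
                     loading = matrix(0, 2, 4),
                     resid = rbind(rep(0.6, 4), rep(3.5, 4)),
                     alpha = c(0, 0), psi = rep(NA_real_, 2),
                     item_models = rep("gaussian", 4))
  wins <- 0L
  for (r in 1:10) {
    it <- simulate_fmm(p_uv, 600, seed = 40 + r)
    f_uv <- fit_fmm(it, fmm_spec("LCA", 2, "uv", it), n_starts = 3,
                    seed = r)
    f_ev <- fit_fmm(it, fmm_spec("LCA", 2, "ev", it), n_starts = 3,
                    seed = r)
    if (bic_difference(f_uv, f_ev) < 0) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("the bootstrap test is exact in its trivial corners", {
  p <- tiny_gaussian_params(K = 2, M = 4, sep = 7)
  it <- gaussian_items(250, p, seed = 6)
  sp2 <- fmm_spec("LCA", 2, "uv", it)
  sp1 <- fmm_spec("LCA", 1, "uv", it)
  # alternative equal to null: LRT ~ 0 and p ~ 1
  b0 <- blrt(it, sp1, sp1, B = 9, n_starts = 2, boot_starts = 1, seed = 7)
  expect_lt(abs(b0$lrt_observed), 1e-4)
  expect_gt(b0$p_value, 0.5)
  # strongly separated two-class data against a one-class null: every
  # bootstrap statistic falls below the observed one
  b1 <- blrt(it, sp2, sp1, B = 49, n_starts = 3, boot_starts = 1, seed = 8)
  expect_equal(b1$p_value, 1 / (b1$B_used + 1))
  expect_true(b1$nested)
  expect_true(all(b1$bootstrap_lrts < b1$lrt_observed))
  # p-value bounds
  expect_gte(b1$p_value, 1 / (b1$B + 1))
  expect_lte(b1$p_value, 1)
})

test_that("identical seeds reproduce the bootstrap statistics bit for bit", {
  p <- tiny_gaussian_params(K = 2, M = 4, sep = 6)
  it <- gaussian_items(200, p, seed = 9)
  sp2 <- fmm_spec("LCA", 2, "uv", it)
  sp1 <- fmm_spec("LCA", 1, "uv", it)
  a <- blrt(it, sp2, sp1, B = 15, n_starts = 2, boot_starts = 1, seed = 123)
  b <- blrt(it, sp2, sp1, B = 15, n_starts = 2, boot_starts = 1, seed = 123)
  expect_identical(a$bootstrap_lrts, b$bootstrap_lrts)
  expect_identical(a$p_value, b$p_value)
})

test_that("early stopping never changes a rejection decision", {
  p <- tiny_gaussian_params(K = 1, M = 4)
  it <- gaussian_items(250, p, seed = 10)
  sp2 <- fmm_spec("LCA", 2, "uv", it)
  sp1 <- fmm_spec("LCA", 1, "uv", it)
  full <- blrt(it, sp2, sp1, B = 19, n_starts = 2, boot_starts = 1,
               seed = 11)
  quick <- blrt(it, sp2, sp1, B = 19, n_starts = 2, boot_starts = 1,
                seed = 11, alpha_stop = 0.05)
  expect_identical(quick$reject, full$p_value <= 0.05)
})

test_that("Monte Carlo diagnostics behave at a well-specified simple model", {
  p1 <- fmm_params(pi = 1, intercept = matrix(c(10, 20, 30, 40, 50), 1, 5),
                   loading = matrix(0, 1, 5),
                   resid = matrix(c(4, 9, 16, 4, 9), 1, 5),
                   alpha = 0, psi = NA_real_,
                   item_models = rep("gaussian", 5))
  sp <- fmm_spec("LCA", 1, "ev", rep("gaussian", 5))
  expect_error(monte_carlo_diagnostics(p1, sp, n = 100, R = 1), "R must be")
  diag <- monte_carlo_diagnostics(p1, sp, n = 1200, R = 100, seed = 21,
                                  n_starts = 1)
  expect_true(all(abs(diag$rel_bias_pct) < 2, na.rm = TRUE))
  # per-parameter coverage carries binomial noise sd ~2.2% at R = 100
  expect_true(all(diag$coverage95 > 0.87 & diag$coverage95 < 0.995))
  expect_gt(mean(diag$coverage95), 0.91)
  expect_lt(mean(diag$coverage95), 0.985)
  # power against zero for parameters far from zero is essentially 1
  expect_true(all(diag$power[grepl("^I\\.", diag$parameter)] > 0.99))
  # SE-bias estimates carry ~7% noise at R = 100, so an occasional flag on
  # one of ten parameters is expected; systematic flagging is not
  expect_lte(sum(diag$se_bias_flag), 2L)
  expect_lt(mean(abs(diag$se_bias_pct)), 8)
})

test_that("misspecified refits raise diagnostic flags", {
  p_uv <- fmm_params(pi = c(0.5, 0.5),
                     intercept = rbind(rep(0, 4), rep(6, 4)),
                     loading = matrix(0, 2, 4),
                     resid = rbind(rep(1, 4), rep(6, 4)),
                     alpha = c(0, 0), psi = rep(NA_real_, 2),
                     item_models = rep("gaussian", 4))
  # refit under the equal-variance constraint: the pooled variance cell
  # cannot cover either class's true value
  sp_ev <- fmm_spec("LCA", 2, "ev", rep("gaussian", 4))
  diag <- monte_carlo_diagnostics(p_uv, sp_ev, n = 600, R = 20, seed = 31,
                                  n_starts = 3)
  bad <- diag[grepl("^th\\.", diag$parameter), ]
  expect_true(min(bad$coverage95) < 0.5 ||
                max(abs(bad$rel_bias_pct), na.rm = TRUE) > 10)
})

test_that("model standard errors agree with replication SDs at large n", {
  p1 <- fmm_params(pi = 1, intercept = matrix(c(0, 5, 10, 15, 20), 1, 5),
                   loading = matrix(0, 1, 5),
                   resid = matrix(2, 1, 5),
                   alpha = 0, psi = NA_real_,
                   item_models = rep("gaussian", 5))
  sp <- fmm_spec("LCA", 1, "ev", rep("gaussian", 5))
  diag <- monte_carlo_diagnostics(p1, sp, n = 4000, R = 40, seed = 41,
                                  n_starts = 1)
  # the replication SD itself has ~11% relative noise at R = 40
  expect_lt(stats::median(abs(diag$se_bias_pct)), 15)
  expect_true(all(abs(diag$se_bias_pct) < 35, na.rm = TRUE))
})

test_that("the comparison ledger records one decision per pair", {
  p <- tiny_gaussian_params(K = 2, M = 4, sep = 6)
  it <- gaussian_items(300, p, seed = 51)
  f2 <- fit_fmm(it, fmm_spec("LCA", 2, "uv", it), n_starts = 3, seed = 1)
  f1 <- fit_fmm(it, fmm_spec("LCA", 1, "uv", it), n_starts = 1, seed = 1)
  b <- blrt(it, f2$spec, f1$spec, B = 19, boot_starts = 1, seed = 3,
            fit_alt = f2, fit_null = f1)
  led <- compare_family(list(list(label = "2 vs 1", kind = "class-count",
                                  fit_alt = f2, fit_null = f1, blrt = b)))
  expect_s3_class(led, "comparison_ledger")
  expect_equal(nrow(led), 1L)
  expect_true(led$reject_null)
  expect_match(led$rationale, "BIC diff")
  empty <- compare_family(list())
  expect_equal(nrow(empty), 0L)
})
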