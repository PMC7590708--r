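test_that("zero-loading one-class model is a sum of univariate normals", {
  p <- tiny_gaussian_params(K = 1, M = 4)
  it <- gaussian_items(30, p, seed = 2)
  direct <- sum(stats::dnorm(it$y, mean = 0, sd = 1, log = TRUE))
  expect_equal(fmm_loglik(p, it), direct, tolerance = 1e-10)
})

test_that("the likelihood matches brute-force factor integration", {
  # small gaussian two-class factor model
  p <- fmm_params(pi = c(0.4, 0.6),
                  intercept = rbind(rep(0, 4), rep(3, 4)),
                  loading = matrix(rep(c(1, 0.7, 1.3, 0.5), each = 2), 2, 4),
                  resid = rbind(rep(1.2, 4), rep(0.8, 4)),
                  alpha = c(0, 2), psi = c(1, 1.5),
                  item_models = rep("gaussian", 4))
  it <- simulate_fmm(p, 20, seed = 3)
  expect_equal(fmm_loglik(p, it), oracle_fmm_loglik(p, it),
               tolerance = 1e-6)
  # and on the full six-item frailty block with censoring and two parts
  items <- small_items()
  sub <- items
  keep <- c(which(items$censored[, 4])[1:3],
            which(items$y[, 5] == 1)[1:5], 1:12)
  keep <- unique(keep[!is.na(keep)])
  sub$y <- items$y[keep, , drop = FALSE]
  sub$censored <- items$censored[keep, , drop = FALSE]
  fit <- fit_fmm(items, fmm_spec("SoMI", 2, "uv", items), n_starts = 2,
                 seed = 4, control = fmm_control(max_iter = 60))
  expect_equal(fmm_loglik(fit$params, sub),
               oracle_fmm_loglik(fit$params, sub), tolerance = 1e-6)
})

test_that("a censored cell contributes the closed-form normal left tail", {
  p <- fmm_params(pi = 1, intercept = matrix(5, 1, 1),
                  loading = matrix(0, 1, 1), resid = matrix(4, 1, 1),
                  alpha = 0, psi = NA_real_, item_models = "censored",
                  floors = 2)
  y <- matrix(2, 1, 1)
  it <- fmm_item_matrix(y, "censored", floors = 2,
                        censored = matrix(TRUE, 1, 1))
  expect_equal(fmm_loglik(p, it),
               stats::pnorm(2, mean = 5, sd = 2, log.p = TRUE),
               tolerance = 1e-10)
})

test_that("EM log-likelihood is non-decreasing for every family member", {
  items <- small_items()
  for (sp in list(fmm_spec("LCA", 2, "uv", items),
                  fmm_spec("SiMI", 2, "ev", items),
                  fmm_spec("SoMI", 2, "uv", items),
                  fmm_spec("WMI", 2, "uv", items),
                  fmm_spec("NMI", 2, "ev", items))) {
    fit <- fit_fmm(items, sp, n_starts = 2, seed = 5,
                   control = fmm_control(max_iter = 150))
    expect_true(all(diff(fit$trace) > -1e-5),
                label = sprintf("monotone trace for %s-%s", sp$family,
                                sp$variance))
  }
})

test_that("constrained fits never beat their unconstrained extensions", {
  items <- small_items()
  ctl <- fmm_control(max_iter = 250, tol = 1e-4)
  # each richer model also starts from the nested solution, so the
  # inequality must hold up to EM tolerance, not up to multistart luck
  f_simi <- fit_fmm(items, fmm_spec("SiMI", 2, "ev", items), n_starts = 3,
                    seed = 6, control = ctl)
  f_somi <- fit_fmm(items, fmm_spec("SoMI", 2, "uv", items), n_starts = 3,
                    seed = 6, control = ctl, init = f_simi$params)
  f_wmi <- fit_fmm(items, fmm_spec("WMI", 2, "uv", items), n_starts = 3,
                   seed = 6, control = ctl, init = f_somi$params)
  f_nmi <- fit_fmm(items, fmm_spec("NMI", 2, "uv", items), n_starts = 3,
                   seed = 6, control = ctl, init = f_wmi$params)
  expect_lte(f_simi$loglik, f_somi$loglik + 1e-4)
  expect_lte(f_somi$loglik, f_wmi$loglik + 1e-4)
  expect_lte(f_wmi$loglik, f_nmi$loglik + 1e-4)
})

test_that("relabelling classes leaves the likelihood unchanged", {
  items <- small_items()
  fit <- fit_fmm(items, fmm_spec("WMI", 3, "uv", items), n_starts = 2,
                 seed = 7, control = fmm_control(max_iter = 80))
  p <- fit$params
  perm <- c(3, 1, 2)
  q <- p
  q$pi <- p$pi[perm]; q$intercept <- p$intercept[perm, ]
  q$loading <- p$loading[perm, ]; q$resid <- p$resid[perm, ]
  q$alpha <- p$alpha[perm]; q$psi <- p$psi[perm]
  expect_equal(fmm_loglik(q, items), fmm_loglik(p, items),
               tolerance = 1e-10)
})

test_that("posteriors follow Bayes rule and modal ties break low", {
  p <- tiny_gaussian_params(K = 2, M = 4, sep = 8)
  it <- gaussian_items(200, p, seed = 8)
  fit <- fit_fmm(it, fmm_spec("LCA", 2, "uv", it), n_starts = 4, seed = 9)
  pp <- posterior_probs(fit, it)
  expect_equal(rowSums(pp$posteriors), rep(1, 200), tolerance = 1e-12)
  # independent Bayes computation from per-class densities
  pr <- fit$params
  for (i in c(1, 50, 131)) {
    lk <- vapply(1:2, function(k)
      sum(stats::dnorm(it$y[i, ], pr$intercept[k, ], sqrt(pr$resid[k, ]),
                       log = TRUE)), 0)
    post <- pr$pi * exp(lk - max(lk))
    post <- post / sum(post)
    expect_equal(pp$posteriors[i, ], post, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # strongly separated classes give near-degenerate posteriors
  expect_true(all(pmax(pp$posteriors[, 1], pp$posteriors[, 2]) > 0.99))
  expect_identical(pp$modal[1],
                   unname(which.max(pp$posteriors[1, ])))
})

test_that("relative entropy is 0 for uniform, 1 for degenerate posteriors", {
  expect_equal(relative_entropy(matrix(0.5, 40, 2)), 0)
  hard <- cbind(rep(c(1, 0), 20), rep(c(0, 1), 20))
  expect_equal(relative_entropy(hard), 1)
  expect_true(is.na(relative_entropy(matrix(1, 10, 1))))
  # hand-computed 3 x 2 posterior matrix
  pmat <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.5, 0.5))
  H <- -sum(pmat * log(pmat))
  expect_equal(relative_entropy(pmat), 1 - H / (3 * log(2)))
})

test_that("a one-class factor model is recovered from its own data", {
  truth <- one_factor_params()
  it <- simulate_fmm(truth, 2000, seed = 10)
  fit <- fit_fmm(it, fmm_spec("SoMI", 1, "ev", rep("gaussian", 5)),
                 n_starts = 1, seed = 11)
  # anchor fixed at 1; remaining loadings within 10% of truth
  expect_equal(fit$params$loading[1, 1], 1)
  rel <- abs(fit$params$loading[1, -1] - truth$loading[1, -1]) /
    truth$loading[1, -1]
  expect_lt(max(rel), 0.10)
  expect_lt(abs(fit$params$psi[1] - truth$psi[1]) / truth$psi[1], 0.15)
})

test_that("zero-loading class-varying spec coincides with a reference GMM", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  p <- tiny_gaussian_params(K = 2, M = 4, sep = 5)
  it <- gaussian_items(400, p, seed = 12)
  fit <- fit_fmm(it, fmm_spec("LCA", 2, "uv", it), n_starts = 5, seed = 13,
                 control = fmm_control(tol = 1e-8))
  ref <- mclust::Mclust(it$y, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-4)
})

test_that("degenerate runs are flagged rather than thrown", {
  # two classes demanded from 35 points of pure one-cluster data: at least
  # the fit must come back flagged or with a sensible likelihood
  p <- tiny_gaussian_params(K = 1, M = 4)
  it <- gaussian_items(35, p, seed = 14)
  fit <- fit_fmm(it, fmm_spec("LCA", 2, "uv", it), n_starts = 4, seed = 15,
                 control = fmm_control(class_floor = 12))
  expect_s3_class(fit, "fmm_fit")
  expect_true(is.finite(fit$loglik) || fit$degenerate)
})

test_that("the one- vs two-factor comparison behaves under both truths", {
  # one-factor truth: non-rejection in >= 90% of replications
  truth1 <- one_factor_params()
  rejections <- 0L
  for (r in 1:30) {
    it <- simulate_fmm(truth1, 300, seed = 100 + r)
    cmp <- compare_factor_dimension(it$y)
    if (cmp$p <= 0.05) rejections <- rejections + 1L
  }
  expect_lte(rejections, 3L + stats::qbinom(0.995, 30, 0.05))
  expect_gte(30L - rejections, 27L)

  # two orthogonal strong factors: rejection
  set.seed(99)
  n <- 400
  f1 <- rnorm(n, 0, 2); f2 <- rnorm(n, 0, 2)
  y2 <- cbind(f1 + rnorm(n, 0, 0.6), 0.9 * f1 + rnorm(n, 0, 0.6),
              0.8 * f1 + rnorm(n, 0, 0.6),
              f2 + rnorm(n, 0, 0.6), 0.9 * f2 + rnorm(n, 0, 0.6))
  cmp2 <- compare_factor_dimension(y2)
  expect_lt(cmp2$p, 0.001)
  expect_identical(cmp2$df, 4L)

  # identical factor counts compare as a zero statistic
  cmp0 <- compare_factor_dimension(y2, m_null = 1, m_alt = 1)
  expect_equal(cmp0$chi2, 0)
})
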