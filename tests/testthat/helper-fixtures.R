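# Shared small fixtures built in code. Anything expensive is memoised within
# a test run.

tiny_gaussian_params <- function(K = 2L, M = 5L, sep = 6) {
  # diagonal-gaussian (latent profile) parameter set, well separated
  fmm_params(pi = rep(1 / K, K),
             intercept = outer(seq_len(K) - 1, rep(sep, M)),
             loading = matrix(0, K, M),
             resid = matrix(1, K, M),
             alpha = rep(0, K), psi = rep(NA_real_, K),
             item_models = rep("gaussian", M))
}

gaussian_items <- function(n, params, seed = 1) {
  simulate_fmm(params, n, seed = seed)
}

one_factor_params <- function(M = 5L, load = c(1, 0.8, 1.2, 0.6, 0.9),
                              psi = 4, theta = 1) {
  fmm_params(pi = 1,
             intercept = matrix(0, 1, M),
             loading = matrix(load, 1, M),
             resid = matrix(theta, 1, M),
             alpha = 0, psi = psi,
             item_models = rep("gaussian", M))
}

small_cohort <- local({
  cache <- NULL
  function(n = 500, seed = 11) {
    if (is.null(cache))
      cache <<- generate_cohort(default_config_frele(n_subjects = n),
                                seed = seed)
    cache
  }
})

small_items <- function(...) encode_fmm_items(small_cohort(...))

# brute-force FMM log-likelihood: numerical integration of the factor per
# subject, item by item (independent of the analytic implementation path)
oracle_fmm_loglik <- function(params, items) {
  n <- nrow(items$y)
  total <- 0
  for (i in seq_len(n)) {
    li <- 0
    for (k in seq_len(params$K)) {
      f <- function(eta) {
        out <- rep(1, length(eta))
        for (m in seq_len(params$M)) {
          mu <- params$intercept[k, m] + params$loading[k, m] * eta
          tp <- params$item_models[m]
          if (tp == "bernoulli") {
            p <- stats::plogis(params$intercept[k, m])
            out <- out * ifelse(items$y[i, m] == 1, p, 1 - p)
          } else if (tp == "censored" && items$censored[i, m]) {
            out <- out * stats::pnorm((items$floors[m] - mu) /
                                        sqrt(params$resid[k, m]))
          } else if (tp == "magnitude" && is.na(items$y[i, m])) {
            # no contribution
          } else {
            out <- out * stats::dnorm(items$y[i, m], mu,
                                      sqrt(params$resid[k, m]))
          }
        }
        out
      }
      int <- if (params$has_factor) {
        # dense trapezoid over the prior's support: robust against the
        # sharply peaked integrands that defeat adaptive quadrature
        ctr <- params$alpha[k]; wd <- 10 * sqrt(params$psi[k])
        grid <- seq(ctr - wd, ctr + wd, length.out = 8001L)
        h <- grid[2] - grid[1]
        vals <- f(grid) * stats::dnorm(grid, ctr, sqrt(params$psi[k]))
        h * (sum(vals) - 0.5 * (vals[1] + vals[length(vals)]))
      } else f(0)
      li <- li + params$pi[k] * int
    }
    total <- total + log(li)
  }
  total
}

# brute-force binary LCA log-likelihood by pattern summation
oracle_lca_loglik <- function(binary, mixing, probs) {
  n <- nrow(binary)
  total <- 0
  for (i in seq_len(n)) {
    li <- 0
    for (k in seq_along(mixing)) {
      pk <- prod(ifelse(binary[i, ] == 1, probs[k, ], 1 - probs[k, ]))
      li <- li + mixing[k] * pk
    }
    total <- total + log(li)
  }
  total
}

rdirichlet1_test <- function(K) {
  g <- stats::rgamma(K, 1)
  g / sum(g)
}

# align the rows of an estimated K x M matrix with a truth matrix by
# greedy minimal distance (label switching)
align_classes <- function(est, truth) {
  K <- nrow(truth)
  perm <- integer(K)
  used <- logical(K)
  for (k in seq_len(K)) {
    d <- apply(est, 1, function(r) sum((r - truth[k, ])^2))
    d[used] <- Inf
    perm[k] <- which.min(d)
    used[perm[k]] <- TRUE
  }
  perm
}
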