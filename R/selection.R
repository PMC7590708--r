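# Model comparison: BIC differences, the parametric bootstrap likelihood
# ratio test (BLRT), Monte Carlo acceptability diagnostics, and the
# comparison ledger that records every decision with its statistics.

#' BIC difference between two fits on the same data
#'
#' `bic(a) - bic(b)`: negative values favour `a`.
#'
#' @param fit_a,fit_b `fmm_fit` or `binary_lca` objects fitted to the same
#'   data.
#' @return scalar difference.
#' @export
bic_difference <- function(fit_a, fit_b) {
  na <- fit_a$n; nb <- fit_b$n
  if (!identical(na, nb))
    stop(sprintf("fits use different n (%d vs %d); BIC differences require the same data",
                 na, nb), call. = FALSE)
  fit_a$bic - fit_b$bic
}

#' Parametric bootstrap likelihood-ratio test
#'
#' Fits the null and alternative models to the data, then refits both to `B`
#' datasets simulated from the fitted null. The p-value is
#' `(1 + #\{LRT_b >= LRT_obs\}) / (B_used + 1)`, the standard add-one
#' estimate. Non-converged or degenerate replicates are dropped and counted;
#' the result is flagged unreliable when more than 20\% fail. With
#' `alpha_stop` set, replication stops as soon as enough bootstrap statistics
#' exceed the observed one that rejection at that level is impossible (the
#' decision is unchanged; the reported p is then a lower-resolution
#' estimate, flagged `early_stopped`).
#'
#' The two specs need not be strictly nested (some of the published
#' comparisons, e.g. latent profile vs strong invariance, are not); the
#' `nested` field records which case applies.
#'
#' @param items an [fmm_item_matrix()], or an `n x M` 0/1 matrix for the
#'   dichotomized-component latent class version.
#' @param spec_alt,spec_null [fmm_spec()] objects (or class counts `K` for the
#'   binary case).
#' @param B bootstrap replications (1000 reproduces the reference
#'   procedure; 99-199 is a practical test profile).
#' @param n_starts random starts for the two observed fits.
#' @param boot_starts random starts for each replicate refit (fewer by
#'   design; replicate likelihoods only feed the null distribution).
#' @param seed seed; replicate `b` uses `seed + b`.
#' @param control [fmm_control()] for observed fits; `boot_control`
#'   (default: coarser tolerance, fewer quadrature points) for replicates.
#' @param alpha_stop optional early-stopping level (see above).
#' @param fit_alt,fit_null optional pre-computed observed fits (skips the two
#'   observed-data fits; the caller guarantees they used `items`).
#' @return object of class `blrt_result`: `lrt_observed`, `B`,
#'   `bootstrap_lrts`, `p_value`, `n_failed_replicates`, `reject` at
#'   `alpha_stop` (if given), flags and seeds.
#' @export
blrt <- function(items, spec_alt, spec_null, B = 1000L, n_starts = 20L,
                 boot_starts = 4L, seed = 1L, control = fmm_control(),
                 boot_control = NULL, alpha_stop = NULL,
                 fit_alt = NULL, fit_null = NULL) {
  if (is.matrix(items) && !inherits(items, "fmm_items"))
    return(.blrt_binary(items, K_alt = spec_alt, K_null = spec_null, B = B,
                        n_starts = n_starts, boot_starts = boot_starts,
                        seed = seed, alpha_stop = alpha_stop))
  stopifnot(inherits(items, "fmm_items"),
            inherits(spec_alt, "fmm_spec"), inherits(spec_null, "fmm_spec"))
  if (is.null(boot_control))
    boot_control <- fmm_control(n_quad = control$n_quad,
                                max_iter = 60L, tol = 5e-2,
                                short_iter = 6L,
                                class_floor = control$class_floor,
                                var_floor_frac = control$var_floor_frac)
  nested <- is_nested(spec_null, spec_alt)

  fit0 <- fit_null %||% fit_fmm(items, spec_null, n_starts = n_starts,
                                seed = seed + 1L, control = control)
  # for same-K nested pairs the null solution seeds the alternative, which
  # keeps the observed ratio non-negative by EM monotonicity
  fit1 <- fit_alt %||% fit_fmm(items, spec_alt, n_starts = n_starts,
                               seed = seed, control = control,
                               init = if (nested &&
                                            spec_null$K == spec_alt$K)
                                 fit0$params else NULL)
  lrt_obs <- -2 * (fit0$loglik - fit1$loglik)
  n <- nrow(items$y)

  sim_fun <- function(b) simulate_fmm(fit0$params, n, seed = seed + 1000L + b)
  # replicate refits start from the observed estimates (plus boot_starts
  # random restarts): the standard practice, and much cheaper than fresh
  # initialization at every replicate
  fit_fun <- function(dat, spec, b, init = NULL) {
    base <- if (identical(unclass(spec), unclass(spec_null))) fit0$params else
      fit1$params
    inits <- c(list(base), if (is.null(init)) NULL else list(init))
    fit_fmm(dat, spec, n_starts = boot_starts, seed = seed + 2000L + b,
            control = boot_control, init = inits)
  }
  .blrt_loop(lrt_obs, B, sim_fun, fit_fun, spec_alt, spec_null,
             alpha_stop, seed, nested,
             observed = list(fit_alt = fit1, fit_null = fit0),
             chain_init = nested && spec_null$K == spec_alt$K)
}

.blrt_binary <- function(binary, K_alt, K_null, B, n_starts, boot_starts,
                         seed, alpha_stop) {
  fit1 <- fit_binary_lca(binary, K_alt, n_starts = n_starts, seed = seed)
  fit0 <- fit_binary_lca(binary, K_null, n_starts = n_starts,
                         seed = seed + 1L)
  lrt_obs <- -2 * (fit0$loglik - fit1$loglik)
  n <- nrow(binary)
  sim_fun <- function(b) simulate_binary_lca(fit0$mixing, fit0$response_probs,
                                             n, seed = seed + 1000L + b)
  fit_fun <- function(dat, K, b)
    fit_binary_lca(dat, K, n_starts = boot_starts, seed = seed + 2000L + b,
                   max_iter = 200L, tol = 1e-3)
  .blrt_loop(lrt_obs, B, sim_fun, fit_fun, K_alt, K_null, alpha_stop, seed,
             nested = K_null <= K_alt,
             observed = list(fit_alt = fit1, fit_null = fit0))
}

.blrt_loop <- function(lrt_obs, B, sim_fun, fit_fun, spec_alt, spec_null,
                       alpha_stop, seed, nested, observed,
                       chain_init = FALSE) {
  lrts <- numeric(0)
  n_failed <- 0L
  exceed <- 0L
  early <- FALSE
  xmax <- if (is.null(alpha_stop)) Inf else
    floor(alpha_stop * (B + 1) - 1 + 1e-9)
  for (b in seq_len(B)) {
    dat <- sim_fun(b)
    f0 <- tryCatch(fit_fun(dat, spec_null, b), error = function(e) NULL)
    f1 <- tryCatch(
      if (chain_init && !is.null(f0))
        fit_fun(dat, spec_alt, b, init = f0$params) else
          fit_fun(dat, spec_alt, b),
      error = function(e) NULL)
    bad <- is.null(f1) || is.null(f0) ||
      isTRUE(f1$degenerate) || isTRUE(f0$degenerate)
    if (bad) { n_failed <- n_failed + 1L; next }
    lrt_b <- -2 * (f0$loglik - f1$loglik)
    lrts <- c(lrts, lrt_b)
    if (lrt_b >= lrt_obs) exceed <- exceed + 1L
    if (exceed > xmax) { early <- TRUE; break }
  }
  B_used <- length(lrts)
  p <- (1 + exceed) / (B_used + 1)
  out <- list(lrt_observed = lrt_obs, B = B, B_used = B_used,
              bootstrap_lrts = lrts, p_value = p,
              n_failed_replicates = n_failed,
              unreliable = n_failed > 0.2 * B,
              early_stopped = early,
              reject = if (is.null(alpha_stop)) NA else
                (!early && p <= alpha_stop),
              alpha_stop = alpha_stop, nested = nested, seed = seed,
              fit_alt = observed$fit_alt, fit_null = observed$fit_null)
  class(out) <- "blrt_result"
  out
}

#' @export
print.blrt_result <- function(x, ...) {
  cat(sprintf("<blrt> LRT = %.3f, p = %.4f (%d/%d replicates%s)%s\n",
              x$lrt_observed, x$p_value, x$B_used, x$B,
              if (x$n_failed_replicates > 0)
                sprintf(", %d failed", x$n_failed_replicates) else "",
              if (x$early_stopped) " [early stop: cannot reject]" else ""))
  if (!x$nested) cat("  note: models are not nested\n")
  invisible(x)
}

# ---- parameter packing (used for SEs and Monte Carlo diagnostics) --------

# free-parameter vector under the spec's identification rules
pack_params <- function(params, spec) {
  K <- spec$K
  v <- c()
  nm <- c()
  if (K > 1L) {
    v <- c(v, params$pi[-K]); nm <- c(nm, paste0("pi", 1:(K - 1)))
  }
  inames <- names(spec$item_models) %||% paste0("item", seq_len(spec$M))
  for (m in seq_len(spec$M)) {
    tp <- spec$item_models[m]
    ks <- if (spec$intercepts_vary) 1:K else 1L
    v <- c(v, params$intercept[ks, m])
    nm <- c(nm, paste0("I.", inames[m], if (length(ks) > 1) paste0(".k", ks)
                       else ""))
    if (spec$has_factor && tp != "bernoulli" && m != spec$anchor) {
      ksl <- if (spec$loadings_vary) 1:K else 1L
      v <- c(v, params$loading[ksl, m])
      nm <- c(nm, paste0("F.", inames[m],
                         if (length(ksl) > 1) paste0(".k", ksl) else ""))
    }
    if (tp != "bernoulli") {
      ksr <- if (spec$resid_vary) 1:K else 1L
      v <- c(v, params$resid[ksr, m])
      nm <- c(nm, paste0("th.", inames[m],
                         if (length(ksr) > 1) paste0(".k", ksr) else ""))
    }
  }
  if (spec$has_factor) {
    if (spec$factor_means_free) {
      v <- c(v, params$alpha[2:K]); nm <- c(nm, paste0("alpha.k", 2:K))
    }
    ksp <- if (spec$factor_var_vary) 1:K else 1L
    v <- c(v, params$psi[ksp])
    nm <- c(nm, paste0("psi", if (length(ksp) > 1) paste0(".k", ksp) else ""))
  }
  stats::setNames(v, nm)
}

unpack_params <- function(v, spec, template) {
  K <- spec$K
  p <- template
  i <- 0L
  take <- function(k) { out <- v[i + seq_len(k)]; i <<- i + k; out }
  if (K > 1L) {
    pk <- take(K - 1L)
    p$pi <- c(pk, 1 - sum(pk))
  } else p$pi <- 1
  for (m in seq_len(spec$M)) {
    tp <- spec$item_models[m]
    if (spec$intercepts_vary) p$intercept[, m] <- take(K) else
      p$intercept[, m] <- rep(take(1L), K)
    if (spec$has_factor && tp != "bernoulli" && m != spec$anchor) {
      if (spec$loadings_vary) p$loading[, m] <- take(K) else
        p$loading[, m] <- rep(take(1L), K)
    }
    if (tp != "bernoulli") {
      if (spec$resid_vary) p$resid[, m] <- take(K) else
        p$resid[, m] <- rep(take(1L), K)
    }
  }
  if (spec$has_factor) {
    if (spec$factor_means_free) p$alpha <- c(0, take(K - 1L)) else
      p$alpha <- rep(0, K)
    if (spec$factor_var_vary) p$psi <- take(K) else p$psi <- rep(take(1L), K)
  }
  p
}

# observed-information standard errors at the MLE (numerically
# differentiated log-likelihood)
.fmm_se <- function(fit, items, n_quad = NULL) {
  spec <- fit$spec
  Q <- n_quad %||% fit$control$n_quad
  v0 <- pack_params(fit$params, spec)
  f <- function(v) {
    p <- unpack_params(v, spec, fit$params)
    if (any(p$pi <= 0) || any(p$resid <= 0, na.rm = TRUE) ||
        (p$has_factor && any(p$psi <= 0))) return(1e10)
    -.fmm_estep(p, items, Q = Q)$loglik
  }
  H <- pracma::hessian(f, v0)
  se <- rep(NA_real_, length(v0))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (!is.null(V)) {
    d <- diag(V)
    se[d > 0] <- sqrt(d[d > 0])
  }
  stats::setNames(se, names(v0))
}

#' Monte Carlo acceptability diagnostics
#'
#' Simulation check of estimator quality at a given parameter set: `R`
#' datasets of size `n` are simulated and refitted under `spec`; for every
#' free parameter the relative bias (absolute when the true value is 0), the
#' standard-error bias (model SE vs the replication SD), the 95\% coverage
#' and the power to reject zero are reported, with flags where the SE bias
#' exceeds 10\%.
#'
#' @param params true [fmm_params()] (must satisfy `spec`'s constraints).
#' @param spec an [fmm_spec()].
#' @param n simulated sample size.
#' @param R replications (>= 2).
#' @param seed seed; replicate r uses `seed + r`.
#' @param n_starts,control fitting settings per replicate.
#' @return object of class `mc_diagnostics`: a data.frame (one row per free
#'   parameter) plus `R_used`.
#' @export
monte_carlo_diagnostics <- function(params, spec, n, R, seed = 1L,
                                    n_starts = 10L, control = fmm_control()) {
  if (R < 2L) stop("R must be >= 2: replication SDs are undefined at R = 1",
                   call. = FALSE)
  truth <- pack_params(params, spec)
  est <- matrix(NA_real_, R, length(truth),
                dimnames = list(NULL, names(truth)))
  ses <- est
  used <- 0L
  for (r in seq_len(R)) {
    dat <- simulate_fmm(params, n, seed = seed + r)
    fit <- tryCatch(fit_fmm(dat, spec, n_starts = n_starts,
                            seed = seed + 5000L + r, control = control),
                    error = function(e) NULL)
    if (is.null(fit) || fit$degenerate) next
    used <- used + 1L
    est[r, ] <- pack_params(fit$params, spec)
    ses[r, ] <- .fmm_se(fit, dat)
  }
  ok <- stats::complete.cases(est)
  est <- est[ok, , drop = FALSE]; ses <- ses[ok, , drop = FALSE]
  if (nrow(est) < 2L)
    stop("fewer than 2 usable replicates; increase R or n_starts",
         call. = FALSE)
  mean_est <- colMeans(est)
  sd_est <- apply(est, 2, stats::sd)
  mean_se <- colMeans(ses, na.rm = TRUE)
  rel_bias <- ifelse(truth == 0, NA_real_,
                     100 * (mean_est - truth) / truth)
  abs_bias <- mean_est - truth
  se_bias <- 100 * (mean_se - sd_est) / sd_est
  lo <- est - 1.96 * ses; hi <- est + 1.96 * ses
  coverage <- colMeans(sweep(lo, 2, truth, `<=`) &
                         sweep(hi, 2, truth, `>=`), na.rm = TRUE)
  power <- colMeans(abs(est / ses) > 1.96, na.rm = TRUE)
  out <- data.frame(parameter = names(truth), true = unname(truth),
                    mean_estimate = unname(mean_est),
                    rel_bias_pct = unname(rel_bias),
                    abs_bias = unname(abs_bias),
                    se_bias_pct = unname(se_bias),
                    coverage95 = unname(coverage), power = unname(power),
                    se_bias_flag = unname(abs(se_bias) > 10))
  attr(out, "R_used") <- nrow(est)
  class(out) <- c("mc_diagnostics", "data.frame")
  out
}

#' Assemble a comparison ledger from fits and tests
#'
#' Records the pairwise comparisons of the model-selection procedure in
#' decision order, each row citing its BIC difference and/or bootstrap
#' p-value with a rationale. When BIC and BLRT disagree the configured rule
#' decides: the default follows the published usage, with the BLRT governing
#' class-count (nested) comparisons and both statistics required to reject a
#' null family member.
#'
#' @param comparisons list of lists, each with `label`, `fit_alt`,
#'   `fit_null`, optional `blrt` (a [blrt()] result), and `kind`
#'   (`"class-count"`, `"variance"`, `"vs-null-family"`).
#' @param alpha significance level.
#' @param rule `"both"`, `"blrt"` or `"bic"` for the vs-null-family rows.
#' @return data.frame of class `comparison_ledger`.
#' @export
compare_family <- function(comparisons, alpha = 0.05,
                           rule = c("both", "blrt", "bic")) {
  rule <- match.arg(rule)
  if (length(comparisons) == 0L) {
    out <- data.frame(label = character(), kind = character(),
                      model_alt = character(), model_null = character(),
                      bic_alt = numeric(), bic_null = numeric(),
                      bic_diff = numeric(), blrt_p = numeric(),
                      reject_null = logical(), rationale = character())
    class(out) <- c("comparison_ledger", "data.frame")
    return(out)
  }
  rows <- lapply(comparisons, function(cmp) {
    fa <- cmp$fit_alt; f0 <- cmp$fit_null
    bd <- bic_difference(fa, f0)
    p <- if (!is.null(cmp$blrt)) cmp$blrt$p_value else NA_real_
    blrt_rej <- if (!is.null(cmp$blrt)) {
      if (!is.null(cmp$blrt$alpha_stop) && cmp$blrt$early_stopped) FALSE else
        p <= alpha
    } else NA
    bic_fav_alt <- bd < 0
    reject <- switch(cmp$kind,
      "class-count" = isTRUE(blrt_rej),
      "variance" = isTRUE(blrt_rej),
      "vs-null-family" = switch(rule,
        both = isTRUE(blrt_rej) && bic_fav_alt,
        blrt = isTRUE(blrt_rej),
        bic = bic_fav_alt),
      isTRUE(blrt_rej))
    rationale <- sprintf(
      "BIC diff (alt - null) = %.1f (%s); BLRT p = %s; rule = %s => %s",
      bd, if (bic_fav_alt) "favours alt" else "favours null",
      if (is.na(p)) "n/a" else formatC(p, digits = 4, format = "f"),
      if (cmp$kind == "vs-null-family") rule else "blrt",
      if (reject) "reject null" else "retain null")
    data.frame(label = cmp$label, kind = cmp$kind,
               model_alt = .model_label(fa), model_null = .model_label(f0),
               bic_alt = fa$bic, bic_null = f0$bic, bic_diff = bd,
               blrt_p = p, reject_null = reject, rationale = rationale)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_ledger", "data.frame")
  out
}

.model_label <- function(fit) {
  if (inherits(fit, "binary_lca")) return(sprintf("binaryLCA-K%d", fit$K))
  sprintf("%s-%s-K%d", fit$spec$family, fit$spec$variance, fit$spec$K)
}

#' @export
print.comparison_ledger <- function(x, ...) {
  cat("<comparison_ledger>\n")
  if (nrow(x) == 0L) { cat("  (no comparisons)\n"); return(invisible(x)) }
  print.data.frame(x[, c("label", "model_alt", "model_null", "bic_diff",
                         "blrt_p", "reject_null")],
                   row.names = FALSE, digits = 4)
  invisible(x)
}
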