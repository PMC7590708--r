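# Latent class analysis of the five dichotomized components: a finite
# mixture of independent Bernoulli items, fitted by EM on the 2^5 response
# patterns. Free parameters: 5K response probabilities + (K - 1) mixing.

.pattern_matrix <- function(M = 5L) {
  as.matrix(expand.grid(rep(list(0:1), M)))[, M:1, drop = FALSE]
}

.collapse_patterns <- function(binary) {
  M <- ncol(binary)
  pat <- .pattern_matrix(M)
  id <- as.vector(binary %*% (2L^((M - 1L):0L)))
  pid <- as.vector(pat %*% (2L^((M - 1L):0L)))
  counts <- tabulate(match(id, pid), nbins = nrow(pat))
  list(patterns = pat, counts = counts, id = match(id, pid))
}

# log P(pattern | class) for all 2^M patterns: patterns (P x M), probs (K x M)
.lca_pattern_logdens <- function(patterns, probs) {
  lp <- log(probs); lq <- log1p(-probs)
  patterns %*% t(lp) + (1 - patterns) %*% t(lq)       # P x K
}

#' Fit a latent class model to dichotomized frailty components
#'
#' EM over `n_starts` random initializations; the best log-likelihood is
#' retained. Class-conditional response probabilities are floored at 1e-6 to
#' keep the log-likelihood finite (a deliberate, documented deviation from
#' unconstrained maximum likelihood). Classes are sorted by decreasing mean
#' deficit prevalence (class 1 = frailest) so reports are deterministic.
#'
#' @param binary `n x 5` 0/1 matrix from [dichotomize()] (any `n x M` 0/1
#'   matrix is accepted).
#' @param K number of classes (>= 1).
#' @param n_starts random EM restarts (ignored for `K = 1`, which is closed
#'   form).
#' @param seed RNG seed for the restarts.
#' @param max_iter,tol EM stopping rule: Aitken-estimated remaining
#'   log-likelihood gain below `tol`, or `max_iter` iterations.
#' @return object of class `binary_lca`: mixing, `response_probs` (K x M),
#'   `loglik`, `n_params = MK + K - 1`, `bic`, per-subject `posteriors`,
#'   `converged`, `n_starts_used`, the EM `trace` of the winning run, and the
#'   pattern bookkeeping used by [lca_goodness_of_fit()].
#' @export
fit_binary_lca <- function(binary, K, n_starts = 50L, seed = 1L,
                           max_iter = 1000L, tol = 1e-6) {
  binary <- unclass(binary)
  stopifnot(all(binary %in% 0:1), K >= 1L)
  n <- nrow(binary); M <- ncol(binary)
  if (n < 10L * K)
    stop(sprintf("n = %d too small for K = %d (need n >= 10K)", n, K),
         call. = FALSE)
  cp <- .collapse_patterns(binary)
  pat <- cp$patterns; cnt <- cp$counts
  floor_p <- 1e-6
  clamp <- function(p) pmin(pmax(p, floor_p), 1 - floor_p)

  run_em <- function(probs, mix) {
    trace <- numeric(0)
    ll1 <- ll2 <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      ld <- .lca_pattern_logdens(pat, probs)            # P x K
      a <- sweep(ld, 2, log(mix), `+`)
      m <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
      w <- exp(a - m)
      ll <- sum(cnt * (m + log(rowSums(w))))
      trace <- c(trace, ll)
      w <- w / rowSums(w)                               # P x K posteriors
      wk <- cnt * w                                     # pattern-weighted
      nk <- colSums(wk)
      mix <- nk / sum(nk)
      probs <- clamp(t(wk) %*% pat / nk)                # K x M
      # Aitken-accelerated stop on the estimated likelihood asymptote
      if (is.finite(ll2)) {
        r <- (ll - ll1) / (ll1 - ll2)
        gap <- if (is.finite(r) && r > 0 && r < 1)
          abs(ll1 + (ll - ll1) / (1 - r) - ll) else abs(ll - ll1)
        if (gap < tol) { converged <- TRUE; break }
      } else if (abs(ll - ll1) < tol) { converged <- TRUE; break }
      ll2 <- ll1
      ll1 <- ll
    }
    list(probs = probs, mix = mix, loglik = ll, converged = converged,
         trace = trace)
  }

  if (K == 1L) {
    probs <- matrix(clamp(colMeans(binary)), 1, M)
    best <- run_em(probs, 1)
    n_used <- 1L
  } else {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    best <- NULL
    n_used <- 0L
    for (s in seq_len(n_starts)) {
      probs <- matrix(clamp(stats::runif(K * M, 0.05, 0.95)), K, M)
      mix <- rdirichlet1(K)
      fit <- run_em(probs, mix)
      n_used <- n_used + 1L
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  }

  # sort classes: frailest (highest mean deficit prevalence) first
  ord <- order(rowMeans(best$probs), decreasing = TRUE)
  probs <- best$probs[ord, , drop = FALSE]
  mix <- best$mix[ord]
  dimnames(probs) <- list(paste0("class", 1:K), colnames(binary))

  ld <- .lca_pattern_logdens(pat, probs)
  a <- sweep(ld, 2, log(mix), `+`)
  mrow <- a[cbind(seq_len(nrow(a)), max.col(a, ties.method = "first"))]
  pw <- exp(a - mrow); pw <- pw / rowSums(pw)
  posteriors <- pw[cp$id, , drop = FALSE]

  n_params <- as.integer(M * K + K - 1L)
  out <- list(K = as.integer(K), mixing = mix, response_probs = probs,
              loglik = best$loglik, n_params = n_params,
              bic = -2 * best$loglik + n_params * log(n),
              posteriors = posteriors, converged = best$converged,
              n_starts_used = n_used, trace = best$trace,
              n = n, M = as.integer(M),
              pattern_counts = cnt, patterns = pat)
  class(out) <- "binary_lca"
  out
}

# dirichlet(1,...,1) draw without an extra dependency
rdirichlet1 <- function(K) {
  g <- stats::rgamma(K, 1)
  g / sum(g)
}

#' @export
print.binary_lca <- function(x, ...) {
  cat(sprintf("<binary_lca> K = %d, loglik = %.3f, BIC = %.2f, %sconverged\n",
              x$K, x$loglik, x$bic, if (x$converged) "" else "NOT "))
  cat("mixing:", paste(formatC(x$mixing, 3, format = "f"), collapse = " "), "\n")
  print(round(x$response_probs, 3))
  invisible(x)
}

#' @export
logLik.binary_lca <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' Pearson chi-square goodness of fit for a binary LCA
#'
#' Compares observed counts over all \eqn{2^M} response patterns with
#' model-implied expected counts. Degrees of freedom are
#' \eqn{(2^M - 1) - (MK + K - 1)}; for the five frailty components this is
#' 26, 20 and 14 at K = 1, 2, 3. A zero expected count with a positive
#' observed count yields an infinite statistic, which is reported rather than
#' masked.
#'
#' @param fit a `binary_lca`.
#' @return list with `chi2`, `df`, `p`.
#' @export
lca_goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "binary_lca"))
  ld <- .lca_pattern_logdens(fit$patterns, fit$response_probs)
  ppat <- as.vector(exp(ld) %*% fit$mixing)
  expected <- fit$n * ppat
  obs <- fit$pattern_counts
  chi2 <- if (any(expected == 0 & obs > 0)) {
    Inf
  } else {
    ok <- expected > 0
    sum((obs[ok] - expected[ok])^2 / expected[ok])
  }
  df <- as.integer((2^fit$M - 1L) - fit$n_params)
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  list(chi2 = chi2, df = df, p = p)
}

#' Per-class component deficit prevalences
#'
#' Class-conditional response probabilities arranged for ordering checks,
#' classes sorted (as in the fit) from frailest to most robust.
#'
#' @param fit a converged `binary_lca`.
#' @return data.frame: one row per class with mixing share, mean deficit
#'   prevalence and the per-component prevalences.
#' @export
class_prevalence_profile <- function(fit) {
  stopifnot(inherits(fit, "binary_lca"))
  data.frame(class = seq_len(fit$K), share = fit$mixing,
             mean_prevalence = rowMeans(fit$response_probs),
             fit$response_probs, row.names = NULL, check.names = FALSE)
}

#' Simulate response patterns from binary LCA parameters
#'
#' @param mixing,response_probs parameters (length K; K x M).
#' @param n subjects.
#' @param seed RNG seed.
#' @return `n x M` 0/1 matrix.
#' @export
simulate_binary_lca <- function(mixing, response_probs, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  response_probs <- as.matrix(response_probs)
  K <- length(mixing); M <- ncol(response_probs)
  cls <- sample.int(K, n, replace = TRUE, prob = mixing)
  y <- matrix(stats::rbinom(n * M, 1L, as.vector(response_probs[cls, ])),
              n, M)
  colnames(y) <- colnames(response_probs)
  y
}
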