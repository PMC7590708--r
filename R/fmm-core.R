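# Factor mixture model core: likelihood, EM estimation, posteriors, entropy.
#
# Measurement model, conditional on class k and factor score eta:
#   gaussian / censored / magnitude item c:  y_c ~ N(I_kc + F_kc * eta, theta_kc)
#   censored item: cells flagged at the floor L contribute P(Y* <= L), the
#     normal left tail (Tobit term)
#   bernoulli item: P(y = 1) = plogis(I_kc + F_kc * eta), with F fixed at 0
#     in the default frailty block
#   factor: eta ~ N(alpha_k, psi_k)
# The factor is integrated out by adaptive Gauss-Hermite quadrature (nodes
# recentred at each class's alpha_k, psi_k); models without a factor (latent
# profile analysis) skip the quadrature entirely.

#' Gauss-Hermite nodes and weights
#'
#' Golub-Welsch nodes/weights for the physicists' weight \eqn{e^{-x^2}};
#' normalized weights sum to 1 so they integrate a N(0, 1/2) density exactly.
#'
#' @param Q number of nodes.
#' @return list with `nodes` and normalized `weights`.
#' @keywords internal
gauss_hermite <- function(Q) {
  key <- as.character(Q)
  hit <- .gh_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- if (Q == 1L) list(nodes = 0, weights = 1) else {
    i <- seq_len(Q - 1L)
    J <- matrix(0, Q, Q)
    off <- sqrt(i / 2)
    J[cbind(i, i + 1L)] <- off
    J[cbind(i + 1L, i)] <- off
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    list(nodes = e$values[ord], weights = (e$vectors[1, ord]^2))
  }
  .gh_cache[[key]] <- out
  out
}
.gh_cache <- new.env(parent = emptyenv())

#' Parameter set for a factor mixture model
#'
#' @param pi mixing proportions (length K).
#' @param intercept K x M matrix of intercepts (logit scale for Bernoulli
#'   items).
#' @param loading K x M matrix of factor loadings (anchor column fixed at 1,
#'   Bernoulli columns at 0; all zero for latent profile models).
#' @param resid K x M matrix of residual variances (`NA` for Bernoulli items).
#' @param alpha,psi per-class factor means and variances (`psi` `NA` when
#'   there is no factor block).
#' @param item_models,floors,anchor item metadata as in [fmm_item_matrix()].
#' @return object of class `fmm_params`.
#' @export
fmm_params <- function(pi, intercept, loading, resid, alpha, psi,
                       item_models, floors = rep(NA_real_, ncol(intercept)),
                       anchor = which(item_models != "bernoulli")[1]) {
  K <- length(pi)
  intercept <- as.matrix(intercept); loading <- as.matrix(loading)
  resid <- as.matrix(resid)
  M <- ncol(intercept)
  stopifnot(nrow(intercept) == K, all(dim(loading) == c(K, M)),
            all(dim(resid) == c(K, M)), length(alpha) == K,
            length(psi) == K, length(item_models) == M)
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1", call. = FALSE)
  if (any(resid[, item_models != "bernoulli"] <= 0, na.rm = FALSE) ||
      any(is.na(resid[, item_models != "bernoulli"])))
    stop("residual variances must be positive for non-Bernoulli items",
         call. = FALSE)
  has_factor <- !all(is.na(psi))
  if (has_factor && any(psi <= 0))
    stop("factor variances must be positive", call. = FALSE)
  structure(list(pi = as.numeric(pi), intercept = intercept,
                 loading = loading, resid = resid,
                 alpha = as.numeric(alpha), psi = as.numeric(psi),
                 item_models = item_models, floors = as.numeric(floors),
                 anchor = as.integer(anchor), K = as.integer(K),
                 M = as.integer(M), has_factor = has_factor),
            class = "fmm_params")
}

#' @export
print.fmm_params <- function(x, ...) {
  cat(sprintf("<fmm_params> K = %d, %d items%s\n", x$K, x$M,
              if (x$has_factor) "" else " (no factor block)"))
  cat("pi:", paste(formatC(x$pi, 3, format = "f"), collapse = " "), "\n")
  invisible(x)
}

# E-step / likelihood workhorse. Returns observed loglik, class posteriors,
# and (optionally) the sufficient statistics needed by the M-step.
#
# The one-factor structure makes the factor integral analytic for rows whose
# gaussian-type cells are all observed (Woodbury identity on
# Sigma = Theta + psi F F'); the normal posterior of eta given (y, class)
# then provides exact conditional moments. Rows with a censored cell are the
# only ones integrated numerically, by Gauss-Hermite quadrature recentred at
# the posterior implied by the row's uncensored cells.
# static per-dataset bookkeeping shared by every E-step call on `items`
.fmm_layout <- function(items) {
  y <- items$y; types <- items$types; cens <- items$censored
  n <- nrow(y); M <- ncol(y)
  gtype <- types %in% c("gaussian", "censored", "magnitude")
  pres <- !is.na(y)                                # cells with data
  obs <- pres & !cens                              # fully observed cells
  has_cens <- rowSums(cens) > 0L
  pat_key <- as.vector((obs & rep(gtype, each = n)) %*% (2^(seq_len(M) - 1)))
  groups <- lapply(split(seq_len(n)[!has_cens], pat_key[!has_cens]),
                   function(g) list(rows = g,
                                    S = which(obs[g[1], ] & gtype)))
  y0 <- y; y0[!pres] <- 0
  Yobs <- y0 * obs
  obsg <- obs & rep(gtype, each = n)
  cens_rows <- which(has_cens)
  cens_groups <- list()
  if (length(cens_rows)) {
    ck <- as.vector((obsg[cens_rows, , drop = FALSE] %*%
                       (2^(seq_len(M) - 1))) +
                      (cens[cens_rows, , drop = FALSE] %*%
                         (2^(seq_len(M) - 1))) * 2^M)
    cens_groups <- lapply(split(seq_along(cens_rows), ck), function(jj) {
      i1 <- cens_rows[jj[1]]
      list(jj = jj, rows = cens_rows[jj],
           S = which(obsg[i1, ]), Cm = which(cens[i1, ]))
    })
    cens_groups <- unname(cens_groups)
  }
  list(n = n, M = M, gtype = gtype, pres = pres * 1, obs = obs,
       obsg = obsg,
       has_cens = has_cens, groups = unname(groups),
       cens_rows = cens_rows, cens_groups = cens_groups, y0 = y0,
       Yobs = Yobs, Y2obs = Yobs * y0,
       ygroups = lapply(unname(groups), function(g)
         y[g$rows, g$S, drop = FALSE]))
}

.fmm_estep <- function(params, items, Q = 21L, want_stats = FALSE,
                       layout = NULL) {
  y <- items$y; types <- items$types; cens <- items$censored
  n <- nrow(y); K <- params$K; M <- params$M
  L <- layout %||% .fmm_layout(items)
  gh <- if (length(L$cens_rows)) gauss_hermite(Q) else NULL

  logf <- matrix(0, n, K)     # log f_k(y_i)
  m1 <- matrix(0, n, K)       # E[eta | y_i, k]
  m2 <- matrix(0, n, K)       # E[eta^2 | y_i, k]
  cens_st <- vector("list", K)

  bern <- which(types == "bernoulli")
  for (k in seq_len(K)) {
    Ik <- params$intercept[k, ]; Fk <- params$loading[k, ]
    th <- params$resid[k, ]
    ak <- params$alpha[k]
    pk <- if (params$has_factor) params$psi[k] else NA_real_
    lf <- numeric(n)
    # bernoulli items carry no loading: a plain additive term
    for (m in bern) {
      p <- min(max(stats::plogis(Ik[m]), 1e-12), 1 - 1e-12)
      lf <- lf + y[, m] * (log(p) - log1p(-p)) + log1p(-p)
    }
    for (gi in seq_along(L$groups)) {
      g <- L$groups[[gi]]$rows
      S <- L$groups[[gi]]$S
      if (length(S) == 0L) next
      yg <- L$ygroups[[gi]]
      mu <- Ik[S] + Fk[S] * ak
      d <- yg - rep(mu, each = length(g))
      if (params$has_factor) {
        b <- as.vector(d %*% (Fk[S] / th[S]))        # sum d F / theta
        a <- sum(Fk[S]^2 / th[S])
        v <- 1 / (1 / pk + a)
        qf <- as.vector(d^2 %*% (1 / th[S])) - v * b^2
        ld <- sum(log(th[S])) + log1p(pk * a)
        lf[g] <- lf[g] - 0.5 * (length(S) * log(2 * pi) + ld + qf)
        mu_post <- ak + v * b
        m1[g, k] <- mu_post
        m2[g, k] <- mu_post^2 + v
      } else {
        lf[g] <- lf[g] - 0.5 * (as.vector(d^2 %*% (1 / th[S])) +
                                  sum(log(2 * pi * th[S])))
      }
    }
    if (length(L$cens_rows)) {
      cs <- .fmm_censored_rows(L$cens_groups, length(L$cens_rows), y,
                               Ik, Fk, th, ak, pk, params$has_factor,
                               items$floors, gh, want_stats)
      lf[L$cens_rows] <- lf[L$cens_rows] + cs$logf
      m1[L$cens_rows, k] <- cs$m1
      m2[L$cens_rows, k] <- cs$m2
      if (want_stats) cens_st[[k]] <- cs$trunc
    }
    logf[, k] <- lf
  }

  A <- logf + rep(log(params$pi), each = n)
  mx <- A[cbind(seq_len(n), max.col(A, ties.method = "first"))]
  W <- exp(A - mx)
  rs <- rowSums(W)
  ll <- sum(mx + log(rs))
  w <- W / rs
  out <- list(loglik = ll, w = w)
  if (!want_stats) return(out)

  # sufficient statistics as K x M matrices via crossproducts
  U1 <- w * m1
  U2 <- w * m2
  st <- list(nk = colSums(w), fm1 = colSums(U1), fm2 = colSums(U2),
             Sy = t(crossprod(L$Yobs, w)), Sy2 = t(crossprod(L$Y2obs, w)),
             Sye = t(crossprod(L$Yobs, U1)), Se = t(crossprod(L$pres, U1)),
             Se2 = t(crossprod(L$pres, U2)), Sw = t(crossprod(L$pres, w)))
  # censored-cell corrections (expected truncated moments)
  if (length(L$cens_rows)) {
    for (k in seq_len(K)) {
      for (key in names(cens_st[[k]])) {
        m <- as.integer(key)
        tr <- cens_st[[k]][[key]]
        cw <- w[tr$rows, k]
        st$Sy[k, m] <- st$Sy[k, m] + sum(cw * tr$Ey)
        st$Sy2[k, m] <- st$Sy2[k, m] + sum(cw * tr$Ey2)
        st$Sye[k, m] <- st$Sye[k, m] + sum(cw * tr$Eye)
      }
    }
  }
  out$stats <- st
  out
}

# exact-enough treatment of rows carrying censored cells: per-row adaptive
# Gauss-Hermite over the factor, recentred at the posterior given the row's
# uncensored cells; returns log f, conditional factor moments and the
# truncated-cell moments (E[y*], E[y*^2], E[y* eta]) needed by the M-step
.fmm_censored_rows <- function(cens_groups, nr, y, Ik, Fk, th, ak, pk,
                               has_factor, floors, gh, want_stats) {
  logf <- numeric(nr); m1 <- numeric(nr); m2 <- numeric(nr)
  trunc <- list()
  lgw <- log(gh$weights)
  Q <- length(gh$nodes)
  l2pi <- log(2 * pi)
  for (grp in cens_groups) {
    jj <- grp$jj                         # positions within the censored set
    ii <- grp$rows
    ng <- length(jj)
    S <- grp$S
    Cm <- grp$Cm
    if (!has_factor) {
      # no factor: the censored cells contribute a constant tail per class
      lf <- 0
      if (length(S))
        lf <- -0.5 * (as.vector((y[ii, S, drop = FALSE] -
                                   rep(Ik[S], each = ng))^2 %*% (1 / th[S])) +
                        sum(l2pi + log(th[S])))
      for (m in Cm)
        lf <- lf + stats::pnorm((floors[m] - Ik[m]) / sqrt(th[m]),
                                log.p = TRUE)
      logf[jj] <- lf
      if (want_stats) {
        for (m in Cm) {
          z <- (floors[m] - Ik[m]) / sqrt(th[m])
          lam <- exp(stats::dnorm(z, log = TRUE) -
                       stats::pnorm(z, log.p = TRUE))
          Ey <- Ik[m] - sqrt(th[m]) * lam
          Ey2 <- Ik[m]^2 + th[m] - sqrt(th[m]) * (floors[m] + Ik[m]) * lam
          key <- as.character(m)
          tr <- trunc[[key]] %||% list(rows = integer(0), Ey = numeric(0),
                                       Ey2 = numeric(0), Eye = numeric(0))
          tr$rows <- c(tr$rows, ii)
          tr$Ey <- c(tr$Ey, rep(Ey, ng))
          tr$Ey2 <- c(tr$Ey2, rep(Ey2, ng))
          tr$Eye <- c(tr$Eye, rep(0, ng))
          trunc[[key]] <- tr
        }
      }
      next
    }
    if (has_factor) {
      d <- y[ii, S, drop = FALSE] - rep(Ik[S] + Fk[S] * ak, each = ng)
      b <- as.vector(d %*% (Fk[S] / th[S]))
      a <- sum(Fk[S]^2 / th[S])
      v <- 1 / (1 / pk + a)
      mu_p <- ak + v * b                 # ng
      eta <- outer(mu_p, sqrt(2 * v) * gh$nodes, `+`)       # ng x Q
      lnode <- rep(lgw, each = ng) - 0.5 * (log(pk) - log(v)) -
        0.5 * (eta - ak)^2 / pk + 0.5 * (eta - mu_p)^2 / v
      for (m in S)
        lnode <- lnode - 0.5 * (l2pi + log(th[m]) +
                                  (y[ii, m] - Ik[m] - Fk[m] * eta)^2 / th[m])
    }
    for (m in Cm)
      lnode <- lnode + stats::pnorm((floors[m] - (Ik[m] + Fk[m] * eta)) /
                                      sqrt(th[m]), log.p = TRUE)
    mmax <- lnode[cbind(seq_len(ng), max.col(lnode, ties.method = "first"))]
    wq <- exp(lnode - mmax)
    Z <- rowSums(wq)
    logf[jj] <- mmax + log(Z)
    wq <- wq / Z
    m1[jj] <- rowSums(wq * eta)
    m2[jj] <- rowSums(wq * eta^2)
    if (want_stats) {
      for (m in Cm) {
        mu <- Ik[m] + Fk[m] * eta
        sg <- sqrt(th[m])
        z <- (floors[m] - mu) / sg
        lam <- exp(stats::dnorm(z, log = TRUE) -
                     stats::pnorm(z, log.p = TRUE))
        Ey <- mu - sg * lam
        Ey2 <- mu^2 + th[m] - sg * (floors[m] + mu) * lam
        key <- as.character(m)
        tr <- trunc[[key]] %||% list(rows = integer(0), Ey = numeric(0),
                                     Ey2 = numeric(0), Eye = numeric(0))
        tr$rows <- c(tr$rows, ii)
        tr$Ey <- c(tr$Ey, rowSums(wq * Ey))
        tr$Ey2 <- c(tr$Ey2, rowSums(wq * Ey2))
        tr$Eye <- c(tr$Eye, rowSums(wq * Ey * eta))
        trunc[[key]] <- tr
      }
    }
  }
  list(logf = logf, m1 = m1, m2 = m2, trunc = trunc)
}

#' Observed-data log-likelihood of a factor mixture model
#'
#' \eqn{\sum_i \log \sum_k \pi_k f_k(y_i)}, where \eqn{f_k} marginalizes the
#' factor by `n_quad`-point adaptive Gauss-Hermite quadrature (items are
#' conditionally independent given class and factor); latent profile models
#' need no quadrature.
#'
#' @param params an [fmm_params()].
#' @param items an [fmm_item_matrix()].
#' @param n_quad quadrature points (default 61; only rows with censored cells are integrated numerically).
#' @return scalar log-likelihood.
#' @export
fmm_loglik <- function(params, items, n_quad = 61L) {
  .fmm_estep(params, items, Q = n_quad)$loglik
}

# parameter initialization for one EM start
.fmm_init <- function(items, spec, start_seed) {
  y <- items$y; types <- items$types
  K <- spec$K; M <- spec$M
  set.seed(start_seed)
  ycc <- y[, types %in% c("gaussian", "censored"), drop = FALSE]
  if (K > 1L) {
    km <- tryCatch(stats::kmeans(scale(ycc), centers = K, nstart = 1,
                                 iter.max = 30),
                   error = function(e) NULL)
    z <- if (is.null(km)) sample.int(K, nrow(y), replace = TRUE) else
      km$cluster
  } else z <- rep(1L, nrow(y))
  shares <- pmax(tabulate(z, K), 1) / sum(pmax(tabulate(z, K), 1))

  a <- y[, spec$anchor] - mean(y[, spec$anchor])
  va <- stats::var(a)
  cl_mean_a <- vapply(1:K, function(k) mean(a[z == k]), 0)
  if (any(!is.finite(cl_mean_a))) cl_mean_a[!is.finite(cl_mean_a)] <- 0

  intercept <- matrix(0, K, M); loading <- matrix(0, K, M)
  resid <- matrix(NA_real_, K, M)
  alpha <- rep(0, K); psi <- rep(NA_real_, K)
  if (spec$has_factor) {
    if (spec$factor_means_free) alpha <- cl_mean_a - min(cl_mean_a)
    wv <- mean(vapply(1:K, function(k)
      if (sum(z == k) > 1) stats::var(a[z == k]) else va, 0))
    psi <- rep(max(wv * 0.6, va * 1e-3), K) *
      stats::runif(K, 0.8, 1.25)
  }
  for (m in seq_len(M)) {
    tp <- types[m]
    if (tp == "bernoulli") {
      if (spec$intercepts_vary) {
        p <- vapply(1:K, function(k) mean(y[z == k, m]), 0)
      } else p <- rep(mean(y[, m]), K)
      p <- pmin(pmax(p, 0.02), 0.98)
      intercept[, m] <- stats::qlogis(p)
      next
    }
    rows <- if (tp == "magnitude") !is.na(y[, m]) else rep(TRUE, nrow(y))
    ym <- y[rows, m]
    vy <- stats::var(ym)
    FF <- if (!spec$has_factor) 0 else if (m == spec$anchor) 1 else
      stats::cov(ym, a[rows]) / va
    loading[, m] <- FF
    if (spec$intercepts_vary) {
      I <- vapply(1:K, function(k) {
        sel <- rows & z == k
        if (any(sel)) mean(y[sel, m]) else mean(ym)
      }, 0)
    } else {
      I <- rep(mean(ym) - FF * sum(shares * alpha), K)
    }
    intercept[, m] <- I * stats::runif(1, 0.97, 1.03)
    th0 <- max(vy * 0.5, vy * 1e-3, 1e-6)
    resid[, m] <- th0 * stats::runif(K, 0.8, 1.25)
  }
  fmm_params(shares, intercept, loading, resid, alpha, psi,
             item_models = types, floors = items$floors,
             anchor = spec$anchor)
}

# one M-step from the E-step sufficient statistics
.fmm_mstep <- function(st, params, spec, var_floor) {
  K <- spec$K; M <- spec$M; types <- spec$item_models
  nk <- st$nk
  n <- sum(nk)
  params$pi <- nk / n

  for (m in seq_len(M)) {
    tp <- types[m]
    if (tp == "bernoulli") {
      if (spec$intercepts_vary) {
        p <- st$Sy[, m] / st$Sw[, m]
      } else {
        p <- rep(sum(st$Sy[, m]) / sum(st$Sw[, m]), K)
      }
      p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
      params$intercept[, m] <- stats::qlogis(p)
      next
    }
    Sy <- st$Sy[, m]; Sy2 <- st$Sy2[, m]; Sye <- st$Sye[, m]
    Se <- st$Se[, m]; Se2 <- st$Se2[, m]; Sw <- st$Sw[, m]
    is_anchor <- spec$has_factor && m == spec$anchor
    no_load <- !spec$has_factor
    # invariant coefficients pooled over classes with class-specific
    # residual variances must weight each class by 1/theta_k (conditional
    # maximization at the current theta; theta is then updated at the new
    # coefficients — both steps increase the EM objective)
    wgt <- if (spec$resid_vary) 1 / params$resid[, m] else rep(1, K)

    if (no_load) {
      FF <- rep(0, K)
      I <- Sy / Sw
    } else if (is_anchor) {
      FF <- rep(1, K)
      I <- if (spec$intercepts_vary) (Sy - Se) / Sw else
        rep(sum(wgt * (Sy - Se)) / sum(wgt * Sw), K)
    } else if (spec$loadings_vary && spec$intercepts_vary) {
      FF <- I <- numeric(K)
      for (k in 1:K) {
        den <- Se2[k] - Se[k]^2 / Sw[k]
        FF[k] <- if (den > 1e-12) (Sye[k] - Sy[k] * Se[k] / Sw[k]) / den else 0
        I[k] <- (Sy[k] - FF[k] * Se[k]) / Sw[k]
      }
    } else if (spec$intercepts_vary) {            # common loading (WMI)
      den <- sum(wgt * (Se2 - Se^2 / Sw))
      FFc <- if (den > 1e-12) sum(wgt * (Sye - Sy * Se / Sw)) / den else 0
      FF <- rep(FFc, K)
      I <- (Sy - FFc * Se) / Sw
    } else {                                      # both invariant (SoMI/SiMI)
      A11 <- sum(wgt * Sw); A12 <- sum(wgt * Se); A22 <- sum(wgt * Se2)
      b1 <- sum(wgt * Sy); b2 <- sum(wgt * Sye)
      det <- A11 * A22 - A12^2
      if (abs(det) > 1e-12) {
        Ic <- (b1 * A22 - b2 * A12) / det
        FFc <- (A11 * b2 - A12 * b1) / det
      } else { Ic <- b1 / A11; FFc <- 0 }
      FF <- rep(FFc, K); I <- rep(Ic, K)
    }
    params$loading[, m] <- FF
    params$intercept[, m] <- I
    rssk <- Sy2 - 2 * I * Sy - 2 * FF * Sye + I^2 * Sw + 2 * I * FF * Se +
      FF^2 * Se2
    th <- if (spec$resid_vary) rssk / Sw else rep(sum(rssk) / sum(Sw), K)
    params$resid[, m] <- pmax(th, var_floor[m])
  }

  if (spec$has_factor) {
    fm1 <- st$fm1
    fm2 <- st$fm2
    if (spec$factor_means_free) {
      alpha <- fm1 / nk
    } else alpha <- rep(0, K)
    psik <- fm2 / nk - 2 * alpha * fm1 / nk + alpha^2
    psi <- if (spec$factor_var_vary) psik else
      rep(sum(psik * nk) / n, K)
    psi_floor <- var_floor[spec$anchor]
    params$psi <- pmax(psi, psi_floor)
    if (spec$factor_means_free) {
      a0 <- min(alpha)
      alpha <- alpha - a0
      # identification shift: absorbed by the (class-invariant) intercepts
      params$intercept <- params$intercept + outer(rep(a0, K),
                                                   params$loading[1, ])
    }
    params$alpha <- alpha
  }
  params
}

.fmm_sort_classes <- function(params, spec) {
  if (params$K == 1L) return(params)
  key <- if (spec$has_factor && spec$factor_means_free) {
    params$alpha
  } else {
    params$intercept[, spec$anchor] +
      params$loading[, spec$anchor] * params$alpha
  }
  ord <- order(key)
  params$pi <- params$pi[ord]
  params$intercept <- params$intercept[ord, , drop = FALSE]
  params$loading <- params$loading[ord, , drop = FALSE]
  params$resid <- params$resid[ord, , drop = FALSE]
  params$alpha <- params$alpha[ord]
  params$psi <- params$psi[ord]
  if (spec$has_factor && spec$factor_means_free) {
    a0 <- params$alpha[1]
    params$alpha <- params$alpha - a0
    params$intercept <- params$intercept +
      outer(rep(a0, params$K), params$loading[1, ])
  }
  attr(params, "order") <- ord
  params
}

#' EM control settings for [fit_fmm()]
#'
#' @param n_quad Gauss-Hermite points for models with a factor and any
#'   censored/Bernoulli/two-part item (pure latent-profile models skip
#'   quadrature).
#' @param max_iter,tol stopping rule: the EM stops when the Aitken
#'   acceleration estimate of the remaining log-likelihood gain falls below
#'   `tol`, or after `max_iter` iterations.
#' @param short_iter iterations used for each random start before the best
#'   start is run to convergence (the classic short-run/long-run strategy).
#' @param class_floor minimum expected class count; a run whose smallest
#'   class drops below it is discarded as degenerate (mirroring stopped
#'   searches on real data).
#' @param var_floor_frac variance floor as a fraction of each item's marginal
#'   variance.
#' @return list of control settings.
#' @export
fmm_control <- function(n_quad = 61L, max_iter = 500L, tol = 1e-6,
                        short_iter = 12L, class_floor = 5,
                        var_floor_frac = 1e-4) {
  list(n_quad = as.integer(n_quad), max_iter = as.integer(max_iter),
       tol = tol, short_iter = as.integer(short_iter),
       class_floor = class_floor, var_floor_frac = var_floor_frac)
}

# run EM from given params; returns params/loglik/trace/flags
.fmm_em_run <- function(params, items, spec, control, max_iter, tol,
                        layout = NULL) {
  layout <- layout %||% .fmm_layout(items)
  var_floor <- control$var_floor_frac *
    apply(items$y, 2, stats::var, na.rm = TRUE)
  var_floor[spec$item_models == "bernoulli"] <- NA_real_
  trace <- numeric(0)
  ll1 <- ll2 <- -Inf
  degenerate <- FALSE
  converged <- FALSE
  floor_hit <- FALSE
  for (it in seq_len(max_iter)) {
    e <- .fmm_estep(params, items, Q = control$n_quad, want_stats = TRUE,
                    layout = layout)
    trace <- c(trace, e$loglik)
    nk <- colSums(e$w)
    if (min(nk) < control$class_floor) { degenerate <- TRUE; break }
    params <- .fmm_mstep(e$stats, params, spec, var_floor)
    if (any(params$resid <= var_floor * (1 + 1e-9), na.rm = TRUE))
      floor_hit <- TRUE
    # Aitken-accelerated stopping: estimate the likelihood asymptote from
    # the geometric EM tail and stop once the remaining gain is below tol
    ll <- e$loglik
    if (is.finite(ll2)) {
      a <- (ll - ll1) / (ll1 - ll2)
      gap <- if (is.finite(a) && a > 0 && a < 1)
        abs(ll1 + (ll - ll1) / (1 - a) - ll) else abs(ll - ll1)
      if (gap < tol) { converged <- TRUE; break }
    } else if (abs(ll - ll1) < tol) { converged <- TRUE; break }
    ll2 <- ll1
    ll1 <- ll
  }
  list(params = params, loglik = if (length(trace)) trace[length(trace)] else
    -Inf, trace = trace, degenerate = degenerate, converged = converged,
    floor_hit = floor_hit)
}

#' Fit a factor mixture model by EM
#'
#' Maximizes the observed-data likelihood under the constraint template of an
#' [fmm_spec()]: the E-step computes class posteriors and conditional factor
#' moments on the quadrature grid, the M-step solves the constrained weighted
#' least-squares updates in closed form (pooled across classes for invariant
#' blocks, Tobit moment imputation for censored cells). `n_starts` perturbed
#' k-means initializations are each run briefly; the best is iterated to
#' convergence. The log-likelihood is non-decreasing across iterations (up to
#' quadrature error) and the trace is kept for inspection. Runs in which a
#' class's expected count falls below the degeneracy floor are discarded and
#' flagged; if every start degenerates the best flagged run is returned
#' rather than an error.
#'
#' Classes are reported in increasing order of factor mean (strong/strict
#' invariance) or anchor-item class mean (other families), i.e. frailest
#' first for the frailty block.
#'
#' @param items an [fmm_item_matrix()].
#' @param spec an [fmm_spec()].
#' @param n_starts number of random starts (default 50; 1 is forced for
#'   K = 1, where the model has no label ambiguity).
#' @param seed RNG seed covering all starts.
#' @param control an [fmm_control()] list.
#' @param init optional [fmm_params()] (or list of them) used as additional
#'   deterministic starts — e.g. the solution of a nested model, which
#'   guarantees the richer model's likelihood is at least as high, or the
#'   observed estimates when refitting bootstrap replicates. With `init`
#'   supplied, `n_starts = 0` runs only the deterministic starts.
#' @return object of class `fmm_fit`: `spec`, `params`, `loglik`, `n_params`,
#'   `bic`, `posteriors`, `entropy` (relative entropy, `NA` for K = 1),
#'   `converged`, `degenerate`, `n_starts_used`, `trace`, `n`, `seed`.
#' @export
fit_fmm <- function(items, spec, n_starts = 50L, seed = 1L,
                    control = fmm_control(), init = NULL) {
  stopifnot(inherits(items, "fmm_items"), inherits(spec, "fmm_spec"))
  if (!identical(items$types, unname(spec$item_models)) &&
      !identical(unname(items$types), unname(spec$item_models)))
    stop("spec item models do not match the item matrix", call. = FALSE)
  n <- nrow(items$y)
  np <- n_parameters(spec)
  if (np >= n) stop(sprintf("spec has %d parameters but only %d subjects",
                            np, n), call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  if (is.null(init) && n_starts < 1L) n_starts <- 1L
  if (spec$K == 1L) n_starts <- min(n_starts, 1L)

  layout <- .fmm_layout(items)
  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    st <- .fmm_init(items, spec, start_seed = seed + 7919L * (s - 1L))
    runs[[s]] <- .fmm_em_run(st, items, spec, control,
                             max_iter = control$short_iter, tol = control$tol,
                             layout = layout)
  }
  if (!is.null(init)) {
    if (inherits(init, "fmm_params")) init <- list(init)
    for (ip in init) {
      stopifnot(inherits(ip, "fmm_params"), ip$K == spec$K)
      runs[[length(runs) + 1L]] <- .fmm_em_run(ip, items, spec, control,
                                               max_iter = control$short_iter,
                                               tol = control$tol,
                                               layout = layout)
    }
  }
  ok <- !vapply(runs, `[[`, TRUE, "degenerate")
  pool <- if (any(ok)) runs[ok] else runs
  lls <- vapply(pool, `[[`, 0, "loglik")
  best <- pool[[which.max(lls)]]
  if (!best$degenerate) {
    long <- .fmm_em_run(best$params, items, spec, control,
                        max_iter = control$max_iter, tol = control$tol,
                        layout = layout)
    long$trace <- c(best$trace, long$trace)
    best <- long
  }

  params <- .fmm_sort_classes(best$params, spec)
  e <- .fmm_estep(params, items, Q = control$n_quad, layout = layout)
  post <- e$w
  colnames(post) <- paste0("class", seq_len(spec$K))
  ent <- if (spec$K >= 2L) relative_entropy(post) else NA_real_
  out <- list(spec = spec, params = params, loglik = e$loglik,
              n_params = np, bic = -2 * e$loglik + np * log(n),
              posteriors = post, entropy = ent,
              converged = best$converged, degenerate = best$degenerate,
              any_degenerate_start = any(!ok),
              variance_floor_hit = best$floor_hit,
              n_starts_used = n_starts, trace = best$trace, n = n,
              seed = seed, control = control)
  class(out) <- "fmm_fit"
  out
}

#' @export
print.fmm_fit <- function(x, ...) {
  cat(sprintf("<fmm_fit> %s-%s K = %d: loglik = %.3f, BIC = %.2f, entropy = %s\n",
              x$spec$family, x$spec$variance, x$spec$K, x$loglik, x$bic,
              ifelse(is.na(x$entropy), "n/a", sprintf("%.3f", x$entropy))))
  if (x$degenerate)
    cat("  ** search degenerated: a class expected count fell below the floor\n")
  cat("  pi:", paste(formatC(x$params$pi, 3, format = "f"), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
logLik.fmm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
BIC.fmm_fit <- function(object, ...) object$bic

#' Posterior class probabilities and modal assignment
#'
#' Bayes-rule posteriors \eqn{P(k \mid y_i)} recomputed from the fitted
#' parameters, with the modal class (ties broken toward the lowest class
#' index).
#'
#' @param fit an `fmm_fit`.
#' @param items item matrix; defaults to the posteriors stored in the fit.
#' @return list with `posteriors` (n x K, rows sum to 1) and `modal`
#'   (integer class labels).
#' @export
posterior_probs <- function(fit, items = NULL) {
  stopifnot(inherits(fit, "fmm_fit"))
  post <- if (is.null(items)) fit$posteriors else
    .fmm_estep(fit$params, items, Q = fit$control$n_quad)$w
  list(posteriors = post, modal = max.col(post, ties.method = "first"))
}

#' Relative entropy of a posterior matrix
#'
#' \eqn{1 - \sum_i \sum_k -p_{ik} \ln p_{ik} / (n \ln K)}: 1 for perfectly
#' separated classes, 0 for uniformly uncertain assignment. Undefined for
#' K = 1 (returned as `NA`).
#'
#' @param posteriors n x K matrix with rows summing to 1.
#' @return scalar in [0, 1], or `NA` when K = 1.
#' @export
relative_entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  K <- ncol(posteriors)
  if (K < 2L) return(NA_real_)
  p <- pmin(pmax(posteriors, 1e-300), 1)
  H <- -sum(p * log(p))
  1 - H / (nrow(posteriors) * log(K))
}

#' Simulate an item matrix from factor mixture parameters
#'
#' Generates data from the model exactly as the likelihood sees it: class,
#' factor score, then items (gait-type items are censored at their floor;
#' two-part magnitudes are drawn only for occurrences). Used by the bootstrap
#' likelihood-ratio test and the Monte Carlo diagnostics.
#'
#' @param params an [fmm_params()].
#' @param n subjects.
#' @param seed RNG seed (optional).
#' @return an [fmm_item_matrix()].
#' @export
simulate_fmm <- function(params, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- params$K; M <- params$M; types <- params$item_models
  cls <- sample.int(K, n, replace = TRUE, prob = params$pi)
  eta <- if (params$has_factor)
    stats::rnorm(n, params$alpha[cls], sqrt(params$psi[cls])) else rep(0, n)
  y <- matrix(NA_real_, n, M)
  cn <- names(types) %||% paste0("item", seq_len(M))
  colnames(y) <- cn
  censored <- matrix(FALSE, n, M)
  for (m in seq_len(M)) {
    mu <- params$intercept[cls, m] + params$loading[cls, m] * eta
    tp <- types[m]
    if (tp == "bernoulli") {
      y[, m] <- stats::rbinom(n, 1L, stats::plogis(mu))
    } else if (tp == "magnitude") {
      next  # filled in below, once its occurrence column exists
    } else {
      y[, m] <- mu + stats::rnorm(n, 0, sqrt(params$resid[cls, m]))
      if (tp == "censored") {
        flag <- y[, m] <= params$floors[m]
        y[flag, m] <- params$floors[m]
        censored[, m] <- flag
      }
    }
  }
  occ_for <- attr(params, "occurrence_for")
  if (is.null(occ_for)) {
    occ_for <- rep(NA_integer_, M)
    bern <- which(types == "bernoulli")
    for (m in which(types == "magnitude"))
      occ_for[m] <- bern[which.min(abs(bern - m))]
  }
  for (m in which(types == "magnitude")) {
    occ <- y[, occ_for[m]]
    sel <- occ == 1
    mu <- params$intercept[cls, m] + params$loading[cls, m] * eta
    y[sel, m] <- mu[sel] + stats::rnorm(sum(sel), 0,
                                        sqrt(params$resid[cls[sel], m]))
    y[!sel, m] <- NA_real_
  }
  fmm_item_matrix(y, types = unname(types), floors = params$floors,
                  censored = censored, occurrence_for = occ_for)
}
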