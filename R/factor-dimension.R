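#' Compare one- versus two-factor structure of the components
#'
#' Likelihood-ratio comparison of maximum-likelihood factor analyses of the
#' five component scores (the weight-loss column uses kg, 0 for subjects
#' without loss). With five indicators the parameter-count difference between
#' the one- and two-factor solutions is 4, so the statistic is referred to a
#' chi-square with 4 degrees of freedom. The rotated two-factor loadings are
#' returned so the alignment of the second dimension (typically gait speed
#' and grip strength versus the exhaustion/activity/weight-loss set) can be
#' inspected rather than being imposed.
#'
#' @param items an [fmm_item_matrix()] with the standard six-item frailty
#'   block, or a plain numeric matrix of indicators.
#' @param m_null,m_alt factor counts under the null and alternative
#'   (default 1 vs 2).
#' @return list with `chi2`, `df`, `p`, `loglik_ratio_inputs` (the two model
#'   fit statistics) and `loadings_alt`.
#' @export
compare_factor_dimension <- function(items, m_null = 1L, m_alt = 2L) {
  if (inherits(items, "fmm_items")) {
    y <- items$y[, items$types %in% c("gaussian", "censored"), drop = FALSE]
    mg <- which(items$types == "magnitude")
    if (length(mg)) {
      kg <- items$y[, mg[1]]
      kg[is.na(kg)] <- 0
      y <- cbind(y, weight_lost_kg = kg)
    }
  } else y <- as.matrix(items)
  if (m_null > m_alt) stop("m_null must be <= m_alt (nested comparison)",
                           call. = FALSE)
  p <- ncol(y)
  dof <- function(m) ((p - m)^2 - (p + m)) / 2
  if (dof(m_alt) < 0)
    stop(sprintf("%d factors are not testable with %d indicators", m_alt, p),
         call. = FALSE)
  if (m_null == m_alt)
    return(list(chi2 = 0, df = 0L, p = 1,
                stat_null = NA_real_, stat_alt = NA_real_,
                loadings_alt = NULL))
  f0 <- stats::factanal(y, factors = m_null, rotation = "none",
                        control = list(nstart = 3, lower = 0.005))
  f1 <- stats::factanal(y, factors = m_alt, rotation = "varimax",
                        control = list(nstart = 3, lower = 0.005))
  chi2 <- max(unname(f0$STATISTIC - f1$STATISTIC), 0)
  df <- as.integer(dof(m_null) - dof(m_alt))
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       stat_null = unname(f0$STATISTIC), stat_alt = unname(f1$STATISTIC),
       loadings_alt = unclass(f1$loadings))
}
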