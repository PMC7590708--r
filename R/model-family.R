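# The measurement-invariance family. Classes always act through the
# "classification" intercepts I_kc; the factor-analytic block carries the
# continuum. Family members differ in which blocks vary across classes:
#
#   LCA   no factor block; intercepts vary            (latent profile analysis)
#   SiMI  intercepts & loadings invariant, ev only    (strict invariance)
#   SoMI  intercepts & loadings invariant             (strong invariance)
#   WMI   intercepts vary, loadings invariant         (weak invariance)
#   NMI   intercepts and loadings vary                (no invariance)
#
# "ev"/"uv": residual variances and the factor variance equal/unequal across
# classes. Identification: the anchor item's loading is fixed at 1; under
# SoMI/SiMI the class factor means are free with the lowest-mean class pinned
# at 0; under WMI/NMI all factor means are 0 (absorbed by the intercepts).

.family_levels <- c("LCA", "SiMI", "SoMI", "WMI", "NMI")

#' Specify a member of the factor-mixture model family
#'
#' Expands a family label, class count and variance structure into the
#' constraint template used by [fit_fmm()] and [n_parameters()].
#'
#' @param family one of `"LCA"`, `"SiMI"`, `"SoMI"`, `"WMI"`, `"NMI"`.
#' @param K number of latent classes (>= 1).
#' @param variance `"ev"` (residual and factor variances equal across classes)
#'   or `"uv"` (class-varying). `SiMI` requires `"ev"`: strict invariance is
#'   strong invariance plus equal variances, so a `SiMI-uv` request is an
#'   error.
#' @param item_models character vector of item models (see
#'   [fmm_item_matrix()]) or an `fmm_items` object; defaults to the six-item
#'   frailty block.
#' @param anchor index of the anchor item whose loading is fixed at 1
#'   (default: the first non-Bernoulli item).
#' @return object of class `fmm_spec` with the constraint flags
#'   (`intercepts_vary`, `loadings_vary`, `resid_vary`, `factor_var_vary`,
#'   `has_factor`, `factor_means_free`).
#' @export
fmm_spec <- function(family = c("LCA", "SiMI", "SoMI", "WMI", "NMI"),
                     K, variance = c("uv", "ev"),
                     item_models = frailty_item_models(), anchor = NULL) {
  family <- match.arg(family)
  variance <- match.arg(variance)
  K <- as.integer(K)
  stopifnot(K >= 1L)
  if (family == "SiMI" && variance == "uv")
    stop(paste("illegal combination SiMI-uv: strict measurement invariance is",
               "strong invariance plus equal residual and factor variances;",
               "use SoMI-uv or SiMI-ev"), call. = FALSE)
  if (inherits(item_models, "fmm_items")) item_models <- item_models$types
  M <- length(item_models)
  stopifnot(all(item_models %in% c("gaussian", "censored", "bernoulli",
                                   "magnitude")))
  if (is.null(anchor)) anchor <- which(item_models != "bernoulli")[1]
  has_factor <- family != "LCA"
  spec <- structure(list(
    family = family, K = K, variance = variance,
    item_models = item_models, M = M, anchor = as.integer(anchor),
    has_factor = has_factor,
    intercepts_vary = family %in% c("LCA", "WMI", "NMI") && K > 1L,
    loadings_vary = family == "NMI" && K > 1L,
    resid_vary = variance == "uv" && K > 1L,
    factor_var_vary = has_factor && variance == "uv" && K > 1L,
    factor_means_free = has_factor && family %in% c("SiMI", "SoMI") && K > 1L),
    class = "fmm_spec")
  spec
}

#' Default six-item frailty measurement block
#'
#' Exhaustion (anchor), physical activity, grip strength (Gaussian),
#' gait speed (left-censored), weight-loss occurrence (Bernoulli, no factor
#' loading) and weight-loss magnitude in kg (two-part conditional Gaussian).
#' @return named character vector of item models.
#' @export
frailty_item_models <- function() {
  c(exhaustion = "gaussian", physical_activity = "gaussian",
    grip_strength = "gaussian", gait_speed = "censored",
    weight_lost_any = "bernoulli", weight_lost_log_kg = "magnitude")
}

#' @export
print.fmm_spec <- function(x, ...) {
  cat(sprintf("<fmm_spec> %s-%s, K = %d, %d items, %d free parameters (%s)\n",
              x$family, x$variance, x$K, x$M, n_parameters(x),
              hypothesis_role(x)))
  invisible(x)
}

#' Count free parameters of a family member
#'
#' Counts the free cells of the expanded template under this package's
#' identification rules: anchor loading fixed at 1, Bernoulli items carry no
#' loading or residual variance, SoMI/SiMI factor means lose one cell to the
#' reference class, WMI/NMI factor means are all fixed at 0.
#'
#' @param spec an [fmm_spec()].
#' @return integer count.
#' @export
n_parameters <- function(spec) {
  stopifnot(inherits(spec, "fmm_spec"))
  K <- spec$K; tm <- spec$item_models
  kc <- function(vary) if (vary) K else 1L
  n <- K - 1L                                           # mixing
  n <- n + length(tm) * kc(spec$intercepts_vary)        # intercepts/thresholds
  loadable <- which(tm != "bernoulli")
  loadable <- setdiff(loadable, spec$anchor)
  if (spec$has_factor) {
    n <- n + length(loadable) * kc(spec$loadings_vary)
    n <- n + kc(spec$factor_var_vary)                   # factor variance(s)
    if (spec$factor_means_free) n <- n + (K - 1L)
  }
  n <- n + sum(tm != "bernoulli") * kc(spec$resid_vary) # residual variances
  as.integer(n)
}

#' Null/non-null role of a family member
#'
#' One-class models are the homogeneity null; SoMI/SiMI with K > 1 are the
#' null of a categorical approximation of a continuous process; LCA, WMI and
#' NMI with K > 1 are the non-null (syndrome-compatible) hypotheses.
#'
#' @param spec an [fmm_spec()].
#' @return `"null-one-class"`, `"null-categorical-approximation"` or
#'   `"non-null"`.
#' @export
hypothesis_role <- function(spec) {
  stopifnot(inherits(spec, "fmm_spec"))
  if (spec$K == 1L) return("null-one-class")
  if (spec$family %in% c("SiMI", "SoMI")) return("null-categorical-approximation")
  "non-null"
}

#' Is one family member nested in another?
#'
#' Nesting holds when every constraint of the alternative is free at least
#' wherever the null's is, on the same items: smaller or equal K, `ev` within
#' `uv`, and family rank SiMI/SoMI within WMI within NMI; LCA is nested
#' within LCA and (via zero loadings) within WMI/NMI, but not within
#' SoMI/SiMI, and no factor model is nested within LCA.
#'
#' @param spec_null,spec_alt [fmm_spec()] objects on the same item set.
#' @return logical.
#' @export
is_nested <- function(spec_null, spec_alt) {
  stopifnot(inherits(spec_null, "fmm_spec"), inherits(spec_alt, "fmm_spec"))
  if (!identical(spec_null$item_models, spec_alt$item_models)) return(FALSE)
  if (spec_null$K > spec_alt$K) return(FALSE)
  vr <- c(ev = 1L, uv = 2L)
  if (vr[[spec_null$variance]] > vr[[spec_alt$variance]]) return(FALSE)
  rank <- c(LCA = 0L, SiMI = 1L, SoMI = 1L, WMI = 2L, NMI = 3L)
  rn <- rank[[spec_null$family]]; ra <- rank[[spec_alt$family]]
  if (spec_alt$family == "LCA") return(spec_null$family == "LCA")
  if (spec_null$family == "LCA") return(ra >= 2L || spec_null$K == 1L)
  rn <= ra
}

#' The canonical family members at their fitted class counts
#'
#' Enumerates the basic members of the model family (latent profile analysis
#' with equal/unequal variances, strict, strong, weak and no measurement
#' invariance with equal/unequal variances) with their hypothesis roles and
#' free-parameter counts at a given K.
#'
#' @param K class count used for the listing (default 2).
#' @param item_models item set (default the six-item frailty block).
#' @return data.frame with `family`, `variance`, `K`, `role`, `n_params`.
#' @export
family_members <- function(K = 2L, item_models = frailty_item_models()) {
  members <- list(c("LCA", "ev"), c("LCA", "uv"), c("SiMI", "ev"),
                  c("SoMI", "uv"), c("WMI", "ev"), c("WMI", "uv"),
                  c("NMI", "ev"), c("NMI", "uv"))
  do.call(rbind, lapply(members, function(m) {
    sp <- fmm_spec(m[1], K, m[2], item_models)
    data.frame(family = m[1], variance = m[2], K = K,
               role = hypothesis_role(sp), n_params = n_parameters(sp))
  }))
}

#' Serialize a spec to JSON (and back)
#' @param spec an [fmm_spec()].
#' @param path file path.
#' @return `write_spec` returns `path` invisibly; `read_spec` an `fmm_spec`.
#' @export
write_spec <- function(spec, path) {
  x <- unclass(spec)
  x$item_models <- as.list(x$item_models)  # keep item names through JSON
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fmm_spec(x$family, x$K, x$variance, unlist(x$item_models),
           anchor = x$anchor)
}
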