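#' Generate a synthetic frailty cohort
#'
#' Draws a subject-level table from the generative model described in
#' [cohort_config()]: latent class first, then a within-class factor score,
#' then the four continuous components (with additive male shifts and
#' left-censored gait speed), the two-part weight-loss item, sex, height, BMI
#' and the class-profiled covariate block. Two calls with an identical config
#' produce bit-identical tables.
#'
#' @param config a [cohort_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return a `data.frame` of class `frail_cohort` with one row per subject:
#'   components `exhaustion`, `physical_activity`, `grip_strength`,
#'   `gait_speed` (+ `gait_censored`), `weight_lost_any`, `weight_lost_kg`
#'   (`NA` when no loss), `sex` (`"F"`/`"M"`), `height_cm`, `bmi`, the
#'   covariate block, and `true_class`. The gait floor is kept in
#'   `attr(, "gait_floor")`.
#' @examples
#' cohort <- generate_cohort(default_config_frele(n_subjects = 200))
#' table(cohort$true_class)
#' @export
generate_cohort <- function(config, seed = NULL) {
  validate_cohort_config(config)
  if (is.null(seed)) seed <- config$seed
  n <- config$n_subjects
  K <- config$K_true

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  cls <- sample.int(K, n, replace = TRUE, prob = config$mixing)
  eta <- stats::rnorm(n, config$factor_means[cls],
                      sqrt(config$factor_variances[cls]))
  sex <- stats::rbinom(n, 1L, config$sex_ratio)        # 1 = male

  comp <- matrix(NA_real_, n, 4,
                 dimnames = list(NULL, .continuous_components))
  for (c in 1:4) {
    comp[, c] <- config$intercepts[cls, c] + config$loadings[c] * eta +
      stats::rnorm(n, 0, sqrt(config$residual_variances[cls, c])) +
      config$sex_shift[c] * sex
  }
  gait_censored <- comp[, "gait_speed"] <= config$gait_censor_floor
  comp[gait_censored, "gait_speed"] <- config$gait_censor_floor

  p_occ <- stats::plogis(config$weightloss_occurrence_logit[cls])
  wl_any <- stats::rbinom(n, 1L, p_occ)
  wl_kg <- rep(NA_real_, n)
  losers <- wl_any == 1L
  if (any(losers)) {
    m <- config$weightloss_magnitude_mean_kg[cls[losers]]
    s <- config$weightloss_magnitude_sd_kg[cls[losers]]
    sdlog <- sqrt(log1p((s / m)^2))
    meanlog <- log(m) - sdlog^2 / 2
    wl_kg[losers] <- stats::rlnorm(sum(losers), meanlog, sdlog)
  }

  height <- ifelse(sex == 1L, stats::rnorm(n, 169.55, 7.0),
                   stats::rnorm(n, 155.81, 6.0))
  bmi <- pmax(stats::rnorm(n, 27.5, 4.5), 16)

  cov <- as.data.frame(matrix(NA_real_, n, length(.covariate_fields),
                              dimnames = list(NULL, .covariate_fields)))
  disp <- c(age = 6, education = 1.5, self_rated_health = 0.8,
            chronic_diseases = 1.5, cognition = 2.5)
  for (nm in .covariate_fields) {
    mu <- config$covariate_profiles[cls, nm]
    if (.covariate_binary[[nm]]) {
      cov[[nm]] <- stats::rbinom(n, 1L, mu)
    } else {
      cov[[nm]] <- stats::rnorm(n, mu, disp[[nm]])
    }
  }
  cov$chronic_diseases <- pmax(cov$chronic_diseases, 0)

  out <- data.frame(
    exhaustion = comp[, "exhaustion"],
    physical_activity = comp[, "physical_activity"],
    grip_strength = comp[, "grip_strength"],
    gait_speed = comp[, "gait_speed"],
    gait_censored = gait_censored,
    weight_lost_any = wl_any,
    weight_lost_kg = wl_kg,
    sex = factor(ifelse(sex == 1L, "M", "F"), levels = c("F", "M")),
    height_cm = height, bmi = bmi)
  out <- cbind(out, cov)
  out$true_class <- cls
  attr(out, "gait_floor") <- config$gait_censor_floor
  class(out) <- c("frail_cohort", "data.frame")
  out
}

#' Analytic per-class component means implied by a config
#'
#' Means of the four uncensored continuous components given class, i.e.
#' \eqn{I_{kc} + F_c \alpha_k + s_c P(\mathrm{male})} where \eqn{s_c} is the
#' male shift. Used by moment-matching checks.
#'
#' @param config a [cohort_config()].
#' @return `K_true` x 4 matrix.
#' @export
analytic_component_means <- function(config) {
  validate_cohort_config(config)
  m <- config$intercepts +
    outer(config$factor_means, config$loadings) +
    matrix(rep(config$sex_shift * config$sex_ratio, each = config$K_true),
           nrow = config$K_true)
  dimnames(m) <- list(paste0("class", seq_len(config$K_true)),
                      .continuous_components)
  m
}

#' Read or write a cohort as CSV
#'
#' Plain-text round trip for [generate_cohort()] tables; the gait floor
#' travels in a `# gait_floor:` header comment so censoring information
#' survives the trip.
#'
#' @param cohort a `frail_cohort` data.frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly, `read_cohort` the cohort.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gait_floor: %.17g",
                     attr(cohort, "gait_floor") %||% NA_real_), con)
  utils::write.csv(as.data.frame(cohort), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1L)
  floor <- NA_real_
  skip <- 0L
  if (startsWith(first, "# gait_floor:")) {
    floor <- as.numeric(sub("# gait_floor:", "", first))
    skip <- 1L
  }
  out <- utils::read.csv(path, skip = skip)
  out$sex <- factor(out$sex, levels = c("F", "M"))
  if ("gait_censored" %in% names(out))
    out$gait_censored <- as.logical(out$gait_censored)
  attr(out, "gait_floor") <- floor
  class(out) <- c("frail_cohort", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
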