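# Cut-point derivation and dichotomization follow the classic phenotype
# operationalization: empirical first quintiles within strata defined by sex,
# sex x height-half, or sex x BMI-quintile; weight loss uses the fixed
# >= 10% of usual weight or >= 4.5 kg rule and is never threshold-derived.

#' Derive stratified deficit cut points from a cohort
#'
#' Computes the empirical thresholds that dichotomize the continuous frailty
#' components:
#' \itemize{
#'   \item exhaustion: unstratified first quintile of the SF-36 vitality score;
#'   \item low activity: sex-stratified first quintile of the PASE score;
#'   \item slowness: first quintile of gait speed within sex x height half
#'     (above/below the sex-specific mean height, recomputed per cohort);
#'   \item weakness: first quintile of grip strength within sex x BMI quintile;
#'   \item weight loss: fixed rule, no empirical threshold.
#' }
#' The first quintile is the empirical 20th percentile with linear
#' interpolation between closest ranks (`stats::quantile` type 7). Being at or
#' below the threshold counts as a deficit.
#'
#' @param cohort a `frail_cohort` (or any data.frame with the component,
#'   `sex`, `height_cm` and `bmi` columns).
#' @param min_per_stratum minimum subjects required in every stratum.
#' @return an object of class `cutpoint_table`: a data.frame with columns
#'   `component`, `stratum`, `threshold`, `direction` plus the stratum
#'   boundary metadata in attributes.
#' @export
derive_cut_points <- function(cohort, min_per_stratum = 5L) {
  stopifnot(all(c("exhaustion", "physical_activity", "grip_strength",
                  "gait_speed", "sex", "height_cm", "bmi") %in% names(cohort)))
  q20 <- function(x) unname(stats::quantile(x, 0.20, type = 7, names = FALSE))
  check <- function(idx, label) {
    if (sum(idx) == 0L)
      stop(sprintf("empty stratum: %s", label), call. = FALSE)
    if (sum(idx) < min_per_stratum)
      stop(sprintf("stratum %s has %d subjects (< %d required)",
                   label, sum(idx), min_per_stratum), call. = FALSE)
  }
  rows <- list()
  add <- function(component, stratum, threshold)
    rows[[length(rows) + 1L]] <<- data.frame(
      component = component, stratum = stratum, threshold = threshold,
      direction = "below", stringsAsFactors = FALSE)

  add("exhaustion", "all", q20(cohort$exhaustion))

  height_mean <- c(F = NA_real_, M = NA_real_)
  bmi_breaks <- list()
  for (s in c("F", "M")) {
    in_sex <- cohort$sex == s
    check(in_sex, sprintf("sex=%s", s))
    add("low_activity", sprintf("sex=%s", s),
        q20(cohort$physical_activity[in_sex]))

    hm <- mean(cohort$height_cm[in_sex])
    height_mean[s] <- hm
    for (half in c("short", "tall")) {
      idx <- in_sex & (if (half == "short") cohort$height_cm <= hm
                       else cohort$height_cm > hm)
      label <- sprintf("sex=%s,height=%s", s, half)
      check(idx, label)
      add("slowness", label, q20(cohort$gait_speed[idx]))
    }

    br <- unname(stats::quantile(cohort$bmi[in_sex], seq(0.2, 0.8, 0.2),
                                 type = 7))
    bmi_breaks[[s]] <- br
    cuts <- cut(cohort$bmi[in_sex], c(-Inf, br, Inf), labels = FALSE)
    for (qq in 1:5) {
      idx_in <- cuts == qq
      label <- sprintf("sex=%s,bmi_q=%d", s, qq)
      check2 <- in_sex
      check2[in_sex] <- idx_in
      check(check2, label)
      add("weakness", label, q20(cohort$grip_strength[in_sex][idx_in]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "height_mean") <- height_mean
  attr(out, "bmi_breaks") <- bmi_breaks
  attr(out, "weight_loss_rule") <- "any unintentional loss >= 10% of usual weight or >= 4.5 kg"
  class(out) <- c("cutpoint_table", "data.frame")
  out
}

#' @export
print.cutpoint_table <- function(x, ...) {
  cat("<cutpoint_table> first-quintile deficit thresholds (deficit = value <= threshold)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a cut-point table to JSON (and back)
#'
#' @param cuts a `cutpoint_table`.
#' @param path file path.
#' @return `write_cut_points` returns `path` invisibly; `read_cut_points` a
#'   `cutpoint_table`.
#' @export
write_cut_points <- function(cuts, path) {
  payload <- list(
    thresholds = as.data.frame(cuts),
    height_mean = as.list(attr(cuts, "height_mean")),
    bmi_breaks = attr(cuts, "bmi_breaks"),
    weight_loss_rule = attr(cuts, "weight_loss_rule"))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_cut_points
#' @export
read_cut_points <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- as.data.frame(x$thresholds)
  attr(out, "height_mean") <- unlist(x$height_mean)
  attr(out, "bmi_breaks") <- lapply(x$bmi_breaks, as.numeric)
  attr(out, "weight_loss_rule") <- x$weight_loss_rule
  class(out) <- c("cutpoint_table", "data.frame")
  out
}

.lookup_threshold <- function(cuts, component, stratum) {
  hit <- cuts$component == component & cuts$stratum == stratum
  if (sum(hit) != 1L)
    stop(sprintf("subject falls in uncovered stratum `%s` for component `%s`",
                 stratum, component), call. = FALSE)
  cuts$threshold[hit]
}

#' Dichotomize components into the five deficit indicators
#'
#' Applies a [derive_cut_points()] table: a deficit is scored when the score
#' is at or below its stratum threshold (boundary inclusive), and weight loss
#' uses the occurrence indicator from the two-part item. Columns are ordered
#' weight loss, exhaustion, low activity, slowness, weakness.
#'
#' @param cohort a `frail_cohort`.
#' @param cuts a `cutpoint_table` covering every stratum present in `cohort`.
#' @return an `n x 5` 0/1 matrix of class `binary_components`.
#' @export
dichotomize <- function(cohort, cuts) {
  n <- nrow(cohort)
  out <- matrix(0L, n, 5, dimnames = list(NULL, .deficit_components))
  out[, "weight_loss"] <- as.integer(cohort$weight_lost_any == 1L)
  out[, "exhaustion"] <-
    as.integer(cohort$exhaustion <= .lookup_threshold(cuts, "exhaustion", "all"))

  hm <- attr(cuts, "height_mean")
  brs <- attr(cuts, "bmi_breaks")
  for (s in c("F", "M")) {
    idx <- cohort$sex == s
    if (!any(idx)) next
    out[idx, "low_activity"] <- as.integer(
      cohort$physical_activity[idx] <=
        .lookup_threshold(cuts, "low_activity", sprintf("sex=%s", s)))
    half <- ifelse(cohort$height_cm[idx] <= hm[[s]], "short", "tall")
    for (hh in unique(half)) {
      thr <- .lookup_threshold(cuts, "slowness",
                               sprintf("sex=%s,height=%s", s, hh))
      sub <- which(idx)[half == hh]
      out[sub, "slowness"] <- as.integer(cohort$gait_speed[sub] <= thr)
    }
    qq <- cut(cohort$bmi[idx], c(-Inf, brs[[s]], Inf), labels = FALSE)
    for (q in unique(qq)) {
      thr <- .lookup_threshold(cuts, "weakness",
                               sprintf("sex=%s,bmi_q=%d", s, q))
      sub <- which(idx)[qq == q]
      out[sub, "weakness"] <- as.integer(cohort$grip_strength[sub] <= thr)
    }
  }
  class(out) <- c("binary_components", class(out))
  out
}

#' Deficit count and robust / prefrail / frail classification
#'
#' @param binary a `binary_components` matrix from [dichotomize()].
#' @return data.frame with `deficit_count` (0-5) and `frailty_class`
#'   (`robust` = 0, `prefrail` = 1-2, `frail` = 3+).
#' @export
frailty_index <- function(binary) {
  stopifnot(is.matrix(binary), ncol(binary) == 5, all(binary %in% 0:1))
  count <- as.integer(rowSums(binary))
  cls <- cut(count, c(-1, 0, 2, 5),
             labels = c("robust", "prefrail", "frail"))
  data.frame(deficit_count = count, frailty_class = cls)
}

#' Encode a cohort as the six-item block of the factor mixture model
#'
#' Deterministic re-encoding of the component block: the four continuous
#' items, the gait censoring flags (propagated from the cohort with the floor
#' kept as item metadata), and the two weight-loss items (binary occurrence,
#' magnitude defined only for losers). The magnitude enters the measurement
#' model as log(kg): weight lost is strongly right-skewed on the kg scale,
#' and a Gaussian item on the log scale keeps skewness from masquerading as
#' latent classes. [decode_fmm_items()] maps it back to kg.
#'
#' @param cohort a `frail_cohort`.
#' @return an `fmm_items` object (see [fmm_item_matrix()]).
#' @export
encode_fmm_items <- function(cohort) {
  if (any(cohort$weight_lost_kg < 0, na.rm = TRUE))
    stop("negative weight_lost_kg", call. = FALSE)
  if (any((cohort$weight_lost_any == 1L) != !is.na(cohort$weight_lost_kg)))
    stop("weight_lost_kg must be defined exactly for subjects with weight_lost_any = 1",
         call. = FALSE)
  floor <- attr(cohort, "gait_floor")
  if (is.null(floor) || is.na(floor)) {
    floor <- if (any(cohort$gait_censored)) {
      min(cohort$gait_speed[cohort$gait_censored])
    } else {
      -Inf
    }
  }
  y <- cbind(exhaustion = cohort$exhaustion,
             physical_activity = cohort$physical_activity,
             grip_strength = cohort$grip_strength,
             gait_speed = cohort$gait_speed,
             weight_lost_any = as.numeric(cohort$weight_lost_any),
             weight_lost_log_kg = log(cohort$weight_lost_kg))
  fmm_item_matrix(
    y,
    types = c("gaussian", "gaussian", "gaussian", "censored",
              "bernoulli", "magnitude"),
    floors = c(NA, NA, NA, floor, NA, NA),
    censored = cbind(matrix(FALSE, nrow(y), 3), cohort$gait_censored,
                     matrix(FALSE, nrow(y), 2)),
    occurrence_for = c(NA, NA, NA, NA, NA, 5L))
}

#' Decode an encoded item block back to the cohort component columns
#'
#' Inverse of [encode_fmm_items()]; round-trips the component block exactly.
#'
#' @param items an `fmm_items` object produced by [encode_fmm_items()].
#' @return data.frame with the component block columns.
#' @export
decode_fmm_items <- function(items) {
  y <- items$y
  data.frame(
    exhaustion = y[, 1], physical_activity = y[, 2], grip_strength = y[, 3],
    gait_speed = y[, 4], gait_censored = items$censored[, 4],
    weight_lost_any = as.integer(y[, 5]), weight_lost_kg = exp(y[, 6]))
}
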