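test_that("every threshold equals a brute-force order-statistic computation", {
  cohort <- generate_cohort(default_config_frele(n_subjects = 500), seed = 3)
  cuts <- derive_cut_points(cohort)
  # independent quantile: sort and linearly interpolate between closest ranks
  q20_sorted <- function(x) {
    xs <- sort(x)
    h <- (length(xs) - 1) * 0.2 + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(cuts$threshold[cuts$component == "exhaustion"],
               q20_sorted(cohort$exhaustion))
  for (s in c("F", "M")) {
    expect_equal(
      cuts$threshold[cuts$component == "low_activity" &
                       cuts$stratum == sprintf("sex=%s", s)],
      q20_sorted(cohort$physical_activity[cohort$sex == s]))
    hm <- mean(cohort$height_cm[cohort$sex == s])
    short <- cohort$sex == s & cohort$height_cm <= hm
    expect_equal(
      cuts$threshold[cuts$component == "slowness" &
                       cuts$stratum == sprintf("sex=%s,height=short", s)],
      q20_sorted(cohort$gait_speed[short]))
  }
})

test_that("a degenerate stratum with one shared value returns that value", {
  cohort <- generate_cohort(default_config_frele(n_subjects = 300), seed = 4)
  cohort$physical_activity[cohort$sex == "F"] <- 77.5
  cuts <- derive_cut_points(cohort)
  expect_equal(cuts$threshold[cuts$component == "low_activity" &
                                cuts$stratum == "sex=F"], 77.5)
})

test_that("an empty stratum raises an error naming the stratum", {
  cohort <- generate_cohort(default_config_frele(n_subjects = 200), seed = 5)
  cohort$sex[] <- "F"
  expect_error(derive_cut_points(cohort), "sex=M")
})

test_that("dichotomization is boundary-inclusive and direction-correct", {
  cohort <- generate_cohort(default_config_frele(n_subjects = 400), seed = 6)
  cuts <- derive_cut_points(cohort)
  thr <- cuts$threshold[cuts$component == "exhaustion"]
  cohort$exhaustion[1] <- thr       # exactly at threshold -> deficit
  cohort$exhaustion[2] <- thr + 1e-9
  bin <- dichotomize(cohort, cuts)
  expect_identical(unname(bin[1, "exhaustion"]), 1L)
  expect_identical(unname(bin[2, "exhaustion"]), 0L)
  expect_identical(colnames(bin), c("weight_loss", "exhaustion",
                                    "low_activity", "slowness", "weakness"))
  # quintile-based components show ~20% deficit prevalence by construction
  for (comp in c("exhaustion", "low_activity", "slowness", "weakness"))
    expect_lt(abs(mean(bin[, comp]) - 0.20), 0.08)
})

test_that("raising grip strength never flips weakness from fine to deficit", {
  cohort <- generate_cohort(default_config_frele(n_subjects = 300), seed = 7)
  cuts <- derive_cut_points(cohort)
  b1 <- dichotomize(cohort, cuts)
  cohort2 <- cohort
  cohort2$grip_strength <- cohort2$grip_strength + 5
  b2 <- dichotomize(cohort2, cuts)
  expect_true(all(b2[, "weakness"] <= b1[, "weakness"]))
})

test_that("the frailty index applies the 0 / 1-2 / 3+ rule and conserves n", {
  rows <- rbind(c(0, 0, 0, 0, 0),
                c(1, 1, 0, 0, 0),
                c(1, 1, 1, 0, 1),
                c(1, 1, 1, 1, 1),
                c(0, 1, 0, 0, 0))
  colnames(rows) <- c("weight_loss", "exhaustion", "low_activity",
                      "slowness", "weakness")
  idx <- frailty_index(rows)
  expect_equal(idx$deficit_count, c(0L, 2L, 4L, 5L, 1L))
  expect_equal(as.character(idx$frailty_class),
               c("robust", "prefrail", "frail", "frail", "prefrail"))
  cohort <- small_cohort()
  bin <- dichotomize(cohort, derive_cut_points(cohort))
  tab <- table(frailty_index(bin)$frailty_class)
  expect_equal(sum(tab), nrow(cohort))
})

test_that("item encoding round-trips, propagates censoring and validates", {
  cohort <- small_cohort()
  items <- encode_fmm_items(cohort)
  expect_s3_class(items, "fmm_items")
  expect_equal(sum(items$censored[, 4]), sum(cohort$gait_censored))
  expect_true(all(is.na(items$y[cohort$weight_lost_any == 0, 6])))
  back <- decode_fmm_items(items)
  expect_equal(back$weight_lost_kg, cohort$weight_lost_kg, tolerance = 1e-12)
  expect_equal(back$exhaustion, cohort$exhaustion)
  expect_identical(back$gait_censored, cohort$gait_censored)

  bad <- cohort
  bad$weight_lost_kg[bad$weight_lost_any == 1][1] <- -2
  expect_error(encode_fmm_items(bad), "negative")
})

test_that("the published-dialect cut-point fixture reads back faithfully", {
  path <- system.file("extdata", "frele_cutpoints.json", package = "frailmix")
  cuts <- read_cut_points(path)
  get <- function(comp, strat)
    cuts$threshold[cuts$component == comp & cuts$stratum == strat]
  expect_equal(get("low_activity", "sex=F"), 32.33)
  expect_equal(get("low_activity", "sex=M"), 39.35)
  expect_equal(get("exhaustion", "all"), 46.88)
  expect_equal(attr(cuts, "height_mean")[["F"]], 155.81)
  expect_equal(attr(cuts, "bmi_breaks")$F[1], 23.49)
  # and our own serializer round-trips a derived table
  cohort <- small_cohort()
  mine <- derive_cut_points(cohort)
  p <- tempfile(fileext = ".json")
  write_cut_points(mine, p)
  back <- read_cut_points(p)
  expect_equal(back$threshold, mine$threshold)
  expect_equal(attr(back, "bmi_breaks"), attr(mine, "bmi_breaks"),
               tolerance = 1e-12)
  unlink(p)
})
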