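# The eight-step structural-validity pipeline: dichotomized LCA, factor
# dimensionality, homogeneity tests, class-count search, variance tests,
# component-ordering checks, tests against the strong-invariance null, and
# class profiling, ending in one of three verdicts:
#   homogeneous                          K = 1 never rejected
#   categorical-approximation-of-continuum   the strong-invariance null survives
#   syndromic                            a single-gradient non-null model
#                                        rejects the strong-invariance null

#' Component ordering of classes
#'
#' For each component, ranks the classes on their class-specific means after
#' aligning directions (so that for every component a lower aligned value is
#' "frailer"); values closer than `tol` tie and collapse to one rank. The
#' syndrome reading requires all components to induce the same class
#' ordering.
#'
#' @param means K x C matrix of class-specific component means or intercepts.
#' @param direction length-C vector of +1 (higher score = healthier) or -1
#'   (higher score = frailer, e.g. weight loss).
#' @param tol tie tolerance.
#' @return object of class `ordering_report`: per-component rank vectors,
#'   the grouping of components by identical ordering, and
#'   `verdict` (`"single-gradient"` or `"multiple-orderings"`).
#' @export
ordering_check <- function(means, direction = rep(1, ncol(means)),
                           tol = 1e-6) {
  means <- as.matrix(means)
  K <- nrow(means); C <- ncol(means)
  stopifnot(K >= 2L, length(direction) == C, all(direction %in% c(-1, 1)))
  comp_names <- colnames(means) %||% paste0("component", seq_len(C))
  ranks <- matrix(NA_integer_, K, C, dimnames = list(NULL, comp_names))
  for (c in seq_len(C)) {
    v <- means[, c] * direction[c]
    o <- order(v)
    grp <- cumsum(c(1, diff(v[o]) > tol))
    r <- integer(K)
    r[o] <- grp
    ranks[, c] <- r                     # 1 = frailest group
  }
  key <- apply(ranks, 2, paste, collapse = "-")
  groups <- split(comp_names, factor(key, levels = unique(key)))
  names(groups) <- NULL
  out <- list(ranks = ranks, groups = groups,
              permutations = stats::setNames(key, comp_names),
              verdict = if (length(groups) == 1L) "single-gradient" else
                "multiple-orderings")
  class(out) <- "ordering_report"
  out
}

#' @export
print.ordering_report <- function(x, ...) {
  cat(sprintf("<ordering_report> %s\n", x$verdict))
  for (g in x$groups)
    cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' Profile latent classes on components and risk factors
#'
#' Per-class means of the component block (weight loss as occurrence rate and
#' mean kg among losers) and of the covariate block, computed on modal
#' assignments. Empty classes yield a zero-size row and are flagged.
#'
#' @param assignments integer class labels, one per subject.
#' @param cohort the `frail_cohort` the model was fitted to.
#' @param K number of classes (defaults to `max(assignments)`).
#' @return data.frame of class `class_profile`, one row per class plus the
#'   class sizes and shares; `attr(, "empty_classes")` lists empty classes.
#' @export
profile_classes <- function(assignments, cohort, K = max(assignments)) {
  stopifnot(length(assignments) == nrow(cohort))
  n <- nrow(cohort)
  rows <- lapply(seq_len(K), function(k) {
    sel <- assignments == k
    sz <- sum(sel)
    num_mean <- function(x) if (sz) mean(x, na.rm = TRUE) else NA_real_
    data.frame(
      class = k, size = sz, share = sz / n,
      exhaustion = num_mean(cohort$exhaustion[sel]),
      physical_activity = num_mean(cohort$physical_activity[sel]),
      grip_strength = num_mean(cohort$grip_strength[sel]),
      gait_speed = num_mean(cohort$gait_speed[sel]),
      weight_loss_rate = num_mean(cohort$weight_lost_any[sel]),
      weight_lost_kg = if (sz && any(cohort$weight_lost_any[sel] == 1))
        mean(cohort$weight_lost_kg[sel], na.rm = TRUE) else NA_real_,
      pct_male = num_mean(cohort$sex[sel] == "M"),
      age = num_mean(cohort$age[sel]),
      education = num_mean(cohort$education[sel]),
      self_rated_health = num_mean(cohort$self_rated_health[sel]),
      chronic_diseases = num_mean(cohort$chronic_diseases[sel]),
      cognition = num_mean(cohort$cognition[sel]),
      depression_rate = num_mean(cohort$depression[sel]),
      iadl_rate = num_mean(cohort$iadl_disability[sel]),
      adl_rate = num_mean(cohort$adl_disability[sel]),
      deceased_rate = num_mean(cohort$deceased[sel]))
  })
  out <- do.call(rbind, rows)
  attr(out, "empty_classes") <- which(out$size == 0)
  class(out) <- c("class_profile", "data.frame")
  out
}

#' Control settings for [run_eight_steps()]
#'
#' @param K_max largest class count explored per family.
#' @param B bootstrap replications per likelihood-ratio test.
#' @param alpha significance level used throughout.
#' @param rule decision rule for comparisons against the strong-invariance
#'   null when BIC and BLRT disagree (see [compare_family()]).
#' @param n_starts,boot_starts random starts for observed fits and bootstrap
#'   refits.
#' @param n_quad,boot_quad quadrature points for observed fits and bootstrap
#'   refits.
#' @param direction component direction flags for [ordering_check()] over the
#'   six items (+1 higher = healthier).
#' @param early_stop use BLRT early stopping at `alpha` (decisions unchanged).
#' @param seed master seed for every fit and bootstrap in the pipeline.
#' @return list of settings.
#' @export
pipeline_control <- function(K_max = 4L, B = 99L, alpha = 0.05,
                             rule = c("both", "blrt", "bic"),
                             n_starts = 10L, boot_starts = 2L,
                             n_quad = 61L, boot_quad = 9L,
                             direction = c(1, 1, 1, 1, -1, -1),
                             early_stop = TRUE, seed = 1L) {
  list(K_max = as.integer(K_max), B = as.integer(B), alpha = alpha,
       rule = match.arg(rule), n_starts = as.integer(n_starts),
       boot_starts = as.integer(boot_starts), n_quad = as.integer(n_quad),
       boot_quad = as.integer(boot_quad), direction = direction,
       early_stop = early_stop, seed = as.integer(seed))
}

.pipeline_families <- function() {
  list(c("LCA", "ev"), c("LCA", "uv"), c("SiMI", "ev"), c("SoMI", "uv"),
       c("WMI", "ev"), c("WMI", "uv"), c("NMI", "ev"), c("NMI", "uv"))
}

# class-specific implied item means of a fitted FMM
.class_item_means <- function(fit) {
  p <- fit$params
  p$intercept + p$loading * p$alpha
}

#' Run the eight-step structural-validity analysis
#'
#' Executes, on one cohort: (1) stratified cut points, dichotomization, the
#' frailty index and a 3-class latent class analysis of the binary components
#' with goodness of fit and bootstrap class-count tests; (2) the one- versus
#' two-factor comparison; (3) the K = 1 homogeneity null against K = 2 for
#' every family member (BIC and BLRT); (4) the minimal acceptable class count
#' per family (grow K while the bootstrap test rejects K - 1 and no
#' degeneracy stop occurs); (5) equal- versus unequal-variance tests within
#' each family line; (6) component-ordering checks on the surviving non-null
#' models, excluding those with multiple orderings; (7) the surviving
#' non-null models against the selected strong-invariance null; (8) class
#' profiles of the final model and of the frailty index. Any stage failure
#' truncates the report at that stage with diagnostics.
#'
#' @param cohort a `frail_cohort`.
#' @param control a [pipeline_control()].
#' @return object of class `pipeline_report`.
#' @export
run_eight_steps <- function(cohort, control = pipeline_control()) {
  report <- list(steps = list(), verdict = NA_character_,
                 alpha = control$alpha, seed = control$seed,
                 truncated_at = NA_character_)
  class(report) <- "pipeline_report"
  ctl <- fmm_control(n_quad = control$n_quad, tol = 5e-3, max_iter = 600L)
  bctl <- fmm_control(n_quad = control$boot_quad, max_iter = 40L,
                      tol = 5e-2, short_iter = 6L)
  astop <- if (control$early_stop) control$alpha else NULL
  seed <- control$seed

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$truncated_at <<- name
      report$steps[[name]] <<- list(error = conditionMessage(e))
      NULL
    })
  }

  # ---- step 1: dichotomized components ----------------------------------
  s1 <- run_stage("step1_binary_lca", {
    cuts <- derive_cut_points(cohort)
    bin <- dichotomize(cohort, cuts)
    idx <- frailty_index(bin)
    lcas <- lapply(1:3, function(K)
      fit_binary_lca(bin, K, n_starts = 15L, seed = seed + K,
                     max_iter = 500L))
    gofs <- lapply(lcas, lca_goodness_of_fit)
    b32 <- blrt(unclass(bin), 3L, 2L, B = control$B, n_starts = 15L,
                boot_starts = 3L, seed = seed + 11L, alpha_stop = astop)
    b21 <- blrt(unclass(bin), 2L, 1L, B = control$B, n_starts = 15L,
                boot_starts = 3L, seed = seed + 12L, alpha_stop = astop)
    list(cuts = cuts, binary = bin, index = idx, fits = lcas, gofs = gofs,
         blrt_3v2 = b32, blrt_2v1 = b21,
         index_table = table(idx$frailty_class))
  })
  if (!is.null(report$steps$step1_binary_lca$error)) return(report)
  report$steps$step1_binary_lca <- s1

  # ---- step 2: factor dimensionality ------------------------------------
  items <- encode_fmm_items(cohort)
  s2 <- run_stage("step2_factor_dimension", compare_factor_dimension(items))
  if (!is.null(report$steps$step2_factor_dimension$error)) return(report)
  report$steps$step2_factor_dimension <- s2

  # fit cache over family members
  fits <- new.env(parent = emptyenv())
  fit_of <- function(family, K, variance) {
    if (K == 1L) variance <- "ev"
    if (K == 1L && family == "SoMI") family <- "SiMI"
    key <- sprintf("%s-%s-K%d", family, variance, K)
    if (!is.null(fits[[key]])) return(fits[[key]])
    spec <- fmm_spec(family, K, variance, items)
    f <- fit_fmm(items, spec, n_starts = control$n_starts,
                 seed = seed + 100L * K + match(family, .family_levels),
                 control = ctl)
    fits[[key]] <- f
    f
  }

  members <- .pipeline_families()

  # ---- step 3: homogeneity nulls ----------------------------------------
  s3 <- run_stage("step3_homogeneity", {
    lapply(members, function(m) {
      f2 <- fit_of(m[1], 2L, m[2])
      f1 <- fit_of(m[1], 1L, m[2])
      bd <- bic_difference(f2, f1)
      b <- blrt(items, f2$spec, f1$spec, B = control$B,
                boot_starts = control$boot_starts, seed = seed + 20L,
                control = ctl, boot_control = bctl, alpha_stop = astop,
                fit_alt = f2, fit_null = f1)
      blrt_rej <- isTRUE(!b$early_stopped && b$p_value <= control$alpha)
      # the bootstrap test alone governs the class-count search (step 4);
      # POPULATION homogeneity is rejected only when BIC agrees, which also
      # keeps the family-wise false-rejection rate over the members low
      list(family = m[1], variance = m[2],
           blrt_reject = blrt_rej,
           reject_one_class = blrt_rej && bd < 0,
           bic_diff = bd, blrt = b)
    })
  })
  if (!is.null(report$steps$step3_homogeneity$error)) return(report)
  report$steps$step3_homogeneity <- s3
  # Homogeneity of the population is judged on the factor-model members:
  # one-class profile analysis assumes independent items, so a homogeneous
  # population whose components share a continuum rejects it trivially
  # without implying latent classes.
  fmm_members <- vapply(s3, function(x) x$family != "LCA", TRUE)
  any_reject_k1 <- any(vapply(s3[fmm_members], `[[`, TRUE,
                              "reject_one_class"))
  if (!any_reject_k1) {
    report$verdict <- "homogeneous"
    report$steps$final <- list(
      reason = "the one-class factor-model null was not rejected for any family member")
    report <- .finalize_pipeline(report, cohort, items, fit_of("SiMI", 1L, "ev"),
                                 control)
    return(report)
  }

  # ---- step 4: minimal acceptable class count per member ----------------
  s4 <- run_stage("step4_class_count", {
    lapply(seq_along(members), function(i) {
      m <- members[[i]]
      rej_k1 <- s3[[i]]$blrt_reject
      K_sel <- 1L
      trail <- list()
      if (rej_k1) {
        K_sel <- 2L
        while (K_sel < control$K_max) {
          f_next <- fit_of(m[1], K_sel + 1L, m[2])
          if (f_next$degenerate) {
            trail[[length(trail) + 1L]] <- list(K = K_sel + 1L,
                                                stopped = "degenerate")
            break
          }
          f_cur <- fit_of(m[1], K_sel, m[2])
          b <- blrt(items, f_next$spec, f_cur$spec, B = control$B,
                    boot_starts = control$boot_starts,
                    seed = seed + 30L + K_sel,
                    control = ctl, boot_control = bctl, alpha_stop = astop,
                    fit_alt = f_next, fit_null = f_cur)
          rej <- isTRUE(!b$early_stopped && b$p_value <= control$alpha)
          trail[[length(trail) + 1L]] <- list(K = K_sel + 1L, p = b$p_value,
                                              reject = rej)
          if (!rej) break
          K_sel <- K_sel + 1L
        }
      }
      list(family = m[1], variance = m[2], K_selected = K_sel, trail = trail)
    })
  })
  if (!is.null(report$steps$step4_class_count$error)) return(report)
  report$steps$step4_class_count <- s4
  K_of <- function(family, variance) {
    for (x in s4) if (x$family == family && x$variance == variance)
      return(x$K_selected)
    1L
  }

  # ---- step 5: ev vs uv within each family line -------------------------
  lines <- list(LCA = c("LCA", "LCA"), SMI = c("SiMI", "SoMI"),
                WMI = c("WMI", "WMI"), NMI = c("NMI", "NMI"))
  s5 <- run_stage("step5_variance", {
    lapply(names(lines), function(ln) {
      fam_ev <- lines[[ln]][1]; fam_uv <- lines[[ln]][2]
      K_ev <- K_of(fam_ev, "ev"); K_uv <- K_of(fam_uv, "uv")
      if (K_ev == 1L && K_uv == 1L)
        return(list(line = ln, selected = sprintf("%s-ev-K1", fam_ev),
                    family = fam_ev, variance = "ev", K = 1L, blrt = NULL))
      f_ev <- fit_of(fam_ev, max(K_ev, 2L), "ev")
      f_uv <- fit_of(fam_uv, max(K_uv, 2L), "uv")
      b <- blrt(items, f_uv$spec, f_ev$spec, B = control$B,
                boot_starts = control$boot_starts, seed = seed + 40L,
                control = ctl, boot_control = bctl, alpha_stop = astop,
                fit_alt = f_uv, fit_null = f_ev)
      uv_wins <- isTRUE(!b$early_stopped && b$p_value <= control$alpha)
      sel <- if (uv_wins) list(family = fam_uv, variance = "uv",
                               K = max(K_uv, 2L)) else
        list(family = fam_ev, variance = "ev", K = max(K_ev, 2L))
      list(line = ln,
           selected = sprintf("%s-%s-K%d", sel$family, sel$variance, sel$K),
           family = sel$family, variance = sel$variance, K = sel$K,
           bic_diff = bic_difference(f_uv, f_ev), blrt = b)
    })
  })
  if (!is.null(report$steps$step5_variance$error)) return(report)
  names(s5) <- names(lines)
  report$steps$step5_variance <- s5

  # ---- step 6: component ordering of non-null survivors -----------------
  s6 <- run_stage("step6_ordering", {
    non_null <- s5[c("LCA", "WMI", "NMI")]
    lapply(non_null, function(sel) {
      if (sel$K < 2L)
        return(list(model = sel$selected, excluded = TRUE,
                    reason = "one class selected; ordering not applicable"))
      f <- fit_of(sel$family, sel$K, sel$variance)
      om <- ordering_check(.class_item_means(f), control$direction)
      list(model = sel$selected, ordering = om,
           excluded = om$verdict != "single-gradient",
           reason = if (om$verdict != "single-gradient")
             "components ordered differently across classes" else NA_character_)
    })
  })
  if (!is.null(report$steps$step6_ordering$error)) return(report)
  report$steps$step6_ordering <- s6

  # ---- step 7: survivors against the strong-invariance null -------------
  smi_sel <- s5$SMI
  smi_fit <- fit_of(smi_sel$family, max(smi_sel$K, 1L), smi_sel$variance)
  s7 <- run_stage("step7_vs_null", {
    survivors <- names(s6)[!vapply(s6, `[[`, TRUE, "excluded")]
    cmps <- lapply(survivors, function(ln) {
      sel <- s5[[ln]]
      f <- fit_of(sel$family, sel$K, sel$variance)
      bd <- bic_difference(f, smi_fit)
      # under the "both" rule a BIC preference for the null already settles
      # the decision; the bootstrap is run only when it can matter
      b <- if (control$rule != "both" || bd < 0)
        blrt(items, f$spec, smi_fit$spec, B = control$B,
             boot_starts = control$boot_starts, seed = seed + 50L,
             control = ctl, boot_control = bctl, alpha_stop = astop,
             fit_alt = f, fit_null = smi_fit) else NULL
      list(label = sprintf("%s vs %s", sel$selected,
                           .model_label(smi_fit)),
           kind = "vs-null-family", fit_alt = f, fit_null = smi_fit,
           blrt = b)
    })
    ledger <- compare_family(cmps, alpha = control$alpha, rule = control$rule)
    list(ledger = ledger, survivors = survivors)
  })
  if (!is.null(report$steps$step7_vs_null$error)) return(report)
  report$steps$step7_vs_null <- s7

  # ---- verdict and step 8 -----------------------------------------------
  led <- s7$ledger
  rejecting <- if (nrow(led)) which(led$reject_null) else integer(0)
  if (length(rejecting)) {
    report$verdict <- "syndromic"
    win <- rejecting[which.min(led$bic_alt[rejecting])]
    win_line <- s7$survivors[win]
    sel <- s5[[win_line]]
    final_fit <- fit_of(sel$family, sel$K, sel$variance)
  } else {
    report$verdict <- "categorical-approximation-of-continuum"
    final_fit <- smi_fit
  }
  report <- .finalize_pipeline(report, cohort, items, final_fit, control)
  report
}

.finalize_pipeline <- function(report, cohort, items, final_fit, control) {
  s8 <- tryCatch({
    pp <- posterior_probs(final_fit, items)
    fmm_profile <- profile_classes(pp$modal, cohort, K = final_fit$spec$K)
    idx <- report$steps$step1_binary_lca$index
    fried_profile <- profile_classes(as.integer(idx$frailty_class), cohort,
                                     K = 3L)
    list(final_model = .model_label(final_fit), final_fit = final_fit,
         fmm_profile = fmm_profile, fried_profile = fried_profile)
  }, error = function(e) list(error = conditionMessage(e)))
  report$steps$step8_profiles <- s8
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.na(x$truncated_at))
    cat("  TRUNCATED at", x$truncated_at, "\n")
  cat("  verdict:", x$verdict, "\n")
  if (!is.null(x$steps$step8_profiles$final_model))
    cat("  final model:", x$steps$step8_profiles$final_model, "\n")
  invisible(x)
}
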