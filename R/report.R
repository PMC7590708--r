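# Rendering of pipeline reports: a machine-readable JSON payload and a
# human-readable markdown summary with sections shaped like the published
# LCA / class-count / model-selection / class-profile tables.

.sanitize <- function(x) {
  if (is.list(x)) return(lapply(x, .sanitize))
  if (is.factor(x)) x <- as.character(x)
  if (length(x) && (is.numeric(x) || is.logical(x)) && anyNA(x)) {
    x <- as.character(x)
  }
  if (is.character(x)) x[is.na(x)] <- "n/a"
  x
}

.df_payload <- function(df) {
  .sanitize(lapply(as.data.frame(df), function(col)
    if (is.factor(col)) as.character(col) else col))
}

.blrt_payload <- function(b) {
  if (is.null(b)) return(NULL)
  .sanitize(list(lrt_observed = b$lrt_observed, p_value = b$p_value,
                 B_used = b$B_used, n_failed = b$n_failed_replicates,
                 early_stopped = b$early_stopped, nested = b$nested))
}

# plain-list payload for serialization
.report_payload <- function(report) {
  st <- report$steps
  payload <- list(
    verdict = report$verdict,
    alpha = report$alpha,
    seed = report$seed,
    truncated_at = if (is.na(report$truncated_at)) "none" else
      report$truncated_at)

  if (!is.null(st$step1_binary_lca) &&
      is.null(st$step1_binary_lca$error)) {
    s1 <- st$step1_binary_lca
    payload$step1 <- list(
      frailty_index = as.list(s1$index_table),
      lca = lapply(seq_along(s1$fits), function(i) {
        f <- s1$fits[[i]]; g <- s1$gofs[[i]]
        .sanitize(list(K = f$K, loglik = f$loglik, bic = f$bic,
                       chi2 = g$chi2, df = g$df, p = g$p))
      }),
      blrt_3v2 = .blrt_payload(s1$blrt_3v2),
      blrt_2v1 = .blrt_payload(s1$blrt_2v1))
  } else if (!is.null(st$step1_binary_lca)) {
    payload$step1 <- .sanitize(st$step1_binary_lca["error"])
  }

  if (!is.null(st$step2_factor_dimension)) {
    s2 <- st$step2_factor_dimension
    payload$step2 <- .sanitize(list(chi2 = s2$chi2, df = s2$df, p = s2$p,
                                    error = s2$error))
  }
  if (!is.null(st$step3_homogeneity) &&
      is.null(st$step3_homogeneity$error)) {
    payload$step3 <- lapply(st$step3_homogeneity, function(x)
      .sanitize(list(member = sprintf("%s-%s", x$family, x$variance),
                     reject_one_class = x$reject_one_class,
                     bic_diff = x$bic_diff,
                     blrt = .blrt_payload(x$blrt))))
  }
  if (!is.null(st$step4_class_count) &&
      is.null(st$step4_class_count$error)) {
    payload$step4 <- lapply(st$step4_class_count, function(x)
      .sanitize(list(member = sprintf("%s-%s", x$family, x$variance),
                     K_selected = x$K_selected)))
  }
  if (!is.null(st$step5_variance) && is.null(st$step5_variance$error)) {
    payload$step5 <- lapply(st$step5_variance, function(x)
      .sanitize(list(line = x$line, selected = x$selected,
                     blrt = .blrt_payload(x$blrt))))
  }
  if (!is.null(st$step6_ordering) && is.null(st$step6_ordering$error)) {
    payload$step6 <- lapply(st$step6_ordering, function(x) {
      out <- list(model = x$model, excluded = x$excluded)
      if (!is.null(x$ordering)) {
        out$verdict <- x$ordering$verdict
        out$groups <- x$ordering$groups
      }
      .sanitize(out)
    })
  }
  if (!is.null(st$step7_vs_null) && is.null(st$step7_vs_null$error)) {
    led <- st$step7_vs_null$ledger
    payload$step7 <- if (nrow(led) == 0L) list(note = "no comparisons") else
      .df_payload(led)
  }
  if (!is.null(st$step8_profiles) && is.null(st$step8_profiles$error)) {
    s8 <- st$step8_profiles
    payload$step8 <- list(final_model = s8$final_model,
                          fmm_profile = .df_payload(s8$fmm_profile),
                          fried_profile = .df_payload(s8$fried_profile))
  }
  payload
}

.payload_json <- function(payload) {
  jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, pretty = TRUE,
                   null = "null")
}

.payload_markdown <- function(p) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("# Structural-validity report")
  add("")
  add("**Verdict:** %s (alpha = %s, seed = %s)", p$verdict, p$alpha, p$seed)
  if (!identical(p$truncated_at, "none"))
    add("**Pipeline truncated at:** %s", p$truncated_at)
  add("")
  if (!is.null(p$step1) && is.null(p$step1$error)) {
    add("## Step 1: dichotomized components (LCA)")
    add("")
    add("| K | loglik | BIC | chi2 GOF | df | p |")
    add("|---|--------|-----|----------|----|---|")
    for (r in p$step1$lca)
      add("| %s | %.1f | %.1f | %s | %s | %s |", r$K, r$loglik, r$bic,
          .fmtnum(r$chi2), r$df, .fmtnum(r$p))
    add("")
    add("Frailty index: %s", paste(names(p$step1$frailty_index),
                                   unlist(p$step1$frailty_index),
                                   sep = " = ", collapse = ", "))
    add("")
  }
  if (!is.null(p$step2)) {
    add("## Step 2: factor dimensionality")
    add("")
    add("One vs two factors: chi2 = %s, df = %s, p = %s",
        .fmtnum(p$step2$chi2), p$step2$df, .fmtnum(p$step2$p))
    add("")
  }
  if (!is.null(p$step3)) {
    add("## Step 3: homogeneity (K = 1) nulls")
    add("")
    add("| member | reject K=1 | BIC diff (K2 - K1) | BLRT p |")
    add("|--------|------------|--------------------|--------|")
    for (r in p$step3)
      add("| %s | %s | %.1f | %s |", r$member, r$reject_one_class,
          r$bic_diff, .fmtnum(r$blrt$p_value))
    add("")
  }
  if (!is.null(p$step4)) {
    add("## Step 4: selected class counts")
    add("")
    for (r in p$step4) add("- %s: K = %s", r$member, r$K_selected)
    add("")
  }
  if (!is.null(p$step5)) {
    add("## Step 5: equal vs unequal variances")
    add("")
    for (r in p$step5) add("- line %s: selected %s", r$line, r$selected)
    add("")
  }
  if (!is.null(p$step6)) {
    add("## Step 6: component ordering")
    add("")
    for (r in p$step6) {
      add("- %s: %s%s", r$model,
          if (!is.null(r$verdict)) r$verdict else "not applicable",
          if (isTRUE(r$excluded)) " (excluded)" else "")
    }
    add("")
  }
  add("## Step 7: non-null models vs the strong-invariance null")
  add("")
  if (is.null(p$step7) || !is.null(p$step7$note)) {
    add("No comparisons were performed.")
  } else {
    add("| comparison | BIC diff | BLRT p | reject null |")
    add("|------------|----------|--------|-------------|")
    for (i in seq_along(p$step7$label))
      add("| %s | %.1f | %s | %s |", p$step7$label[i], p$step7$bic_diff[i],
          .fmtnum(p$step7$blrt_p[i]), p$step7$reject_null[i])
  }
  add("")
  if (!is.null(p$step8)) {
    add("## Step 8: class profiles (final model: %s)", p$step8$final_model)
    add("")
    add(.profile_md(p$step8$fmm_profile))
    add("")
    add("Frailty-index classes (1 = robust, 2 = prefrail, 3 = frail):")
    add("")
    add(.profile_md(p$step8$fried_profile))
  }
  paste(ln, collapse = "\n")
}

.fmtnum <- function(x) {
  if (is.null(x) || length(x) == 0L) return("n/a")
  if (is.character(x)) return(x)
  if (is.na(x)) return("n/a")
  if (is.infinite(x)) return("Inf")
  formatC(x, digits = 4, format = "g")
}

.profile_md <- function(pr) {
  cols <- names(pr)
  hdr <- paste0("| ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|")
  rows <- vapply(seq_along(pr$class), function(i)
    paste0("| ", paste(vapply(cols, function(cn) {
      v <- pr[[cn]][i]
      if (is.numeric(v)) formatC(v, digits = 4, format = "g") else
        as.character(v)
    }, ""), collapse = " | "), " |"), "")
  paste(c(hdr, sep, rows), collapse = "\n")
}

#' Render a pipeline report to JSON and markdown files
#'
#' Writes `report.json` (machine-readable, stable under a parse/serialize
#' round trip) and `report.md` (tables shaped like the published summaries)
#' into `dir`. Accepts either a live [run_eight_steps()] report or a payload
#' previously loaded with [read_report()]; output is deterministic given the
#' report.
#'
#' @param report a `pipeline_report` or `pipeline_report_json` payload.
#' @param dir output directory (created if needed).
#' @return named character vector of the two file paths, invisibly.
#' @export
render_report <- function(report, dir) {
  payload <- if (inherits(report, "pipeline_report_json")) {
    unclass(report)
  } else {
    .report_payload(report)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, "report.json")
  mpath <- file.path(dir, "report.md")
  writeLines(.payload_json(payload), jpath)
  writeLines(.payload_markdown(payload), mpath)
  invisible(c(json = jpath, markdown = mpath))
}

#' @rdname render_report
#' @param path path to a `report.json` written by [render_report()].
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  structure(x, class = "pipeline_report_json")
}
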