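#' Item block for factor mixture modelling
#'
#' Container for the measurement items handed to [fit_fmm()]: a numeric
#' matrix plus per-item model tags. Supported item models are
#' `"gaussian"` (linear-normal), `"censored"` (normal, left-censored at a
#' floor; flagged cells contribute the normal left-tail probability),
#' `"bernoulli"` (binary, logit intercept, no factor loading), and
#' `"magnitude"` (the conditional-magnitude half of a two-part item: normal,
#' observed only where its paired occurrence item equals 1).
#'
#' @param y numeric `n x M` matrix; `NA` allowed only in magnitude columns
#'   (exactly where the paired occurrence is 0).
#' @param types length-M character vector of item models.
#' @param floors length-M numeric; censoring floor for `"censored"` items,
#'   `NA` elsewhere.
#' @param censored `n x M` logical; `TRUE` only in `"censored"` columns.
#' @param occurrence_for length-M integer; for a `"magnitude"` item, the
#'   column index of its `"bernoulli"` occurrence item.
#' @return an object of class `fmm_items`.
#' @export
fmm_item_matrix <- function(y, types, floors = rep(NA_real_, ncol(y)),
                            censored = NULL, occurrence_for = rep(NA_integer_,
                                                                  ncol(y))) {
  y <- as.matrix(y)
  M <- ncol(y)
  stopifnot(length(types) == M,
            all(types %in% c("gaussian", "censored", "bernoulli", "magnitude")))
  if (is.null(censored)) censored <- matrix(FALSE, nrow(y), M)
  censored <- as.matrix(censored)
  stopifnot(nrow(censored) == nrow(y), ncol(censored) == M)
  if (any(censored[, types != "censored"]))
    stop("censoring flags are only allowed on censored items", call. = FALSE)
  for (m in which(types == "censored")) {
    if (is.na(floors[m])) stop(sprintf("item %d is censored but has no floor", m),
                               call. = FALSE)
    if (any(censored[, m] & y[, m] > floors[m] + 1e-8))
      stop(sprintf("item %d: censored cells must sit at the floor", m),
           call. = FALSE)
  }
  for (m in which(types == "magnitude")) {
    occ <- occurrence_for[m]
    if (is.na(occ) || types[occ] != "bernoulli")
      stop(sprintf("magnitude item %d needs a bernoulli occurrence item", m),
           call. = FALSE)
    if (any(is.na(y[, m]) != (y[, occ] == 0)))
      stop(sprintf("magnitude item %d must be NA exactly where item %d is 0",
                   m, occ), call. = FALSE)
  }
  if (any(is.na(y[, types != "magnitude", drop = FALSE])))
    stop("missing values are only allowed in magnitude items", call. = FALSE)
  structure(list(y = y, types = types, floors = as.numeric(floors),
                 censored = censored,
                 occurrence_for = as.integer(occurrence_for),
                 names = colnames(y) %||% paste0("item", seq_len(M))),
            class = "fmm_items")
}

#' @export
print.fmm_items <- function(x, ...) {
  cat(sprintf("<fmm_items> %d subjects x %d items\n", nrow(x$y), ncol(x$y)))
  cat(paste(sprintf("  %s [%s]", x$names, x$types), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.fmm_items <- function(x) dim(x$y)
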