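#' @title Accuracy-complexity model selection over a quadratic term library
#' @description
#' The published 5-parameter tied bi-quadratic was selected as the best
#' trade-off between accuracy and complexity among candidate functional
#' forms. This module reproduces that selection step transparently: instead
#' of a genetic-programming search it fits *every* admissible subset of a
#' fixed quadratic term library by least squares and exposes the Pareto
#' front in (number of parameters, squared error). The library is
#' `1, PNA, (1+PNA) tied, GA, GA^2, GA*PNA, PNA^2`; the tied term is mutually
#' exclusive with the separate intercept and linear-PNA terms, since it is an
#' alternative encoding of the same two regressors under one coefficient.
#' @name model_selection
NULL

.term_library <- c("1", "PNA", "TIED", "GA", "GA2", "GA.PNA", "PNA2")

.term_column <- function(term, ga, pna) {
  switch(term,
         "1"      = rep_len(1, length(ga)),
         "PNA"    = pna,
         "TIED"   = 1 + pna,
         "GA"     = ga,
         "GA2"    = ga^2,
         "GA.PNA" = ga * pna,
         "PNA2"   = pna^2,
         stop("unknown term: ", term, call. = FALSE))
}

.mask_admissible <- function(terms) {
  !("TIED" %in% terms && any(c("1", "PNA") %in% terms))
}

#' Enumerate admissible term masks
#'
#' All nonempty subsets of the 7-term library in which the tied `(1+PNA)`
#' term does not co-occur with the separate intercept or linear-PNA term.
#'
#' @param max_params largest subset size to include (<= 7).
#' @return A list of character vectors (term names, library order).
#' @export
enumerate_masks <- function(max_params = 7L) {
  stopifnot(max_params >= 1L, max_params <= 7L)
  masks <- list()
  for (k in seq_len(max_params)) {
    combos <- utils::combn(.term_library, k, simplify = FALSE)
    masks <- c(masks, Filter(.mask_admissible, combos))
  }
  masks
}

.mask_label <- function(terms) paste(terms, collapse = "+")

#' Fit every candidate model on a grid dataset
#'
#' Each admissible mask is fitted to the grid's mean values by closed-form
#' least squares; candidates whose design matrix is rank-deficient on the
#' given grid are skipped (with a message). Complexity is counted as the
#' number of free coefficients.
#'
#' @param data a `grid_dataset` (columns `ga`, `pna`, `mean`).
#' @param max_params largest candidate size (<= 7).
#' @return A data.frame of class `candidate_table` with columns `mask`,
#'   `n_params`, `sse`, `mae`, one row per fitted candidate, plus a
#'   `coefficients` list attribute keyed by mask label.
#' @export
enumerate_candidates <- function(data, max_params = 7L) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("empty grid dataset", call. = FALSE)
  masks <- enumerate_masks(max_params)
  rows <- vector("list", length(masks))
  coefs <- list()
  skipped <- 0L
  for (i in seq_along(masks)) {
    terms <- masks[[i]]
    X <- do.call(cbind, lapply(terms, .term_column,
                               ga = data$ga, pna = data$pna))
    qrX <- qr(X)
    if (qrX$rank < length(terms)) {
      skipped <- skipped + 1L
      next
    }
    beta <- qr.coef(qrX, data$mean)
    resid <- data$mean - drop(X %*% beta)
    label <- .mask_label(terms)
    rows[[i]] <- data.frame(mask = label, n_params = length(terms),
                            sse = sum(resid^2), mae = mean(abs(resid)),
                            stringsAsFactors = FALSE)
    coefs[[label]] <- stats::setNames(beta, terms)
  }
  if (skipped > 0L) {
    message(sprintf("skipped %d rank-deficient candidate(s) on this grid",
                    skipped))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "coefficients") <- coefs
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Accuracy-complexity Pareto front
#'
#' A candidate is dominated if another candidate has no more parameters and
#' no larger squared error, with at least one strict improvement. The front
#' is returned sorted by parameter count; when two candidates tie on both
#' axes the lexicographically smallest mask label is kept.
#'
#' @param candidates a `candidate_table` (or data.frame with `mask`,
#'   `n_params`, `sse`).
#' @return The non-dominated subset, with a logical `on_front` column set to
#'   `TRUE`, ordered by `n_params`.
#' @export
pareto_front <- function(candidates) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L)
  n <- nrow(candidates)
  dominated <- vapply(seq_len(n), function(i) {
    any(candidates$n_params <= candidates$n_params[i] &
          candidates$sse <= candidates$sse[i] &
          (candidates$n_params < candidates$n_params[i] |
             candidates$sse < candidates$sse[i]))
  }, logical(1))
  front <- candidates[!dominated, , drop = FALSE]
  front <- front[order(front$n_params, front$sse, front$mask), , drop = FALSE]
  # collapse exact ties on both axes to the lexicographically smallest mask
  key <- paste(front$n_params, front$sse)
  front <- front[!duplicated(key), , drop = FALSE]
  front$on_front <- TRUE
  rownames(front) <- NULL
  front
}

#' Mark front membership on a full candidate table
#'
#' @inheritParams pareto_front
#' @return `candidates` with an `on_front` logical column.
#' @export
annotate_front <- function(candidates) {
  front <- pareto_front(candidates)
  candidates$on_front <- candidates$mask %in% front$mask
  candidates
}
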