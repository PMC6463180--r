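#' Design row / design matrix for the tied bi-quadratic surface
#'
#' The mean surface is linear in its five parameters once the tied first
#' coefficient is encoded as a single regressor `(1 + pna)`. The fixed basis
#' order is `(1 + pna, ga, ga^2, ga*pna, pna^2)`, matching the parameter
#' order `p1..p5` of [surface_parameters()].
#'
#' @param ga gestational ages in weeks.
#' @param pna postnatal ages in days (same length, or scalar).
#' @return A numeric matrix with one row per (ga, pna) pair and 5 columns
#'   named `p1..p5`.
#' @export
design_matrix <- function(ga, pna) {
  .check_ages(ga, pna)
  n <- max(length(ga), length(pna))
  ga <- rep_len(as.double(ga), n)
  pna <- rep_len(as.double(pna), n)
  m <- cbind(1 + pna, ga, ga^2, ga * pna, pna^2)
  colnames(m) <- c("p1", "p2", "p3", "p4", "p5")
  m
}

#' @rdname design_matrix
#' @export
design_row <- function(ga, pna) {
  stopifnot(length(ga) == 1L, length(pna) == 1L)
  drop(design_matrix(ga, pna))
}

#' Assemble a grid dataset
#'
#' A grid dataset holds the reference values the surface is fitted to: mean
#' (and optionally 5th/95th percentile) values at a set of (GA, PNA) points.
#'
#' @param ga,pna,mean numeric vectors of equal length.
#' @param p5,p95 optional percentile columns; `NA` where unavailable.
#' @param analyte "cHb" or "Hct".
#' @return A data.frame of class `grid_dataset` with attribute `analyte`.
#' @export
grid_dataset <- function(ga, pna, mean, p5 = NA_real_, p95 = NA_real_,
                         analyte = "cHb") {
  n <- max(length(ga), length(pna), length(mean))
  if (n > 0L) {
    ga <- rep_len(as.double(ga), n)
    pna <- rep_len(as.double(pna), n)
    mean <- rep_len(as.double(mean), n)
  }
  p5 <- rep_len(as.double(p5), n)
  p95 <- rep_len(as.double(p95), n)
  bad <- which(!is.na(p5) & !is.na(p95) & !is.na(mean) &
                 !(p5 <= mean & mean <= p95))
  if (length(bad)) {
    stop("grid rows violate p5 <= mean <= p95 at record(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(ga = as.double(ga), pna = as.double(pna),
                    mean = as.double(mean), p5 = p5, p95 = p95)
  attr(out, "analyte") <- normalize_analyte(analyte)
  class(out) <- c("grid_dataset", "data.frame")
  out
}

.fit_result <- function(surface, data, method, converged = TRUE,
                        n_iterations = 0L, offset = NA_real_) {
  resid <- data$mean - evaluate_mean(surface, data$ga, data$pna)
  structure(
    list(surface = surface, offset = offset,
         sse = sum(resid^2), mae_insample = mean(abs(resid)),
         n_points = nrow(data), converged = converged,
         n_iterations = as.integer(n_iterations), method = method),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Surface fit (%s): %s after %d iteration(s)\n", x$method,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(unclass(x$surface))
  cat(sprintf("  n = %d, SSE = %.6g, in-sample MAE = %.6g\n",
              x$n_points, x$sse, x$mae_insample))
  if (!is.na(x$offset)) cat(sprintf("  percentile offset = %.6g\n", x$offset))
  invisible(x)
}

#' Closed-form least-squares fit of the tied surface
#'
#' Because the tied bi-quadratic is linear in its five parameters, the
#' least-squares problem has a unique closed-form solution whenever the
#' design matrix has rank 5. The solution is computed by QR decomposition.
#' This is the default fitting path and the exact oracle against which the
#' iterative [fit_lm()] is checked.
#'
#' @param data a `grid_dataset` (or data.frame with `ga`, `pna`, `mean`).
#' @return A `fit_result` with `method = "closed_form"`.
#' @export
fit_closed_form <- function(data) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  X <- design_matrix(data$ga, data$pna)
  qrX <- qr(X)
  if (qrX$rank < 5L) {
    deficient <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, 5L)]]
    stop(sprintf(
      "design matrix is rank-deficient (rank %d < 5); unidentifiable basis direction(s): %s",
      qrX$rank, paste(deficient, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrX, data$mean)
  surface <- surface_parameters(beta[1], beta[2], beta[3], beta[4], beta[5])
  .fit_result(surface, data, method = "closed_form")
}

#' Levenberg-Marquardt fit of the tied surface
#'
#' Minimises the sum of squared residuals of [evaluate_mean()] by
#' Levenberg-Marquardt iteration (via MINPACK). The model is linear in its
#' parameters, so from any finite start the iteration converges to the same
#' solution as [fit_closed_form()]; the path is retained as an independent
#' numerical route and for fidelity to the nonlinear-least-squares workflow
#' the published coefficients came from.
#'
#' @inheritParams fit_closed_form
#' @param init starting [surface_parameters]; the zero vector by default
#'   (the start is immaterial for a linear-in-parameters model).
#' @param tol convergence tolerance applied to the relative reductions in
#'   sum of squares and parameters (ftol/ptol).
#' @param max_iter iteration cap.
#' @return A `fit_result` with `method = "levenberg_marquardt"`.
#' @export
fit_lm <- function(data, init = surface_parameters(0, 0, 0, 0, 0),
                   tol = 1e-10, max_iter = 200L) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  if (!inherits(init, "surface_parameters")) {
    init <- do.call(surface_parameters, as.list(unname(init)))
  }
  residual_fn <- function(par) {
    s <- surface_parameters(par[1], par[2], par[3], par[4], par[5])
    data$mean - evaluate_mean(s, data$ga, data$pna)
  }
  # nls.lm warns on its own non-convergence; we inspect `info` and raise a
  # structured error instead
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = unclass(init), fn = residual_fn,
    control = minpack.lm::nls.lm.control(ftol = tol, ptol = tol,
                                         maxiter = as.integer(max_iter))))
  # info codes 1-4 are MINPACK success; 5 = maxiter exhausted
  converged <- fit$info %in% 1:4
  if (!converged) {
    cond <- simpleError(sprintf(
      "Levenberg-Marquardt did not converge within %d iterations: %s",
      max_iter, fit$message))
    cond$iterate <- fit$par
    stop(cond)
  }
  surface <- do.call(surface_parameters, as.list(unname(fit$par)))
  .fit_result(surface, data, method = "levenberg_marquardt",
              converged = TRUE, n_iterations = fit$niter)
}

#' Estimate the constant percentile offset
#'
#' The percentile surfaces sit at a constant distance from the mean surface,
#' reflecting the symmetric, age-invariant spread of the underlying value
#' distributions. The least-squares constant under that symmetric-band model
#' is the pooled mean half-spread: the average of all available
#' `mean - p5` and `p95 - mean` values. Where the grid's own mean column is
#' missing, the fitted mean from `surface` is substituted.
#'
#' @param data a `grid_dataset` with at least one non-missing `p5` or `p95`.
#' @param surface a [surface_parameters] object (or `reference_model`)
#'   supplying fitted means for records whose `mean` is missing.
#' @return The estimated offset (band half-width), a single number.
#' @export
estimate_offset <- function(data, surface = NULL) {
  stopifnot(is.data.frame(data))
  if (!any(!is.na(data$p5)) && !any(!is.na(data$p95))) {
    stop("no percentile data: every p5 and p95 value is missing",
         call. = FALSE)
  }
  mu <- data$mean
  if (anyNA(mu)) {
    if (is.null(surface)) {
      stop("grid has missing mean values; supply a fitted surface",
           call. = FALSE)
    }
    mu[is.na(mu)] <- evaluate_mean(surface, data$ga[is.na(mu)],
                                   data$pna[is.na(mu)])
  }
  half_spreads <- c((mu - data$p5)[!is.na(data$p5)],
                    (data$p95 - mu)[!is.na(data$p95)])
  mean(half_spreads)
}

#' Refit a full reference model from a grid dataset
#'
#' Two-stage estimation: the mean surface is fitted first (closed form by
#' default, or Levenberg-Marquardt), then the constant percentile offset is
#' estimated from the grid's percentile columns if any are present.
#'
#' @inheritParams fit_closed_form
#' @param method "closed_form" or "levenberg_marquardt" (alias "lm").
#' @param ... passed to [fit_lm()] when that method is chosen.
#' @return A `fit_result`; its `offset` field is filled when percentile
#'   columns were available, `NA` otherwise.
#' @export
fit_reference_model <- function(data, method = c("closed_form",
                                                 "levenberg_marquardt", "lm"),
                                ...) {
  method <- match.arg(method)
  fit <- if (method == "closed_form") fit_closed_form(data) else fit_lm(data, ...)
  if (any(!is.na(data$p5)) || any(!is.na(data$p95))) {
    fit$offset <- estimate_offset(data, fit$surface)
  }
  fit
}

#' Turn a fit into a usable reference model
#'
#' @param fit a converged `fit_result`.
#' @param analyte "cHb" or "Hct".
#' @param offset percentile offset; defaults to the fit's own estimate.
#' @param ... passed to [reference_model()].
#' @return A `reference_model`.
#' @export
as_reference_model <- function(fit, analyte, offset = fit$offset, ...) {
  stopifnot(inherits(fit, "fit_result"))
  if (!isTRUE(fit$converged)) {
    stop("refusing to build a model from a non-converged fit", call. = FALSE)
  }
  if (is.na(offset)) {
    stop("no percentile offset available; supply `offset`", call. = FALSE)
  }
  reference_model(analyte, fit$surface, offset,
                  provenance = sprintf("refit (%s) from %d grid points",
                                       fit$method, fit$n_points), ...)
}
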