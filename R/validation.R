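#' Mean absolute error of the mean surface against a grid
#'
#' The fidelity statistic used to compare a model's predicted mean values
#' with a reference grid: the mean over grid records of
#' `|evaluate_mean(ga, pna) - mean|`.
#'
#' @param model a `reference_model` (or [surface_parameters]).
#' @param data a `grid_dataset` with a non-missing `mean` column.
#' @return The MAE in analyte units.
#' @export
mae_against_grid <- function(model, data) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0L) stop("empty grid dataset", call. = FALSE)
  if (anyNA(data$mean)) stop("grid mean column has missing values",
                             call. = FALSE)
  pred <- evaluate_mean(model, data$ga, data$pna)
  mean(abs(pred - data$mean))
}

#' Percentile-band coverage of a cohort
#'
#' Classifies every observation against the model's 5th-95th percentile band
#' at its own (GA, PNA) and tallies how many fall below, within, and above.
#' The coverage fraction — the share of values inside the band — is the
#' headline external-validation statistic for a reference-range model: under
#' a well-calibrated band it should approach 0.90 for values drawn from the
#' reference population.
#'
#' @param model a `reference_model`.
#' @param cohort a data.frame of observations (columns `ga`, `pna`,
#'   `analyte`, `value`; optionally a logical `transfused` column).
#' @param exclude_transfused drop observations flagged `transfused` before
#'   tallying. Default keeps them (with a message), since published cohorts
#'   typically report the transfused neonate alongside the rest.
#' @param quiet suppress extrapolation warnings and notes.
#' @return A list of class `validation_report`: `analyte`,
#'   `coverage_fraction`, `n_observations`, `n_below`, `n_within`, `n_above`,
#'   and the classified cohort in `$classified`.
#' @export
coverage <- function(model, cohort, exclude_transfused = FALSE,
                     quiet = FALSE) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  if ("transfused" %in% names(cohort)) {
    n_tr <- sum(cohort$transfused %in% TRUE)
    if (exclude_transfused) {
      cohort <- cohort[!(cohort$transfused %in% TRUE), , drop = FALSE]
      if (nrow(cohort) == 0L) {
        stop("all observations excluded as post-transfusion", call. = FALSE)
      }
    } else if (n_tr > 0L && !quiet) {
      message(sprintf("keeping %d post-transfusion observation(s); set exclude_transfused = TRUE to drop them", n_tr))
    }
  }
  cls <- classify(model, cohort, quiet = quiet)
  counts <- table(cls$flag)
  n <- nrow(cls)
  structure(
    list(analyte = model$analyte,
         coverage_fraction = as.numeric(counts[["within"]]) / n,
         n_observations = n,
         n_below = as.integer(counts[["below"]]),
         n_within = as.integer(counts[["within"]]),
         n_above = as.integer(counts[["above"]]),
         classified = cls),
    class = "validation_report"
  )
}

#' Pool per-analyte coverage reports
#'
#' Combines the tallies of several [coverage()] reports (e.g. the cHb and
#' Hct reports of one cohort) into one pooled report, the form in which a
#' joint "fraction of all values in range" is quoted.
#'
#' @param ... `validation_report` objects.
#' @return A `validation_report` with `analyte = "pooled"` and no
#'   `classified` component.
#' @export
pool_coverage <- function(...) {
  reports <- list(...)
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "validation_report")))
  tot <- function(field) sum(vapply(reports, `[[`, numeric(1), field))
  n <- tot("n_observations")
  structure(
    list(analyte = "pooled",
         coverage_fraction = tot("n_within") / n,
         n_observations = as.integer(n),
         n_below = as.integer(tot("n_below")),
         n_within = as.integer(tot("n_within")),
         n_above = as.integer(tot("n_above")),
         classified = NULL),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (%s): %d observation(s)\n",
              x$analyte, x$n_observations))
  cat(sprintf("  below band: %d   within: %d   above: %d\n",
              x$n_below, x$n_within, x$n_above))
  cat(sprintf("  coverage of the 5th-95th percentile band: %.1f%%\n",
              100 * x$coverage_fraction))
  invisible(x)
}

#' Full validation of a model against a grid and a cohort
#'
#' @param model a `reference_model`.
#' @param grid optional `grid_dataset` for the MAE statistic.
#' @param cohort optional observation data.frame for the coverage statistic.
#' @param ... passed to [coverage()].
#' @return A list with `mae_mean_surface`, `n_grid_points`, and the
#'   `validation_report` under `$coverage` (components are `NULL` when the
#'   corresponding input is absent).
#' @export
validate_model <- function(model, grid = NULL, cohort = NULL, ...) {
  out <- list(analyte = model$analyte, mae_mean_surface = NULL,
              n_grid_points = NULL, coverage = NULL)
  if (!is.null(grid)) {
    out$mae_mean_surface <- mae_against_grid(model, grid)
    out$n_grid_points <- nrow(grid)
  }
  if (!is.null(cohort)) out$coverage <- coverage(model, cohort, ...)
  out
}
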