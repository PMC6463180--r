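#' Noise specification for synthetic reference grids
#'
#' @param sd_mean Gaussian standard deviation added to the mean surface
#'   (analyte units; 0 = noise-free).
#' @param sd_band Gaussian standard deviation added independently to the
#'   p5 and p95 columns, on top of the mean-centred offsets. Nonzero values
#'   let tests probe how the offset estimator behaves when the band spread
#'   is not exactly symmetric.
#' @param seed integer seed; identical seed gives an identical dataset.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(sd_mean = 0, sd_band = 0, seed = 1L) {
  stopifnot(is.numeric(sd_mean), sd_mean >= 0,
            is.numeric(sd_band), sd_band >= 0)
  structure(list(sd_mean = sd_mean, sd_band = sd_band,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Cohort specification for synthetic clinical samples
#'
#' Defaults emulate a small cohort of clinically stable preterm neonates:
#' n = 19, GA 33.91 +/- 1.73 weeks, PNA 8.26 +/- 7.31 days.
#'
#' @param n number of neonates.
#' @param ga_mean,ga_sd GA distribution in weeks.
#' @param pna_mean,pna_sd PNA distribution in days.
#' @param value_sd Gaussian sd of measured values about the model mean
#'   surface (analyte units).
#' @param seed integer seed.
#' @param round_days round sampled PNA to whole days (off by default; the
#'   model itself is continuous in both ages).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 19L, ga_mean = 33.91, ga_sd = 1.73,
                        pna_mean = 8.26, pna_sd = 7.31,
                        value_sd = 1, seed = 1L, round_days = FALSE) {
  stopifnot(n >= 1L, ga_sd >= 0, pna_sd >= 0, value_sd >= 0)
  structure(list(n = as.integer(n), ga_mean = ga_mean, ga_sd = ga_sd,
                 pna_mean = pna_mean, pna_sd = pna_sd, value_sd = value_sd,
                 seed = as.integer(seed), round_days = round_days),
            class = "cohort_spec")
}

#' Default 77-point grid layout
#'
#' The empirical reference grid behind the shipped models has 77 points per
#' analyte, presented as a GA trend and PNA trends. The default synthetic
#' layout mirrors that structure: one GA sweep over integer weeks 22-42 at
#' day of birth (21 points), plus PNA sweeps over days 1-28 at two
#' representative gestational ages (2 x 28 points) - a moderately preterm
#' (GA 30) and a term (GA 40) neonate by default.
#'
#' @param ga_sweep integer GA values for the day-0 sweep.
#' @param pna_sweep PNA days for the two longitudinal sweeps.
#' @param sweep_ga the two (or more) GA values at which PNA sweeps run.
#' @return A data.frame with columns `ga`, `pna` (77 rows under defaults).
#' @export
default_grid_layout <- function(ga_sweep = 22:42, pna_sweep = 1:28,
                                sweep_ga = c(30, 40)) {
  rbind(
    data.frame(ga = as.double(ga_sweep), pna = 0),
    do.call(rbind, lapply(sweep_ga, function(g) {
      data.frame(ga = as.double(g), pna = as.double(pna_sweep))
    }))
  )
}

#' Generate a synthetic reference grid from a model
#'
#' Evaluates the model's mean and percentile surfaces at a set of (GA, PNA)
#' points and adds Gaussian noise per the [noise_spec()]. The mean column is
#' `evaluate_mean + N(0, sd_mean)`; the percentile columns are
#' `mean -/+ offset + N(0, sd_band)` independently. When band noise inverts
#' the ordering of a record, its (p5, mean, p95) triple is re-sorted so the
#' grid invariant p5 <= mean <= p95 always holds; the number of re-ordered
#' records is reported via a message.
#'
#' @param model a `reference_model`.
#' @param layout a data.frame of `ga`, `pna` points; defaults to the
#'   77-point [default_grid_layout()]. Alternatively give `ga_values` and
#'   `pna_values` for a full cartesian grid.
#' @param noise a [noise_spec()].
#' @param ga_values,pna_values optional vectors; when both are supplied the
#'   layout is their cartesian product.
#' @param percentiles include the p5/p95 columns (default TRUE).
#' @return A `grid_dataset`.
#' @export
generate_grid <- function(model, layout = default_grid_layout(),
                          noise = noise_spec(),
                          ga_values = NULL, pna_values = NULL,
                          percentiles = TRUE) {
  stopifnot(inherits(model, "reference_model"), inherits(noise, "noise_spec"))
  if (!is.null(ga_values) || !is.null(pna_values)) {
    if (is.null(ga_values) || is.null(pna_values) ||
        length(ga_values) == 0L || length(pna_values) == 0L) {
      stop("both ga_values and pna_values must be nonempty", call. = FALSE)
    }
    layout <- expand.grid(ga = as.double(ga_values),
                          pna = as.double(pna_values))
  }
  stopifnot(is.data.frame(layout), nrow(layout) >= 1L,
            all(c("ga", "pna") %in% names(layout)))
  set.seed(noise$seed)
  n <- nrow(layout)
  mu <- evaluate_mean(model$surface, layout$ga, layout$pna)
  mean_col <- mu + stats::rnorm(n, 0, noise$sd_mean)
  if (!percentiles) {
    return(grid_dataset(layout$ga, layout$pna, mean_col,
                        analyte = model$analyte))
  }
  p5 <- mean_col - model$offset + stats::rnorm(n, 0, noise$sd_band)
  p95 <- mean_col + model$offset + stats::rnorm(n, 0, noise$sd_band)
  trip <- cbind(p5, mean_col, p95)
  inverted <- !(trip[, 1] <= trip[, 2] & trip[, 2] <= trip[, 3])
  if (any(inverted)) {
    trip[inverted, ] <- t(apply(trip[inverted, , drop = FALSE], 1, sort))
    message(sprintf("re-ordered %d record(s) whose noisy band inverted",
                    sum(inverted)))
  }
  grid_dataset(layout$ga, layout$pna, trip[, 2], trip[, 1], trip[, 3],
               analyte = model$analyte)
}

# truncated-normal sampling by rejection; falls back to the bound-clamped
# draw only if rejection stalls (pathologically narrow truncation)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  for (tries in 1:1000) {
    draw <- stats::rnorm(2L * (n - length(out)), mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("truncated-normal rejection sampling failed to accept enough draws",
       call. = FALSE)
}

#' Generate a synthetic clinical cohort from a model
#'
#' Samples GA from a normal distribution truncated to the model's GA domain,
#' PNA from a normal truncated below at 0, and measured values as the model
#' mean at each neonate's ages plus Gaussian noise `N(0, value_sd)`.
#'
#' @param model a `reference_model`.
#' @param spec a [cohort_spec()].
#' @return A data.frame of observations (columns `id`, `ga`, `pna`,
#'   `analyte`, `value`).
#' @export
generate_cohort <- function(model, spec = cohort_spec()) {
  stopifnot(inherits(model, "reference_model"), inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ga <- .rtruncnorm(spec$n, spec$ga_mean, spec$ga_sd,
                    model$domain_ga[1], model$domain_ga[2])
  pna <- .rtruncnorm(spec$n, spec$pna_mean, spec$pna_sd, lower = 0)
  if (spec$round_days) pna <- round(pna)
  value <- evaluate_mean(model$surface, ga, pna) +
    stats::rnorm(spec$n, 0, spec$value_sd)
  data.frame(id = sprintf("sim%04d", seq_len(spec$n)),
             ga = ga, pna = pna, analyte = model$analyte, value = value,
             stringsAsFactors = FALSE)
}
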