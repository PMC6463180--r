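#' Tied-coefficient bi-quadratic surface parameters
#'
#' Creates the parameter set of one mean-value surface. The surface is a
#' bi-quadratic polynomial in gestational age (GA, weeks) and postnatal age
#' (PNA, days) with five free coefficients, the first of which is *tied*:
#' `p1` multiplies both the intercept and the linear PNA term, so
#'
#' \deqn{mean(GA, PNA) = p_1 (1 + PNA) + p_2 GA + p_3 GA^2 + p_4 GA\,PNA + p_5 PNA^2.}
#'
#' @param p1 coefficient in analyte units; doubles as intercept and as the
#'   linear-PNA coefficient (units per day).
#' @param p2 coefficient per week of GA.
#' @param p3 coefficient per week^2.
#' @param p4 coefficient per week x day.
#' @param p5 coefficient per day^2.
#' @return An object of class `surface_parameters`: a named numeric vector of
#'   length 5.
#' @examples
#' sp <- surface_parameters(-0.3409, 0.8300, -0.0093, 0.0003, 0.0058)
#' evaluate_mean(sp, ga = 40, pna = 0)
#' @export
surface_parameters <- function(p1, p2, p3, p4, p5) {
  p <- c(p1 = unname(p1), p2 = unname(p2), p3 = unname(p3),
         p4 = unname(p4), p5 = unname(p5))
  if (length(p) != 5L || !is.numeric(p) || !all(is.finite(p))) {
    stop("surface parameters must be exactly 5 finite real values",
         call. = FALSE)
  }
  structure(as.double(p), names = names(p), class = "surface_parameters")
}

#' @export
print.surface_parameters <- function(x, ...) {
  cat("Tied bi-quadratic surface parameters (p1 = intercept and linear-PNA):\n")
  print(unclass(x), ...)
  invisible(x)
}

# Published coefficients for the two shipped analytes, as printed.
.preset_coefficients <- list(
  cHb = c(-0.3409, 0.8300, -0.0093, 0.0003, 0.0058),
  Hct = c(-1.2956, 2.5369, -0.0300, 0.0069, 0.0190)
)
.preset_offsets <- c(cHb = 3.76, Hct = 10.69)
.analyte_units  <- c(cHb = "g/dL", Hct = "%")

#' Normalise an analyte name
#'
#' Accepts case-insensitive spellings ("chb", "cHb", "HCT", ...) and returns
#' the canonical "cHb" or "Hct".
#' @param analyte character scalar.
#' @return "cHb" or "Hct".
#' @export
normalize_analyte <- function(analyte) {
  if (!is.character(analyte) || length(analyte) != 1L) {
    stop("analyte must be a single character string", call. = FALSE)
  }
  key <- tolower(analyte)
  if (key == "chb") return("cHb")
  if (key == "hct") return("Hct")
  stop(sprintf("unknown analyte '%s' (expected 'cHb' or 'Hct')", analyte),
       call. = FALSE)
}

#' Construct a reference-range model
#'
#' A reference model couples a mean surface with a constant percentile offset:
#' the 5th and 95th percentile surfaces are `mean - offset` and
#' `mean + offset`, so the band width `p95 - p5 = 2 * offset` is the same at
#' every age. The validity domain is GA 22-42 weeks, PNA 0-28 days by default;
#' queries outside it are answered but flagged as extrapolation.
#'
#' @param analyte "cHb" or "Hct" (case-insensitive).
#' @param surface a [surface_parameters] object.
#' @param offset nonnegative half-width of the 5th-95th percentile band, in
#'   analyte units.
#' @param domain_ga closed GA interval in weeks, length-2 numeric.
#' @param domain_pna closed PNA interval in days, length-2 numeric.
#' @param unit unit string; defaults to "g/dL" for cHb and "%" for Hct.
#' @param provenance free-text note on where the parameters came from.
#' @return An object of class `reference_model`.
#' @seealso [preset_model()] for the shipped cHb and Hct models.
#' @export
reference_model <- function(analyte, surface, offset,
                            domain_ga = c(22, 42), domain_pna = c(0, 28),
                            unit = NULL, provenance = "user-defined") {
  analyte <- normalize_analyte(analyte)
  if (!inherits(surface, "surface_parameters")) {
    surface <- do.call(surface_parameters, as.list(unname(surface)))
  }
  if (!is.numeric(offset) || length(offset) != 1L || !is.finite(offset) ||
      offset < 0) {
    stop("offset must be a single nonnegative finite number", call. = FALSE)
  }
  stopifnot(length(domain_ga) == 2L, length(domain_pna) == 2L,
            domain_ga[1] <= domain_ga[2], domain_pna[1] <= domain_pna[2])
  if (is.null(unit)) unit <- .analyte_units[[analyte]]
  structure(
    list(analyte = analyte, unit = unit, surface = surface,
         offset = as.double(offset),
         domain_ga = as.double(domain_ga), domain_pna = as.double(domain_pna),
         provenance = provenance),
    class = "reference_model"
  )
}

#' Shipped reference models
#'
#' Returns the published model for one analyte: the five tied bi-quadratic
#' coefficients together with the constant percentile offset (3.76 g/dL for
#' cHb, 10.69% for Hct) and the GA 22-42 week / PNA 0-28 day domain.
#'
#' @param analyte "cHb" or "Hct" (case-insensitive).
#' @return A `reference_model`.
#' @examples
#' m <- preset_model("cHb")
#' evaluate_band(m, ga = 40, pna = 0)
#' @export
preset_model <- function(analyte) {
  analyte <- normalize_analyte(analyte)
  co <- .preset_coefficients[[analyte]]
  reference_model(
    analyte,
    surface_parameters(co[1], co[2], co[3], co[4], co[5]),
    offset = .preset_offsets[[analyte]],
    provenance = "published tied bi-quadratic fit to a digitized neonatal reference grid"
  )
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("Reference model: %s [%s]\n", x$analyte, x$unit))
  cat(sprintf("  domain: GA %g-%g weeks, PNA %g-%g days\n",
              x$domain_ga[1], x$domain_ga[2], x$domain_pna[1], x$domain_pna[2]))
  cat(sprintf("  percentile offset (band half-width): %g %s\n", x$offset, x$unit))
  cat("  surface coefficients:\n")
  print(unclass(x$surface))
  invisible(x)
}

.check_ages <- function(ga, pna) {
  if (!is.numeric(ga) || !is.numeric(pna) ||
      !all(is.finite(ga)) || !all(is.finite(pna))) {
    stop("ga and pna must be finite numeric values", call. = FALSE)
  }
  if (length(ga) != length(pna) && length(ga) != 1L && length(pna) != 1L) {
    stop("ga and pna lengths must match (or be scalar)", call. = FALSE)
  }
  invisible(NULL)
}

#' Evaluate the mean surface
#'
#' Computes `p1*(1 + pna) + p2*ga + p3*ga^2 + p4*ga*pna + p5*pna^2`, the mean
#' reference value at the given ages. Vectorised over `ga`/`pna`.
#'
#' @param surface a [surface_parameters] object, or a `reference_model` whose
#'   surface is used.
#' @param ga gestational age in weeks (finite numeric).
#' @param pna postnatal age in days (finite numeric).
#' @return Mean reference value(s) in analyte units.
#' @export
evaluate_mean <- function(surface, ga, pna) {
  if (inherits(surface, "reference_model")) surface <- surface$surface
  if (!inherits(surface, "surface_parameters")) {
    stop("surface must be a surface_parameters or reference_model object",
         call. = FALSE)
  }
  .check_ages(ga, pna)
  p <- unname(unclass(surface))
  p[1] * (1 + pna) + p[2] * ga + p[3] * ga^2 + p[4] * ga * pna + p[5] * pna^2
}

#' Partial derivatives of the mean surface
#'
#' Returns the GA- and PNA-gradients of the mean surface. Because `p1` is
#' tied, it reappears in the PNA derivative:
#' d/dGA = `p2 + 2*p3*ga + p4*pna`; d/dPNA = `p1 + p4*ga + 2*p5*pna`.
#' These support checking the expected physiology: reference values rise with
#' gestational age and fall over the first weeks of life.
#'
#' @inheritParams evaluate_mean
#' @return A list with numeric components `d_ga` and `d_pna`.
#' @export
partial_derivatives <- function(surface, ga, pna) {
  if (inherits(surface, "reference_model")) surface <- surface$surface
  .check_ages(ga, pna)
  p <- unname(unclass(surface))
  list(d_ga  = p[2] + 2 * p[3] * ga + p[4] * pna,
       d_pna = p[1] + p[4] * ga + 2 * p[5] * pna)
}

#' Evaluate the reference band at given ages
#'
#' Returns mean, 5th and 95th percentile values. The band is symmetric:
#' `p5 = mean - offset`, `p95 = mean + offset`. Ages outside the model domain
#' are still evaluated but flagged `extrapolated` and a warning is emitted,
#' since the surface is unvalidated there.
#'
#' @param model a `reference_model`.
#' @inheritParams evaluate_mean
#' @param quiet suppress the extrapolation warning.
#' @return A data.frame of class `reference_band` with columns `ga`, `pna`,
#'   `mean`, `p5`, `p95`, `extrapolated`.
#' @export
evaluate_band <- function(model, ga, pna, quiet = FALSE) {
  stopifnot(inherits(model, "reference_model"))
  .check_ages(ga, pna)
  n <- max(length(ga), length(pna))
  ga <- rep_len(as.double(ga), n)
  pna <- rep_len(as.double(pna), n)
  mean <- evaluate_mean(model$surface, ga, pna)
  extrapolated <- ga < model$domain_ga[1] | ga > model$domain_ga[2] |
    pna < model$domain_pna[1] | pna > model$domain_pna[2]
  if (any(extrapolated) && !quiet) {
    warning(sprintf(
      "%d of %d quer%s outside the validated domain (GA %g-%g wk, PNA %g-%g d); values are extrapolated",
      sum(extrapolated), n, if (n == 1L) "y is" else "ies are",
      model$domain_ga[1], model$domain_ga[2],
      model$domain_pna[1], model$domain_pna[2]), call. = FALSE)
  }
  structure(
    data.frame(ga = ga, pna = pna, mean = mean,
               p5 = mean - model$offset, p95 = mean + model$offset,
               extrapolated = extrapolated),
    class = c("reference_band", "data.frame")
  )
}

#' Create a single observation
#'
#' One measured analyte value on one neonate at a given gestational and
#' postnatal age.
#'
#' @param ga gestational age in weeks, > 0.
#' @param pna postnatal age in days, >= 0.
#' @param analyte "cHb" or "Hct".
#' @param value measured value in analyte units, > 0.
#' @param id opaque label.
#' @return A one-row data.frame with columns `id`, `ga`, `pna`, `analyte`,
#'   `value`.
#' @export
observation <- function(ga, pna, analyte, value, id = NA_character_) {
  analyte <- normalize_analyte(analyte)
  if (!is.finite(ga) || ga <= 0) stop("ga must be > 0", call. = FALSE)
  if (!is.finite(pna) || pna < 0) stop("pna must be >= 0", call. = FALSE)
  if (!is.finite(value) || value <= 0) stop("value must be > 0", call. = FALSE)
  data.frame(id = as.character(id), ga = as.double(ga), pna = as.double(pna),
             analyte = analyte, value = as.double(value),
             stringsAsFactors = FALSE)
}

#' Classify observations against a reference band
#'
#' Flags each measured value as below, within, or above the model's 5th-95th
#' percentile band at its own (GA, PNA). Both band edges are inclusive: a
#' value exactly equal to the 5th or 95th percentile is "within".
#'
#' @param model a `reference_model`.
#' @param obs a data.frame of observations (columns `ga`, `pna`, `analyte`,
#'   `value`, optionally `id`), e.g. from [observation()] or
#'   [read_cohort_csv()].
#' @param quiet suppress extrapolation warnings.
#' @return `obs` with the band columns (`mean`, `p5`, `p95`, `extrapolated`)
#'   and a `flag` factor with levels below/within/above appended.
#' @export
classify <- function(model, obs, quiet = FALSE) {
  stopifnot(inherits(model, "reference_model"), is.data.frame(obs))
  required <- c("ga", "pna", "analyte", "value")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols)) {
    stop("observations lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  analytes <- vapply(obs$analyte, normalize_analyte, character(1))
  if (any(analytes != model$analyte)) {
    stop(sprintf("analyte mismatch: model is %s but observations include %s",
                 model$analyte,
                 paste(unique(analytes[analytes != model$analyte]),
                       collapse = ", ")), call. = FALSE)
  }
  band <- evaluate_band(model, obs$ga, obs$pna, quiet = quiet)
  flag <- ifelse(obs$value < band$p5, "below",
                 ifelse(obs$value > band$p95, "above", "within"))
  out <- cbind(obs,
               band[, c("mean", "p5", "p95", "extrapolated")],
               flag = factor(flag, levels = c("below", "within", "above")))
  rownames(out) <- NULL
  out
}
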