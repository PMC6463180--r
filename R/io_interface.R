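#' Save / load a reference model as JSON
#'
#' The on-disk schema is a flat JSON object:
#' `{analyte, unit, parameters[5], offset, domain_ga[2], domain_pna[2],
#' provenance}`. Numbers are written at full precision so that
#' `load_model(save_model(m))` reproduces `m` bit-exactly. The shipped
#' presets live in the package as `extdata/chb_table1.json` and
#' `extdata/hct_table1.json`.
#'
#' @param model a `reference_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns a
#'   `reference_model`.
#' @examples
#' m <- load_model(system.file("extdata", "chb_table1.json",
#'                             package = "neoref"))
#' m$surface[["p2"]]  # 0.83
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "reference_model"))
  obj <- list(analyte = model$analyte, unit = model$unit,
              parameters = as.double(model$surface),
              offset = model$offset,
              domain_ga = model$domain_ga, domain_pna = model$domain_pna,
              provenance = model$provenance)
  # 17 significant digits guarantee an exact double round-trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("analyte", "parameters", "offset")
  missing_fields <- setdiff(required, names(obj))
  if (length(missing_fields)) {
    stop("model JSON lacks field(s): ", paste(missing_fields, collapse = ", "),
         call. = FALSE)
  }
  if (length(obj$parameters) != 5L || !is.numeric(obj$parameters)) {
    stop(sprintf("field 'parameters' must hold exactly 5 numbers (got %d)",
                 length(obj$parameters)), call. = FALSE)
  }
  if (!is.numeric(obj$offset) || obj$offset < 0) {
    stop("field 'offset' must be a nonnegative number", call. = FALSE)
  }
  p <- obj$parameters
  reference_model(
    obj$analyte, surface_parameters(p[1], p[2], p[3], p[4], p[5]),
    offset = obj$offset,
    domain_ga = if (!is.null(obj$domain_ga)) obj$domain_ga else c(22, 42),
    domain_pna = if (!is.null(obj$domain_pna)) obj$domain_pna else c(0, 28),
    unit = obj$unit,
    provenance = if (!is.null(obj$provenance)) obj$provenance else "unknown")
}

#' Read a cohort CSV
#'
#' Expected header: `id,ga_weeks,pna_days,analyte,value` (an optional
#' logical `transfused` column is carried through). Rows violating the
#' observation invariants (GA > 0, PNA >= 0, value > 0, known analyte) are
#' rejected with line-numbered messages; the accepted/rejected counts are
#' reported.
#'
#' @param path CSV file path.
#' @param quiet suppress the acceptance-count message.
#' @return A data.frame of observations (`id`, `ga`, `pna`, `analyte`,
#'   `value`[, `transfused`]).
#' @export
read_cohort_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("cohort file is empty: ", path, call. = FALSE)
  required <- c("id", "ga_weeks", "pna_days", "analyte", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("cohort CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ok <- rep(TRUE, nrow(raw))
  reason <- character(nrow(raw))
  analyte_ok <- tolower(raw$analyte) %in% c("chb", "hct")
  for (i in seq_len(nrow(raw))) {
    if (!analyte_ok[i]) {
      ok[i] <- FALSE; reason[i] <- sprintf("unknown analyte '%s'", raw$analyte[i])
    } else if (!is.finite(raw$ga_weeks[i]) || raw$ga_weeks[i] <= 0) {
      ok[i] <- FALSE; reason[i] <- "ga_weeks must be > 0"
    } else if (!is.finite(raw$pna_days[i]) || raw$pna_days[i] < 0) {
      ok[i] <- FALSE; reason[i] <- "pna_days must be >= 0"
    } else if (!is.finite(raw$value[i]) || raw$value[i] <= 0) {
      ok[i] <- FALSE; reason[i] <- "value must be > 0"
    }
  }
  if (any(!ok)) {
    for (i in which(!ok)) {
      # +1: header line
      message(sprintf("%s line %d rejected: %s", basename(path), i + 1L,
                      reason[i]))
    }
  }
  if (!quiet) {
    message(sprintf("%s: accepted %d row(s), rejected %d",
                    basename(path), sum(ok), sum(!ok)))
  }
  kept <- raw[ok, , drop = FALSE]
  out <- data.frame(id = as.character(kept$id), ga = kept$ga_weeks,
                    pna = kept$pna_days,
                    analyte = vapply(kept$analyte, normalize_analyte,
                                     character(1)),
                    value = kept$value, stringsAsFactors = FALSE)
  if ("transfused" %in% names(kept)) out$transfused <- as.logical(kept$transfused)
  rownames(out) <- NULL
  out
}

#' Write a cohort CSV
#'
#' @param cohort observation data.frame (`id`, `ga`, `pna`, `analyte`,
#'   `value`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- data.frame(id = cohort$id, ga_weeks = cohort$ga,
                    pna_days = cohort$pna, analyte = cohort$analyte,
                    value = cohort$value)
  if ("transfused" %in% names(cohort)) out$transfused <- cohort$transfused
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a grid-dataset CSV
#'
#' Dialect: header `ga_weeks,pna_days,mean,p5,p95`, comma-separated, "."
#' decimal; `p5`/`p95` cells may be empty (missing percentiles).
#'
#' @param path CSV file path.
#' @param analyte analyte tag to attach ("cHb" by default).
#' @return `read_grid_csv`: a `grid_dataset`; `write_grid_csv`: `path`,
#'   invisibly.
#' @export
read_grid_csv <- function(path, analyte = "cHb") {
  if (!file.exists(path)) stop("grid file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("grid file is empty: ", path, call. = FALSE)
  required <- c("ga_weeks", "pna_days", "mean")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("grid CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  grid_dataset(raw$ga_weeks, raw$pna_days, raw$mean,
               p5 = if ("p5" %in% names(raw)) raw$p5 else NA_real_,
               p95 = if ("p95" %in% names(raw)) raw$p95 else NA_real_,
               analyte = analyte)
}

#' @rdname read_grid_csv
#' @param data a `grid_dataset`.
#' @export
write_grid_csv <- function(data, path) {
  out <- data.frame(ga_weeks = data$ga, pna_days = data$pna,
                    mean = data$mean, p5 = data$p5, p95 = data$p95)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Export a tabulated reference table
#'
#' Evaluates the reference band over the cartesian grid of the requested
#' ages and (optionally) writes it as CSV with columns
#' `ga_weeks,pna_days,mean,p5,p95,extrapolated`. Values are stored at full
#' precision; `round_digits` rounds for clinical display in the written file
#' only — the returned table keeps full precision.
#'
#' @param model a `reference_model`.
#' @param ga_list,pna_list nonempty age vectors.
#' @param path optional output CSV path.
#' @param round_digits optional number of decimals for the written file.
#' @return The reference table as a data.frame (one row per GA x PNA pair),
#'   invisibly when `path` is given.
#' @export
export_reference_table <- function(model, ga_list, pna_list, path = NULL,
                                   round_digits = NULL) {
  stopifnot(length(ga_list) >= 1L, length(pna_list) >= 1L)
  grid <- expand.grid(ga = as.double(ga_list), pna = as.double(pna_list))
  band <- evaluate_band(model, grid$ga, grid$pna, quiet = TRUE)
  tab <- data.frame(ga_weeks = band$ga, pna_days = band$pna,
                    mean = band$mean, p5 = band$p5, p95 = band$p95,
                    extrapolated = band$extrapolated)
  attr(tab, "analyte") <- model$analyte
  attr(tab, "unit") <- model$unit
  if (!is.null(path)) {
    disp <- tab
    if (!is.null(round_digits)) {
      for (col in c("mean", "p5", "p95")) {
        disp[[col]] <- round(disp[[col]], round_digits)
      }
    }
    utils::write.csv(disp, path, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}
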