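#' Concentration-time profile tables
#'
#' A profile table is an ordinary tibble with one blood sample per row and
#' one profile per (subject, analyte) pair, the layout used throughout the
#' package for in vivo pharmacokinetic data.  Cassette dosing (several probe
#' substrates given together) is represented naturally: the same subject
#' appears once per analyte.
#'
#' Required columns:
#' \describe{
#'   \item{subject_id}{character; animal or volunteer label.}
#'   \item{analyte}{character; drug measured, e.g. `"midazolam"`.}
#'   \item{group}{character; treatment arm, e.g. `"vehicle"` or `"RIF"`.}
#'   \item{dose_mg_per_kg}{numeric, > 0; administered dose.}
#'   \item{route}{`"oral"` or `"intraperitoneal"`.}
#'   \item{time_h}{numeric, >= 0; sampling time after dosing, hours.}
#'   \item{conc}{numeric, >= 0; measured concentration, `NA` when `blq`.}
#'   \item{conc_unit}{`"ng/ml"` or `"ug/ml"`; constant within the table
#'     after validation.}
#'   \item{blq}{logical; `TRUE` when the sample was below the limit of
#'     quantification, in which case `conc` is `NA`.}
#' }
#'
#' `pk_profiles()` validates a data frame against these rules, normalises
#' all concentrations to `conc_unit` (1 ug/ml = 1000 ng/ml exactly), sorts
#' rows by subject, analyte and time, and returns a tibble.  Validation
#' requires, per profile: at least two samples, strictly increasing
#' non-negative times, non-negative concentrations for every quantifiable
#' sample, a single positive dose and a single route.
#'
#' @param data A data frame with the columns listed above.  A missing `blq`
#'   column is taken as all-`FALSE`; a missing `group` defaults to
#'   `"control"`.
#' @param conc_unit Target concentration unit, `"ng/ml"` or `"ug/ml"`.
#' @return A validated tibble sorted by subject, analyte and time, with all
#'   concentrations expressed in `conc_unit`.
#' @examples
#' pk_profiles(tibble::tibble(
#'   subject_id = "m1", analyte = "midazolam", group = "vehicle",
#'   dose_mg_per_kg = 10, route = "oral",
#'   time_h = c(0.5, 1, 2, 4), conc = c(4, 8, 6, 2),
#'   conc_unit = "ug/ml", blq = FALSE
#' ))
#' @export
pk_profiles <- function(data, conc_unit = c("ng/ml", "ug/ml")) {
  conc_unit <- match.arg(conc_unit)
  required <- c("subject_id", "analyte", "dose_mg_per_kg", "route",
                "time_h", "conc", "conc_unit")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Profile table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "transddi_format_error")
  }
  data <- tibble::as_tibble(data)
  if (!"group" %in% names(data)) data$group <- "control"
  if (!"blq" %in% names(data)) data$blq <- FALSE
  data$blq <- as.logical(data$blq)
  data$blq[is.na(data$blq)] <- FALSE

  bad_unit <- setdiff(unique(data$conc_unit), names(.conc_unit_factors))
  if (length(bad_unit) > 0) {
    abort(paste0("Unknown concentration unit(s): ",
                 paste(bad_unit, collapse = ", "),
                 " (expected ng/ml or ug/ml)"),
          class = "transddi_format_error")
  }
  bad_route <- setdiff(unique(data$route), c("oral", "intraperitoneal"))
  if (length(bad_route) > 0) {
    abort(paste0("Unknown route(s): ", paste(bad_route, collapse = ", ")),
          class = "transddi_validation_error")
  }

  .check_rows <- function(ok, what) {
    if (any(!ok)) {
      abort(paste0(what, " at row(s) ",
                   paste(which(!ok), collapse = ", ")),
            class = "transddi_validation_error")
    }
  }
  .check_rows(!is.na(data$time_h) & data$time_h >= 0, "Negative or missing time")
  .check_rows(data$blq | (!is.na(data$conc) & data$conc >= 0),
              "Negative or missing concentration in a quantifiable sample")
  .check_rows(!is.na(data$dose_mg_per_kg) & data$dose_mg_per_kg > 0,
              "Non-positive dose")
  data$conc[data$blq] <- NA_real_

  data$conc <- unname(data$conc * .conc_unit_factors[data$conc_unit] /
                        .conc_unit_factors[[conc_unit]])
  data$conc_unit <- conc_unit

  data <- dplyr::arrange(data, .data$subject_id, .data$analyte, .data$time_h)

  dup <- duplicated(data[, c("subject_id", "analyte", "time_h")])
  if (any(dup)) {
    abort(paste0("Duplicate (subject, analyte, time) sample(s) at sorted row(s) ",
                 paste(which(dup), collapse = ", ")),
          class = "transddi_validation_error")
  }
  per <- dplyr::summarise(
    dplyr::group_by(data, .data$subject_id, .data$analyte),
    n = dplyr::n(),
    n_dose = dplyr::n_distinct(.data$dose_mg_per_kg),
    n_route = dplyr::n_distinct(.data$route),
    .groups = "drop"
  )
  if (any(per$n < 2)) {
    abort("Each (subject, analyte) profile needs at least 2 samples",
          class = "transddi_validation_error")
  }
  if (any(per$n_dose > 1) || any(per$n_route > 1)) {
    abort("Dose and route must be constant within a (subject, analyte) profile",
          class = "transddi_validation_error")
  }
  data
}

# exact by definition: 1 ug/ml = 1000 ng/ml
.conc_unit_factors <- c("ng/ml" = 1, "ug/ml" = 1000)

#' Read concentration-time profiles from CSV
#'
#' Reads the flat one-sample-per-row CSV dialect described in
#' [pk_profiles()].  The `conc` field may hold the literal token `"BLQ"`
#' for a sample below the limit of quantification; such samples carry
#' `blq = TRUE` and no numeric concentration.  All concentrations are
#' converted to `conc_unit` on read.
#'
#' @param path Path to a CSV file with header row.
#' @inheritParams pk_profiles
#' @return A validated profile tibble (see [pk_profiles()]).
#' @seealso [write_pk_profiles()] for the inverse; the pair round-trips
#'   field-for-field.
#' @export
read_pk_profiles <- function(path, conc_unit = c("ng/ml", "ug/ml")) {
  conc_unit <- match.arg(conc_unit)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "transddi_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  required <- c("subject_id", "analyte", "dose_mg_per_kg", "route",
                "time_h", "conc", "conc_unit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s) in ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "transddi_format_error")
  }
  blq_token <- !is.na(raw$conc) & toupper(trimws(raw$conc)) == "BLQ"
  blq_col <- if ("blq" %in% names(raw)) {
    tolower(trimws(raw$blq)) %in% c("true", "t", "1", "yes")
  } else {
    rep(FALSE, nrow(raw))
  }
  raw$blq <- blq_token | blq_col
  raw$conc[raw$blq] <- NA_character_
  parsed <- dplyr::mutate(
    raw,
    dose_mg_per_kg = as.numeric(.data$dose_mg_per_kg),
    time_h = as.numeric(.data$time_h),
    conc = as.numeric(.data$conc)
  )
  pk_profiles(parsed, conc_unit = conc_unit)
}

#' Write concentration-time profiles to CSV
#'
#' Inverse of [read_pk_profiles()]: below-limit-of-quantification samples
#' are written with the `"BLQ"` token in the `conc` field so the file
#' round-trips exactly.  An empty collection yields a header-only file.
#'
#' @param profiles A validated profile tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pk_profiles <- function(profiles, path) {
  out <- dplyr::mutate(
    profiles,
    conc = dplyr::if_else(.data$blq, "BLQ", format(.data$conc, digits = 17,
                                                   trim = TRUE, scientific = FALSE))
  )
  cols <- c("subject_id", "analyte", "group", "dose_mg_per_kg", "route",
            "time_h", "conc", "conc_unit", "blq")
  out <- out[, intersect(cols, names(out))]
  tryCatch(
    readr::write_csv(out, path),
    error = function(e) abort(paste0("Cannot write ", path, ": ",
                                     conditionMessage(e)),
                              class = "transddi_io_error")
  )
  invisible(path)
}
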