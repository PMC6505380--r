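#' Linear trapezoidal AUC over the observed samples
#'
#' Area under the concentration-time curve from the first to the last
#' quantifiable sample (AUC_all) by the linear trapezoidal rule.
#' Below-limit-of-quantification samples follow the package BLQ policy:
#' leading BLQ samples are set to zero concentration, trailing and embedded
#' BLQ samples are dropped.
#'
#' @param time_h Sampling times, hours, strictly increasing.
#' @param conc Concentrations at `time_h`; `NA` marks a BLQ sample.
#' @return AUC in concentration x hours.
#' @examples
#' auc_trapezoid(c(0, 1, 2, 4), c(4, 8, 6, 2))  # 21
#' @export
auc_trapezoid <- function(time_h, conc) {
  s <- .apply_blq_policy(time_h, conc)
  if (length(s$time_h) < 2) {
    abort("Need at least 2 quantifiable samples for AUC",
          class = "transddi_insufficient_data")
  }
  sum(diff(s$time_h) * (head(s$conc, -1) + tail(s$conc, -1)) / 2)
}

# Leading BLQ (NA before the first quantifiable sample) -> concentration 0;
# any later BLQ -> sample dropped.
.apply_blq_policy <- function(time_h, conc) {
  stopifnot(length(time_h) == length(conc))
  quant <- !is.na(conc)
  if (!any(quant)) return(list(time_h = numeric(0), conc = numeric(0)))
  first_q <- which(quant)[1]
  leading <- seq_along(conc) < first_q
  conc[leading] <- 0
  keep <- leading | quant
  list(time_h = time_h[keep], conc = conc[keep])
}

#' Terminal elimination rate constant by best log-linear window
#'
#' Ordinary least squares of log concentration against time over candidate
#' terminal windows.  Candidates are the last k samples for k from
#' `min_points` up to all samples strictly after Tmax (Cmax itself is
#' excluded); the window with the highest adjusted R-squared wins, ties
#' going to the window with more points.  Zero-concentration and BLQ
#' samples cannot enter the fit.
#'
#' @inheritParams auc_trapezoid
#' @param min_points Smallest window size considered (>= 3).
#' @return A list with `lambda_z` (1/h), `half_life_h`, `r2adj`,
#'   `n_points`, and `intercept` (log concentration at time zero of the
#'   regression).
#' @examples
#' t <- c(1, 2, 4, 8)
#' fit_lambda_z(t, 100 * exp(-0.5 * t))$lambda_z  # 0.5
#' @export
fit_lambda_z <- function(time_h, conc, min_points = 3) {
  if (min_points < 3) abort("min_points must be >= 3",
                            class = "transddi_domain_error")
  s <- .apply_blq_policy(time_h, conc)
  pos <- s$conc > 0
  t <- s$time_h[pos]
  y <- log(s$conc[pos])
  n <- length(t)
  i_max <- which.max(s$conc[pos])  # earliest maximum
  max_window <- n - i_max          # points strictly after Tmax
  best <- NULL
  for (k in seq(from = min_points, by = 1,
                length.out = max(0, min(n, max_window) - min_points + 1))) {
    idx <- seq.int(n - k + 1, n)
    fit <- lm(y[idx] ~ t[idx])
    slope <- coef(fit)[[2]]
    if (!is.finite(slope) || slope >= 0) next
    r2adj <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || r2adj >= best$r2adj) {  # ties -> more points
      best <- list(lambda_z = -slope,
                   half_life_h = log(2) / -slope,
                   r2adj = r2adj,
                   n_points = k,
                   intercept = coef(fit)[[1]])
    }
  }
  if (is.null(best)) {
    abort("No terminal window with a positive elimination rate; terminal phase undefined",
          class = "transddi_terminal_phase_undefined")
  }
  best
}

#' AUC extrapolated to infinity
#'
#' `AUC_all + C_last / lambda_z`, where `C_last` is the last quantifiable
#' concentration and `lambda_z` comes from [fit_lambda_z()].  When the
#' profile ends at zero concentration there is nothing to extrapolate and
#' AUC_inf equals AUC_all.
#'
#' @inheritParams fit_lambda_z
#' @return AUC_inf in concentration x hours.
#' @export
auc_to_infinity <- function(time_h, conc, min_points = 3) {
  auc_all <- auc_trapezoid(time_h, conc)
  s <- .apply_blq_policy(time_h, conc)
  c_last <- tail(s$conc, 1)
  if (c_last == 0) return(auc_all)
  lz <- fit_lambda_z(time_h, conc, min_points = min_points)
  auc_all + c_last / lz$lambda_z
}

#' Apparent oral clearance CL/F
#'
#' Dose divided by AUC_inf, in ml/h per kg, for any supported input
#' concentration unit.  With dose in mg/kg and AUC in h.ug/ml this is
#' `1000 * dose / auc_inf`.
#'
#' @param dose_mg_per_kg Administered dose, mg/kg, > 0.
#' @param auc_inf AUC extrapolated to infinity, in `conc_unit` x hours, > 0.
#' @param conc_unit Unit of the concentrations the AUC was computed from.
#' @return CL/F in ml/h per kg.
#' @examples
#' cl_over_f(10, 76)  # 131.6, the vehicle-arm value reported as 132
#' @export
cl_over_f <- function(dose_mg_per_kg, auc_inf, conc_unit = c("ug/ml", "ng/ml")) {
  conc_unit <- match.arg(conc_unit)
  if (any(dose_mg_per_kg <= 0) || any(auc_inf <= 0)) {
    abort("dose and AUC_inf must be positive", class = "transddi_domain_error")
  }
  dose_ng_per_kg <- dose_mg_per_kg * 1e6
  auc_ng <- auc_inf * .conc_unit_factors[[conc_unit]]
  dose_ng_per_kg / auc_ng
}

#' Ratio of group mean AUCs
#'
#' The AUC ratio (AUCR) of a treated over a control arm, computed as the
#' ratio of arithmetic group means, the convention behind reported
#' fold-changes such as 2008 / 230 h.ng/ml = 8.7-fold.
#'
#' @param treated,control Positive AUC values for each arm, same units.
#' @return The dimensionless ratio mean(treated) / mean(control).
#' @export
group_aucr <- function(treated, control) {
  if (length(treated) == 0 || length(control) == 0) {
    abort("Both groups must be non-empty", class = "transddi_insufficient_data")
  }
  if (any(treated <= 0) || any(control <= 0)) {
    abort("AUC values must be positive", class = "transddi_domain_error")
  }
  mean(treated) / mean(control)
}

#' Noncompartmental analysis of a profile table
#'
#' Runs model-free PK parameter estimation on every (subject, analyte)
#' profile in a validated table (see [pk_profiles()]): Cmax and Tmax from
#' the observed samples (earliest time wins a tie), AUC_all by linear
#' trapezoid, the terminal rate constant from the best adjusted-R-squared
#' log-linear window ([fit_lambda_z()]), AUC_inf, terminal half-life and
#' CL/F.  Profiles with an undefined terminal phase keep their AUC_all and
#' report `NA` for the extrapolated quantities.
#'
#' @param profiles A validated profile tibble.
#' @param min_lambda_points Minimum samples in the terminal regression.
#' @return A tibble with one row per (subject, analyte): `subject_id`,
#'   `analyte`, `group`, `dose_mg_per_kg`, `conc_unit`, `c_max`, `t_max_h`,
#'   `auc_all`, `auc_inf`, `lambda_z`, `terminal_half_life_h`,
#'   `cl_over_f_ml_h_kg`, `n_lambda_points`, `lambda_fit_r2adj`.
#' @export
nca <- function(profiles, min_lambda_points = 3) {
  profiles |>
    dplyr::group_by(.data$subject_id, .data$analyte) |>
    dplyr::group_modify(~ .nca_one(.x, min_lambda_points)) |>
    dplyr::ungroup()
}

.nca_one <- function(d, min_points) {
  s <- .apply_blq_policy(d$time_h, d$conc)
  i_max <- which.max(s$conc)
  auc_all <- auc_trapezoid(d$time_h, d$conc)
  lz <- tryCatch(fit_lambda_z(d$time_h, d$conc, min_points = min_points),
                 transddi_terminal_phase_undefined = function(e) NULL)
  c_last <- tail(s$conc, 1)
  auc_inf <- if (c_last == 0) auc_all
             else if (is.null(lz)) NA_real_
             else auc_all + c_last / lz$lambda_z
  tibble::tibble(
    group = d$group[1],
    dose_mg_per_kg = d$dose_mg_per_kg[1],
    conc_unit = d$conc_unit[1],
    c_max = s$conc[i_max],
    t_max_h = s$time_h[i_max],
    auc_all = auc_all,
    auc_inf = auc_inf,
    lambda_z = if (is.null(lz)) NA_real_ else lz$lambda_z,
    terminal_half_life_h = if (is.null(lz)) NA_real_ else lz$half_life_h,
    cl_over_f_ml_h_kg = if (is.na(auc_inf) || auc_inf <= 0) NA_real_
                        else cl_over_f(d$dose_mg_per_kg[1],
                                       auc_inf, d$conc_unit[1]),
    n_lambda_points = if (is.null(lz)) NA_integer_ else lz$n_points,
    lambda_fit_r2adj = if (is.null(lz)) NA_real_ else lz$r2adj
  )
}

#' Group summary of NCA results
#'
#' Mean and standard deviation of each NCA parameter by treatment group and
#' analyte, the usual PK-table layout.
#'
#' @param nca_results Output of [nca()].
#' @return A tibble with one row per (analyte, group) and `<param>_mean` /
#'   `<param>_sd` columns plus the group size `n`.
#' @export
nca_summary <- function(nca_results) {
  params <- c("c_max", "t_max_h", "auc_all", "auc_inf",
              "terminal_half_life_h", "cl_over_f_ml_h_kg")
  nca_results |>
    dplyr::group_by(.data$analyte, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(params),
                    list(mean = ~ mean(.x, na.rm = TRUE),
                         sd = ~ sd(.x, na.rm = TRUE))),
      .groups = "drop"
    )
}
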