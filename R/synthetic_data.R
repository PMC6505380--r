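#' One-compartment oral concentration-time model
#'
#' Closed-form concentration for first-order absorption and elimination,
#' \deqn{C(t) = 1000\, D\, (F/V)\, \frac{k_a}{k_a - k_e}
#'       \left(e^{-k_e t} - e^{-k_a t}\right)}
#' in ug/ml when `dose` is in mg/kg and `f_over_v` (bioavailability over
#' apparent volume of distribution) is in 1/(ml/kg).  Flip-flop kinetics
#' (`ka < ke`) is allowed; at `ka == ke` the analytic limit
#' `1000 D (F/V) ka t exp(-ka t)` is used.  The analytic
#' `AUC(0, Inf) = 1000 D (F/V) / ke` and `CL/F = ke / (F/V)` ml/h per kg.
#'
#' @param t Times, hours.
#' @param dose Dose, mg/kg.
#' @param f_over_v Bioavailability over volume of distribution, 1/(ml/kg).
#' @param ka,ke First-order absorption and elimination rates, 1/h.
#' @return Concentrations in ug/ml at `t`.
#' @export
one_compartment_oral <- function(t, dose, f_over_v, ka, ke) {
  stopifnot(dose > 0, f_over_v > 0, ka > 0, ke > 0)
  scale <- 1000 * dose * f_over_v
  if (ka == ke) {
    scale * ka * t * exp(-ka * t)
  } else {
    scale * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))
  }
}

#' Simulate a sparse oral blood-sampling profile
#'
#' Evaluates the one-compartment oral model at the sampling times and
#' applies multiplicative lognormal measurement noise with the given
#' coefficient of variation (unit mean, so zero noise returns the model
#' exactly and a concentration of zero stays zero).  The default sampling
#' grid mimics a sparse rodent design: 8 samples from 15 minutes to 24
#' hours.  The default kinetic parameters give a profile on the scale of
#' an oral probe-drug study in mice: dose 10 mg/kg, absorption half-life
#' about 14 min, elimination half-life about 1.7 h, Cmax in the tens of
#' ug/ml and CL/F near 130 ml/h per kg.
#'
#' @inheritParams one_compartment_oral
#' @param sampling_times Sampling times, hours, strictly increasing.
#' @param noise_cv Lognormal measurement coefficient of variation
#'   (fraction; 0 = noiseless).
#' @param seed Optional integer seed; identical seeds give identical
#'   profiles.
#' @param subject_id,analyte,group,route Profile metadata.
#' @return A validated profile tibble (see [pk_profiles()]) with
#'   concentrations in ug/ml.
#' @examples
#' simulate_profile(seed = 1, noise_cv = 0.1)
#' @export
simulate_profile <- function(dose = 10, f_over_v = 0.003, ka = 3, ke = 0.4,
                             sampling_times = c(0.25, 0.5, 1, 2, 4, 8, 12, 24),
                             noise_cv = 0, seed = NULL,
                             subject_id = "sim-1", analyte = "probe",
                             group = "control", route = "oral") {
  if (noise_cv < 0) abort("noise_cv must be >= 0",
                          class = "transddi_domain_error")
  conc <- one_compartment_oral(sampling_times, dose, f_over_v, ka, ke)
  conc <- conc * .lognormal_noise(length(conc), noise_cv, seed)
  pk_profiles(tibble::tibble(
    subject_id = subject_id, analyte = analyte, group = group,
    dose_mg_per_kg = dose, route = route,
    time_h = sampling_times, conc = conc,
    conc_unit = "ug/ml", blq = FALSE
  ), conc_unit = "ug/ml")
}

# unit-mean multiplicative lognormal noise at a given CV
.lognormal_noise <- function(n, cv, seed = NULL) {
  if (cv == 0) return(rep(1, n))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate paired control / treated cohorts for a DDI study
#'
#' Generates two arms of sparse oral profiles with lognormal inter-subject
#' variability on the elimination rate and on F/V.  The treated arm's
#' elimination rate is scaled mechanistically according to the static
#' model: under inhibition by `(1 - f_m) + f_m / (1 + i_over_ki)`, so that
#' the true AUC ratio equals [aucr_forward()]`(f_m, i_over_ki)`; under
#' induction by `(1 - f_m) + f_m * induction_fold`, giving a true AUC
#' ratio of `1 / ((1 - f_m) + f_m * induction_fold)` (a fall in exposure).
#' Exactly one of `i_over_ki` / `induction_fold` must be given.  The
#' inhibitor or inducer exposure is treated as constant over the victim
#' profile, matching the static-model assumption.
#'
#' A single integer seed drives all subjects: draws are consumed in a fixed
#' subject order, so cohorts are bit-reproducible.
#'
#' @inheritParams simulate_profile
#' @param f_m Fraction of victim clearance through the affected enzyme.
#' @param i_over_ki Inhibitor potency `[I]/Ki` (inhibition arm), or `NULL`.
#' @param induction_fold Fold induction of the affected pathway (>= 1), or
#'   `NULL`.
#' @param n_per_group Subjects per arm, >= 2.
#' @param inter_subject_cv Lognormal between-subject CV on ke and F/V.
#' @param seed Integer seed (required for reproducibility contracts).
#' @return A validated profile tibble with `group` `"control"` /
#'   `"treated"` and one subject per `subject_id`.
#' @export
simulate_ddi_cohorts <- function(f_m, i_over_ki = NULL, induction_fold = NULL,
                                 n_per_group = 8, inter_subject_cv = 0.1,
                                 dose = 10, f_over_v = 0.003, ka = 3, ke = 0.4,
                                 sampling_times = c(0.25, 0.5, 1, 2, 4, 8, 12, 24),
                                 noise_cv = 0, seed = NULL,
                                 analyte = "probe") {
  if (is.null(i_over_ki) == is.null(induction_fold)) {
    abort("give exactly one of i_over_ki or induction_fold",
          class = "transddi_config_error")
  }
  if (n_per_group < 2) abort("n_per_group must be >= 2",
                             class = "transddi_config_error")
  if (f_m < 0 || f_m > 1) abort("f_m must lie in [0, 1]",
                                class = "transddi_domain_error")
  cl_scale <- if (!is.null(i_over_ki)) {
    if (i_over_ki < 0) abort("i_over_ki must be >= 0",
                             class = "transddi_domain_error")
    (1 - f_m) + f_m / (1 + i_over_ki)
  } else {
    if (induction_fold < 1) abort("induction_fold must be >= 1",
                                  class = "transddi_domain_error")
    (1 - f_m) + f_m * induction_fold
  }

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  sdlog <- sqrt(log(1 + inter_subject_cv^2))
  one_subject <- function(id, group, ke_scale) {
    ke_i <- ke * ke_scale *
      (if (inter_subject_cv > 0) rlnorm(1, -sdlog^2 / 2, sdlog) else 1)
    fov_i <- f_over_v *
      (if (inter_subject_cv > 0) rlnorm(1, -sdlog^2 / 2, sdlog) else 1)
    conc <- one_compartment_oral(sampling_times, dose, fov_i, ka, ke_i) *
      .lognormal_noise(length(sampling_times), noise_cv)
    tibble::tibble(
      subject_id = id, analyte = analyte, group = group,
      dose_mg_per_kg = dose, route = "oral",
      time_h = sampling_times, conc = conc,
      conc_unit = "ug/ml", blq = FALSE
    )
  }
  rows <- dplyr::bind_rows(
    purrr::map(seq_len(n_per_group),
               ~ one_subject(sprintf("ctl-%02d", .x), "control", 1)),
    purrr::map(seq_len(n_per_group),
               ~ one_subject(sprintf("trt-%02d", .x), "treated", cl_scale))
  )
  pk_profiles(rows, conc_unit = "ug/ml")
}

#' Simulate a Michaelis-Menten assay table
#'
#' Velocities `vmax * S / (km + S)` on a substrate grid with unit-mean
#' multiplicative lognormal noise, the fixture generator for kinetics
#' fits.
#'
#' @param km,vmax True Michaelis constant (uM) and maximal velocity.
#' @param s_grid Substrate concentrations, uM; must be non-degenerate.
#' @param noise_cv Lognormal CV of the velocity noise (0 = exact).
#' @param n_replicates Replicate measurements per substrate concentration.
#' @param seed Optional integer seed.
#' @return An assay tibble with `conc_um`, `velocity`, `replicate`.
#' @examples
#' simulate_mm_assay(1.2, 5100, noise_cv = 0.05, seed = 7)
#' @export
simulate_mm_assay <- function(km, vmax,
                              s_grid = c(0.25, 0.5, 1, 2, 4, 8, 16, 32) * km,
                              noise_cv = 0, n_replicates = 1, seed = NULL) {
  if (km <= 0 || vmax <= 0) abort("km and vmax must be positive",
                                  class = "transddi_domain_error")
  if (length(s_grid) == 0 || dplyr::n_distinct(s_grid) < 2) {
    abort("s_grid must contain at least 2 distinct concentrations",
          class = "transddi_config_error")
  }
  s <- rep(s_grid, times = n_replicates)
  v <- vmax * s / (km + s)
  v <- v * .lognormal_noise(length(s), noise_cv, seed)
  tibble::tibble(
    conc_um = s,
    velocity = v,
    replicate = rep(seq_len(n_replicates), each = length(s_grid))
  )
}
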