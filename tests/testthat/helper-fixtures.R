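# Shared fixture builders for the suite.

make_profile_tbl <- function(time_h, conc, subject_id = "s1",
                             analyte = "drug", group = "control",
                             dose = 10, conc_unit = "ug/ml",
                             blq = FALSE) {
  tibble::tibble(
    subject_id = subject_id, analyte = analyte, group = group,
    dose_mg_per_kg = dose, route = "oral",
    time_h = time_h, conc = conc, conc_unit = conc_unit, blq = blq
  )
}

# validated profile table, keeping ug/ml so concentrations are untouched
make_profiles <- function(...) {
  pk_profiles(make_profile_tbl(...), conc_unit = "ug/ml")
}

# noiseless one-compartment oral profile as a validated table
make_oral_profile <- function(times, dose = 10, f_over_v = 0.003,
                              ka = 3, ke = 0.4, ...) {
  make_profiles(times, one_compartment_oral(times, dose, f_over_v, ka, ke),
                dose = dose, ...)
}
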