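test_that("linear trapezoid reproduces hand-computed areas", {
  expect_equal(auc_trapezoid(c(0, 1), c(0, 0)), 0)
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 10, 0)), 10)
  # 0.5*(4+8) + 0.5*(8+6) + 2*0.5*(6+2) = 21
  expect_equal(auc_trapezoid(c(0, 1, 2, 4), c(4, 8, 6, 2)), 21)
  expect_error(auc_trapezoid(1, 5), class = "transddi_insufficient_data")
})

test_that("AUC_all is invariant under insertion of a collinear sample", {
  t <- c(0, 1, 2, 4)
  c0 <- c(4, 8, 6, 2)
  base <- auc_trapezoid(t, c0)
  # insert the midpoint of the last segment (collinear)
  expect_equal(auc_trapezoid(c(0, 1, 2, 3, 4), c(4, 8, 6, 4, 2)), base)
})

test_that("BLQ policy zeroes leading BLQ and drops trailing BLQ", {
  t <- c(0.25, 0.5, 1, 2)
  # leading BLQ counts as 0; trailing BLQ sample is dropped
  a <- auc_trapezoid(t, c(NA, 8, 6, NA))
  expect_equal(a, 0.25 * (0 + 8) / 2 + 0.5 * (8 + 6) / 2)
})

test_that("lambda_z is exact on log-linear data and gives the matching half-life", {
  t <- c(1, 2, 4, 8)
  fit <- fit_lambda_z(t, 100 * exp(-0.5 * t))
  expect_equal(fit$lambda_z, 0.5, tolerance = 1e-12)
  expect_equal(fit$half_life_h, log(2) / 0.5, tolerance = 1e-12)
  expect_error(fit_lambda_z(t, c(1, 2, 3, 4)),
               class = "transddi_terminal_phase_undefined")
})

test_that("lambda_z recovers ke within 2% on a noiseless oral curve over 5 half-lives", {
  ke <- 0.4
  times <- seq(0.25, 5 * log(2) / ke, length.out = 12)
  conc <- one_compartment_oral(times, 10, 0.003, ka = 3, ke = ke)
  fit <- fit_lambda_z(times, conc)
  expect_equal(fit$lambda_z, ke, tolerance = 0.02)
})

test_that("AUC_inf matches the analytic oral integral within 5% on dense profiles", {
  # monoexponential: analytic AUC = C0/ke = 100/0.5 = 200
  t <- exp(seq(log(0.1), log(16), length.out = 8))
  a <- auc_to_infinity(t, 100 * exp(-0.5 * t))
  expect_equal(a, 200, tolerance = 0.05)

  # one-compartment oral: analytic AUC = 1000*D*FoV/ke
  ke <- 0.4
  times <- seq(0.1, 5 * log(2) / ke, length.out = 20)
  conc <- one_compartment_oral(times, 10, 0.003, 3, ke)
  expect_equal(auc_to_infinity(times, conc), 1000 * 10 * 0.003 / ke,
               tolerance = 0.05)

  # profile ending at zero has nothing to extrapolate
  expect_equal(auc_to_infinity(c(0, 1, 2, 3, 4), c(0, 10, 5, 2, 0)),
               auc_trapezoid(c(0, 1, 2, 3, 4), c(0, 10, 5, 2, 0)))
})

test_that("CL/F reproduces the reported vehicle and induced-arm values", {
  expect_equal(cl_over_f(10, 76, "ug/ml"), 10000 / 76)   # reported as 132
  expect_equal(cl_over_f(10, 76, "ug/ml"), 132, tolerance = 0.01)
  expect_equal(cl_over_f(10, 24.2, "ug/ml"), 413, tolerance = 0.002)
  # normalisation: dose D with AUC 1000*D in matching units gives exactly 1
  expect_equal(cl_over_f(7, 7000, "ug/ml"), 1)
  # unit consistency: same profile in ng/ml gives the same clearance
  expect_equal(cl_over_f(10, 76000, "ng/ml"), cl_over_f(10, 76, "ug/ml"))
  expect_error(cl_over_f(0, 76), class = "transddi_domain_error")
})

test_that("cl_over_f times AUC returns the dose in consistent units", {
  d <- c(1, 10, 3.5)
  a <- c(76, 24.2, 500)
  expect_equal(cl_over_f(d, a, "ug/ml") * a, d * 1000)
})

test_that("group AUC ratio is the ratio of arithmetic means", {
  expect_equal(group_aucr(2008, 230), 8.73, tolerance = 5e-4)
  expect_equal(round(group_aucr(2008, 230), 1), 8.7)
  expect_equal(group_aucr(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(group_aucr(2 * c(1, 5, 9), c(1, 5, 9)), 2)
  expect_error(group_aucr(numeric(0), 1), class = "transddi_insufficient_data")
})

test_that("nca() recovers Cmax/Tmax and the one-compartment truth on noiseless data", {
  ke <- 0.4; fov <- 0.003; dose <- 10
  times <- seq(0.1, 5 * log(2) / ke, length.out = 20)
  prof <- make_oral_profile(times, dose = dose, f_over_v = fov, ke = ke)
  res <- nca(prof)
  expect_identical(nrow(res), 1L)
  conc <- one_compartment_oral(times, dose, fov, 3, ke)
  expect_equal(res$c_max, max(conc))
  expect_equal(res$t_max_h, times[which.max(conc)])
  expect_equal(res$lambda_z, ke, tolerance = 0.02)
  expect_equal(res$auc_inf, 1000 * dose * fov / ke, tolerance = 0.05)
  # CL/F truth is ke / (F/V) ml/h per kg
  expect_equal(res$cl_over_f_ml_h_kg, ke / fov, tolerance = 0.05)
  expect_true(res$auc_inf >= res$auc_all)
  expect_equal(res$terminal_half_life_h, log(2) / res$lambda_z)
})

test_that("Cmax ties go to the earliest time", {
  prof <- make_profiles(c(0.5, 1, 2, 4), c(2, 9, 9, 1))
  res <- nca(prof)
  expect_equal(res$t_max_h, 1)
})

test_that("nca_summary mirrors the mean +/- SD group layout", {
  set.seed(11)
  cohort <- simulate_ddi_cohorts(f_m = 0.9, i_over_ki = 20, n_per_group = 3,
                                 inter_subject_cv = 0.05, seed = 11)
  sm <- nca_summary(nca(cohort))
  expect_identical(nrow(sm), 2L)
  expect_identical(sort(sm$group), c("control", "treated"))
  expect_true(all(c("auc_inf_mean", "auc_inf_sd", "c_max_mean", "n") %in% names(sm)))
  expect_identical(sm$n, c(3L, 3L))
})
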