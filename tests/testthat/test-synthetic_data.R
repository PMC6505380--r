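test_that("the oral model is zero at t = 0 and matches its analytic AUC", {
  expect_equal(one_compartment_oral(0, 10, 0.003, 3, 0.4), 0)
  # dense-grid NCA against the closed-form AUC(0, Inf) = 1000*D*FoV/ke
  times <- c(seq(0.05, 2, by = 0.05), seq(2.25, 30, by = 0.25))
  conc <- one_compartment_oral(times, 10, 0.003, 3, 0.4)
  expect_equal(auc_to_infinity(times, conc), 1000 * 10 * 0.003 / 0.4,
               tolerance = 0.01)
})

test_that("the ka == ke limit is continuous with the general formula", {
  t <- c(0.5, 1, 2, 4)
  lim <- one_compartment_oral(t, 10, 0.003, 1, 1)
  near <- one_compartment_oral(t, 10, 0.003, 1 + 1e-9, 1)
  expect_equal(lim, near, tolerance = 1e-6)
})

test_that("flip-flop kinetics (ka < ke) yields a valid positive profile", {
  t <- c(0.5, 1, 2, 4, 8, 24)
  conc <- one_compartment_oral(t, 10, 0.003, ka = 0.2, ke = 1)
  expect_true(all(conc > 0))
})

test_that("profile simulation is bit-reproducible by seed and noisy otherwise", {
  p1 <- simulate_profile(noise_cv = 0.2, seed = 123)
  p2 <- simulate_profile(noise_cv = 0.2, seed = 123)
  p3 <- simulate_profile(noise_cv = 0.2, seed = 124)
  expect_identical(p1, p2)
  expect_false(isTRUE(all.equal(p1$conc, p3$conc)))
  # zero noise returns the model curve exactly
  p0 <- simulate_profile(noise_cv = 0)
  expect_equal(p0$conc, one_compartment_oral(p0$time_h, 10, 0.003, 3, 0.4))
})

test_that("lognormal noise has unit mean at the requested CV", {
  # deep in saturation every velocity is ~vmax, so the spread is pure noise
  a <- simulate_mm_assay(1, 1, s_grid = c(1e6, 2e6), noise_cv = 0.25,
                         n_replicates = 10000, seed = 77)
  x <- a$velocity
  expect_equal(mean(x), 1, tolerance = 0.01)
  expect_equal(sd(x) / mean(x), 0.25, tolerance = 0.03)
})

test_that("noiseless DDI cohorts reproduce the static-model AUCR", {
  cohort <- simulate_ddi_cohorts(f_m = 0.94, i_over_ki = 21, n_per_group = 2,
                                 inter_subject_cv = 0, seed = 1)
  res <- nca(cohort)
  aucr <- group_aucr(res$auc_inf[res$group == "treated"],
                     res$auc_inf[res$group == "control"])
  expect_equal(aucr, aucr_forward(0.94, 21), tolerance = 0.05)

  null <- simulate_ddi_cohorts(f_m = 0.94, i_over_ki = 0, n_per_group = 2,
                               inter_subject_cv = 0, seed = 1)
  rn <- nca(null)
  expect_equal(group_aucr(rn$auc_inf[rn$group == "treated"],
                          rn$auc_inf[rn$group == "control"]), 1,
               tolerance = 1e-6)
})

test_that("induction cohorts show the analytic fall in exposure", {
  # near-complete CYP dependence with 12-fold induction: AUC drops ~12-fold
  fold <- 12; fm <- 0.98
  cohort <- simulate_ddi_cohorts(f_m = fm, induction_fold = fold,
                                 n_per_group = 2, inter_subject_cv = 0,
                                 sampling_times = c(seq(0.05, 8, by = 0.05),
                                                    seq(8.5, 48, by = 0.5)),
                                 seed = 2)
  res <- nca(cohort)
  aucr <- group_aucr(res$auc_inf[res$group == "treated"],
                     res$auc_inf[res$group == "control"])
  expect_equal(aucr, 1 / ((1 - fm) + fm * fold), tolerance = 0.02)
})

test_that("cohort simulation validates its arm specification", {
  expect_error(simulate_ddi_cohorts(f_m = 0.9),
               class = "transddi_config_error")
  expect_error(simulate_ddi_cohorts(f_m = 0.9, i_over_ki = 2,
                                    induction_fold = 3),
               class = "transddi_config_error")
  expect_error(simulate_ddi_cohorts(f_m = 0.9, i_over_ki = 2, n_per_group = 1),
               class = "transddi_config_error")
})

test_that("assay simulation hits half-Vmax at S = Km and is seed-stable", {
  a <- simulate_mm_assay(km = 2, vmax = 40, s_grid = c(0.5, 1, 2, 4, 8))
  expect_equal(a$velocity[a$conc_um == 2], 20)
  s1 <- simulate_mm_assay(1.2, 5100, noise_cv = 0.05, seed = 6)
  s2 <- simulate_mm_assay(1.2, 5100, noise_cv = 0.05, seed = 6)
  expect_identical(s1, s2)
})
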