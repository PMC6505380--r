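#' Fit a Michaelis-Menten model to an enzyme assay table
#'
#' Nonlinear least squares fit of
#' \deqn{V = \frac{V_{max} [S]}{K_m + [S]}}
#' to substrate-concentration / velocity data, the standard analysis for
#' microsomal probe-substrate kinetics.  Standard errors come from the
#' Gauss-Newton curvature of the objective at the optimum.  By default the
#' fit is unweighted; `weighting = "inv_v"` applies 1/V weights and
#' `"inv_v2"` applies 1/V^2 (relative) weights, the correct variance model
#' when measurement error is proportional to the signal.
#'
#' Default starting values: `vmax` at the largest observed velocity and
#' `km` at the substrate concentration where the velocity first crosses
#' half of that maximum, linearly interpolated.
#'
#' @param assay A data frame with numeric columns `conc_um` (substrate
#'   concentration, uM) and `velocity` (reaction velocity, e.g.
#'   pmol/min per mg protein); an optional `replicate` column is carried
#'   but not used by the fit.  At least 4 distinct substrate
#'   concentrations are required.
#' @param start Optional named list/vector with starting values `km` and
#'   `vmax`.
#' @param weighting `"none"` (default), `"inv_v"` or `"inv_v2"`.
#' @return An object of class `mm_fit`: a list with `km`, `vmax`,
#'   `km_se`, `vmax_se`, `rss`, `n`, `converged`, `weighting`, the
#'   underlying `nls` fit (`fit`) and the data (`assay`).
#'   [tidy()] returns the two-parameter coefficient table; [glance()] the
#'   fit diagnostics.
#' @examples
#' a <- simulate_mm_assay(km = 0.35, vmax = 20.7,
#'                        s_grid = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10))
#' fit_michaelis_menten(a)
#' @export
fit_michaelis_menten <- function(assay, start = NULL,
                                 weighting = c("none", "inv_v", "inv_v2")) {
  weighting <- match.arg(weighting)
  .check_assay(assay)
  s <- assay$conc_um
  v <- assay$velocity
  if (is.null(start)) start <- .mm_start(s, v)
  args <- list(
    velocity ~ vmax * conc_um / (km + conc_um),
    data = data.frame(conc_um = s, velocity = v),
    start = as.list(start),
    lower = c(km = 0, vmax = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (weighting != "none") {
    pw <- if (weighting == "inv_v") 1 else 2
    args$weights <- 1 / pmax(v, .Machine$double.eps)^pw
  }
  fit <- tryCatch(
    do.call(minpack.lm::nlsLM, args),
    error = function(e) {
      abort(paste0("Michaelis-Menten fit failed: ", conditionMessage(e)),
            class = "transddi_fit_error")
    }
  )
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(km = NA_real_, vmax = NA_real_))
  structure(
    list(
      km = est[["km"]], vmax = est[["vmax"]],
      km_se = se[["km"]], vmax_se = se[["vmax"]],
      rss = sum(stats::residuals(fit)^2),  # weighted residuals when weighted
      n = length(v),
      converged = fit$convInfo$isConv,
      weighting = weighting,
      fit = fit,
      assay = tibble::as_tibble(assay)
    ),
    class = "mm_fit"
  )
}

.check_assay <- function(assay) {
  if (!all(c("conc_um", "velocity") %in% names(assay))) {
    abort("assay needs columns conc_um and velocity",
          class = "transddi_format_error")
  }
  if (any(assay$conc_um < 0) || any(assay$velocity < 0)) {
    abort("substrate concentrations and velocities must be >= 0",
          class = "transddi_validation_error")
  }
  if (dplyr::n_distinct(assay$conc_um) < 4) {
    abort("need at least 4 distinct substrate concentrations",
          class = "transddi_domain_error")
  }
}

.mm_start <- function(s, v) {
  vmax0 <- max(v)
  half <- vmax0 / 2
  o <- order(s)
  km0 <- tryCatch(
    stats::approx(v[o], s[o], xout = half, ties = mean)$y,
    error = function(e) NA_real_
  )
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(s[s > 0])
  c(km = km0, vmax = vmax0)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit (", x$n, " points, ",
      if (isTRUE(x$converged)) "converged" else "NOT converged", ")\n", sep = "")
  cat(sprintf("  Km   = %.4g +/- %.3g uM\n", x$km, x$km_se))
  cat(sprintf("  Vmax = %.4g +/- %.3g\n", x$vmax, x$vmax_se))
  cat(sprintf("  RSS  = %.4g\n", x$rss))
  invisible(x)
}

#' @rdname fit_michaelis_menten
#' @param x An `mm_fit` object.
#' @param ... Unused.
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("km", "vmax"),
    estimate = c(x$km, x$vmax),
    std.error = c(x$km_se, x$vmax_se)
  )
}

#' @rdname fit_michaelis_menten
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(
    km = x$km, vmax = x$vmax, rss = x$rss, n = x$n,
    df.residual = x$n - 2L, converged = x$converged
  )
}

#' Extra-sum-of-squares F-test comparing two enzyme preparations
#'
#' Tests whether two assay datasets (for example, humanized-mouse and human
#' liver microsomes probed with the same substrate) are consistent with
#' shared Michaelis-Menten parameters.  The shared model is refit on the
#' pooled data; the F statistic is
#' \deqn{F = \frac{(RSS_{shared} - RSS_{sep}) / \Delta df}{RSS_{sep} / df_{sep}}}
#' with the p-value from the F distribution.  Two comparisons are reported:
#' both parameters shared (`"km_vmax"`, the full preparation comparison,
#' delta df = 2) and Km alone shared with preparation-specific Vmax
#' (`"km_only"`, the affinity comparison, delta df = 1) — Vmax tracks
#' enzyme expression level, so equal affinity with different expression is
#' a meaningful intermediate hypothesis.
#'
#' @param assay_a,assay_b Two assay tables (see [fit_michaelis_menten()]).
#' @param alpha Significance level for the verdict column.
#' @param weighting Weighting scheme applied to every fit entering the
#'   test (see [fit_michaelis_menten()]).  Under proportional measurement
#'   error the unweighted test is anticonservative; `"inv_v2"` restores
#'   nominal calibration.
#' @return A tibble with one row per comparison: `comparison`, `f_stat`,
#'   `df1`, `df2`, `p_value`, `verdict` (`"shared"` or `"separate"`).
#' @export
compare_fits_f_test <- function(assay_a, assay_b, alpha = 0.05,
                                weighting = c("none", "inv_v", "inv_v2")) {
  weighting <- match.arg(weighting)
  fa <- fit_michaelis_menten(assay_a, weighting = weighting)
  fb <- fit_michaelis_menten(assay_b, weighting = weighting)
  rss_sep <- fa$rss + fb$rss
  n <- fa$n + fb$n
  df_sep <- n - 4

  pooled <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(assay_a)[, c("conc_um", "velocity")], prep = "a"),
    dplyr::mutate(tibble::as_tibble(assay_b)[, c("conc_um", "velocity")], prep = "b")
  )

  # fully shared (Km, Vmax)
  shared <- fit_michaelis_menten(pooled, weighting = weighting)
  # shared Km, separate Vmax
  start_kmonly <- list(km = (fa$km + fb$km) / 2, vmax_a = fa$vmax, vmax_b = fb$vmax)
  kmonly_args <- list(
    velocity ~ ifelse(prep == "a", vmax_a, vmax_b) * conc_um / (km + conc_um),
    data = pooled, start = start_kmonly,
    lower = c(km = 0, vmax_a = 0, vmax_b = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (weighting != "none") {
    pw <- if (weighting == "inv_v") 1 else 2
    kmonly_args$weights <- 1 / pmax(pooled$velocity, .Machine$double.eps)^pw
  }
  fit_kmonly <- tryCatch(
    do.call(minpack.lm::nlsLM, kmonly_args),
    error = function(e) abort(paste0("shared-Km fit failed: ",
                                     conditionMessage(e)),
                              class = "transddi_fit_error")
  )
  rss_kmonly <- sum(stats::residuals(fit_kmonly)^2)

  .f_row <- function(comparison, rss_shared, ddf) {
    f_stat <- max(0, (rss_shared - rss_sep) / ddf) / (rss_sep / df_sep)
    p <- pf(f_stat, ddf, df_sep, lower.tail = FALSE)
    tibble::tibble(comparison = comparison, f_stat = f_stat,
                   df1 = ddf, df2 = df_sep, p_value = p,
                   verdict = ifelse(p > alpha, "shared", "separate"))
  }
  dplyr::bind_rows(
    .f_row("km_vmax", shared$rss, 2L),
    .f_row("km_only", rss_kmonly, 1L)
  )
}

#' Residual activity as percent of control
#'
#' `100 * inhibited / control`, the presentation used for
#' single-concentration chemical-inhibition panels.
#'
#' @param activity_inhibited Activity in the presence of inhibitor.
#' @param activity_control Activity without inhibitor, > 0.
#' @return Percent of control activity.
#' @examples
#' percent_of_control(0.06 * 250, 250)  # 6
#' @export
percent_of_control <- function(activity_inhibited, activity_control) {
  if (any(activity_control <= 0)) {
    abort("control activity must be positive", class = "transddi_domain_error")
  }
  100 * activity_inhibited / activity_control
}

#' First-order substrate-depletion kinetics
#'
#' Log-linear regression of remaining substrate against incubation time in
#' a microsomal stability assay: `k_dep` is minus the slope of
#' `ln(C)` vs `t` and the depletion half-life is `ln(2) / k_dep`.  A
#' non-negative slope — as in a no-cofactor control — yields a `"stable"`
#' verdict with no half-life.
#'
#' @param time_min Incubation times, minutes; at least 3.
#' @param conc Remaining substrate concentrations, > 0, same length.
#' @return A tibble with `k_dep_per_min`, `half_life_min`, `stable`
#'   (logical) and `r_squared`.
#' @examples
#' t <- c(0, 5, 10, 20)
#' depletion_half_life(t, 10 * exp(-0.1 * t))
#' @export
depletion_half_life <- function(time_min, conc) {
  if (length(time_min) < 3 || length(conc) != length(time_min)) {
    abort("need >= 3 matched time/concentration points",
          class = "transddi_insufficient_data")
  }
  if (any(conc <= 0)) {
    abort("depletion fitting needs positive concentrations",
          class = "transddi_domain_error")
  }
  fit <- lm(log(conc) ~ time_min)
  slope <- coef(fit)[[2]]
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (slope >= 0) {
    tibble::tibble(k_dep_per_min = NA_real_, half_life_min = NA_real_,
                   stable = TRUE, r_squared = r2)
  } else {
    tibble::tibble(k_dep_per_min = -slope, half_life_min = log(2) / -slope,
                   stable = FALSE, r_squared = r2)
  }
}
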