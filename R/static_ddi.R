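#' Forward static reverse-inhibition model: AUCR from f_m and [I]/Ki
#'
#' The reverse-inhibition component of the combined static drug-drug
#' interaction model.  A victim drug with fraction `f_m` of its clearance
#' through the inhibited enzyme, exposed to an inhibitor at concentration
#' `[I]` with dissociation constant `Ki`, shows the AUC ratio
#' \deqn{AUCR = \frac{1}{(1 - f_m) + \dfrac{f_m}{1 + [I]/K_i}}}
#' AUCR is 1 with no inhibitor or an uninvolved enzyme, and approaches the
#' complete-inhibition ceiling `1 / (1 - f_m)` as `[I]/Ki` grows.
#'
#' @param f_m Fraction of victim clearance via the inhibited enzyme, in
#'   \[0, 1\].
#' @param i_over_ki Dimensionless inhibitor potency `[I]/Ki`, >= 0
#'   (`Inf` allowed: complete inhibition).
#' @return The AUC ratio, >= 1.  `f_m = 1` with infinite `i_over_ki`
#'   returns `Inf`.
#' @examples
#' aucr_forward(0.94, 21)   # 9.73
#' aucr_forward(0.5, Inf)   # 2, the ceiling 1 / (1 - f_m)
#' @export
aucr_forward <- function(f_m, i_over_ki) {
  if (any(f_m < 0 | f_m > 1)) {
    abort("f_m must lie in [0, 1]", class = "transddi_domain_error")
  }
  if (any(i_over_ki < 0)) {
    abort("i_over_ki must be >= 0", class = "transddi_domain_error")
  }
  inhibited <- ifelse(is.infinite(i_over_ki), 0, f_m / (1 + i_over_ki))
  1 / ((1 - f_m) + inhibited)
}

#' Back-solve inhibitor potency [I]/Ki from an observed AUCR
#'
#' Rearrangement of [aucr_forward()]:
#' \deqn{[I]/K_i = \frac{f_m}{1/AUCR - (1 - f_m)} - 1}
#' Only AUC ratios strictly between 1 and the complete-inhibition ceiling
#' `1 / (1 - f_m)` are feasible for a given `f_m`.
#'
#' @param aucr Observed AUC ratio, in `(1, 1 / (1 - f_m))`.
#' @param f_m Fraction metabolized by the inhibited enzyme, in (0, 1\].
#' @return `[I]/Ki`, satisfying
#'   `aucr_forward(f_m, iki_from_aucr(aucr, f_m)) == aucr` to within
#'   1e-10 relative.
#' @examples
#' iki_from_aucr(5.3, 0.85)  # 20.98, reported as 21
#' @export
iki_from_aucr <- function(aucr, f_m) {
  if (any(f_m <= 0 | f_m > 1)) {
    abort("f_m must lie in (0, 1]", class = "transddi_domain_error")
  }
  if (any(aucr <= 1)) {
    abort("AUCR must exceed 1 for an inhibition interaction",
          class = "transddi_no_interaction")
  }
  ceiling_aucr <- 1 / (1 - f_m)
  if (any(aucr >= ceiling_aucr)) {
    abort(paste0("AUCR exceeds the complete-inhibition ceiling 1/(1 - f_m) = ",
                 format(ceiling_aucr, digits = 4), " for f_m = ",
                 format(f_m, digits = 4)),
          class = "transddi_infeasible")
  }
  f_m / (1 / aucr - (1 - f_m)) - 1
}

#' Fraction metabolized from a complete-inhibition (or null-genotype) AUCR
#'
#' In the limit of complete inhibition (`[I]/Ki -> Inf`), or equivalently
#' when comparing extensive against poor metabolizers in whom the enzyme is
#' absent, the static model reduces to `AUCR = 1 / (1 - f_m)`, so
#' \deqn{f_m = 1 - 1/AUCR.}
#'
#' @param aucr AUC ratio under complete loss of the enzyme, >= 1.
#' @return `f_m` in \[0, 1).
#' @examples
#' fm_from_complete_inhibition(8.1)   # 0.877, reported as 0.88
#' fm_from_complete_inhibition(16.3)  # 0.939, reported as 0.94
#' @export
fm_from_complete_inhibition <- function(aucr) {
  if (any(aucr < 1)) {
    abort("AUCR must be >= 1 under pure inhibition",
          class = "transddi_domain_error")
  }
  1 - 1 / aucr
}

#' Translational chain: predict a human AUCR from a calibration interaction
#'
#' Chains the static-model algebra across drugs sharing the same inhibitor
#' and enzyme: back-solve `[I]/Ki` from a clinically observed calibration
#' interaction (`f_m_cal`, `aucr_cal`), then evaluate the forward model for
#' a victim drug with fraction metabolized `victim_f_m`.  The intermediate
#' is carried unrounded by default; `round_intermediate = TRUE` rounds
#' `[I]/Ki` to the nearest integer before the forward step, matching the
#' convention of reported worked examples (21 rather than 20.98).
#'
#' @param f_m_cal,aucr_cal Calibration drug fraction metabolized and
#'   observed AUC ratio (must be feasible for [iki_from_aucr()]).
#' @param victim_f_m Victim drug fraction metabolized, in \[0, 1\].
#' @param round_intermediate Round `[I]/Ki` to the nearest integer before
#'   prediction?
#' @return An object of class `ddi_prediction`: a list with the inputs,
#'   the exact and used `i_over_ki`, and `predicted_aucr`.  [tidy()] gives
#'   a one-row tibble; [glance()] a one-row tibble with paper-style rounded
#'   display values (f_m to 2 decimals, `[I]/Ki` to the nearest integer,
#'   AUCR to 2 decimals).
#' @examples
#' predict_human_aucr(0.85, 5.3, 0.94, round_intermediate = TRUE)
#' @export
predict_human_aucr <- function(f_m_cal, aucr_cal, victim_f_m,
                               round_intermediate = FALSE) {
  if (victim_f_m < 0 || victim_f_m > 1) {
    abort("victim_f_m must lie in [0, 1]", class = "transddi_domain_error")
  }
  iki <- if (aucr_cal == 1) 0 else iki_from_aucr(aucr_cal, f_m_cal)
  iki_used <- if (round_intermediate) round(iki) else iki
  structure(
    list(
      f_m_cal = f_m_cal,
      aucr_cal = aucr_cal,
      victim_f_m = victim_f_m,
      i_over_ki = iki,
      i_over_ki_used = iki_used,
      round_intermediate = round_intermediate,
      predicted_aucr = aucr_forward(victim_f_m, iki_used)
    ),
    class = "ddi_prediction"
  )
}

#' @export
print.ddi_prediction <- function(x, ...) {
  cat("Static reverse-inhibition DDI prediction\n")
  cat(sprintf("  calibration: f_m = %.4g, AUCR = %.4g\n", x$f_m_cal, x$aucr_cal))
  cat(sprintf("  inferred [I]/Ki = %.6g%s\n", x$i_over_ki,
              if (x$round_intermediate)
                sprintf(" (used rounded: %g)", x$i_over_ki_used) else ""))
  cat(sprintf("  victim f_m = %.4g -> predicted AUCR = %.4g\n",
              x$victim_f_m, x$predicted_aucr))
  invisible(x)
}

#' @rdname predict_human_aucr
#' @param x A `ddi_prediction` object.
#' @param ... Unused.
#' @method tidy ddi_prediction
#' @export
tidy.ddi_prediction <- function(x, ...) {
  tibble::tibble(
    f_m_cal = x$f_m_cal,
    aucr_cal = x$aucr_cal,
    victim_f_m = x$victim_f_m,
    i_over_ki = x$i_over_ki,
    i_over_ki_used = x$i_over_ki_used,
    predicted_aucr = x$predicted_aucr
  )
}

#' @rdname predict_human_aucr
#' @method glance ddi_prediction
#' @export
glance.ddi_prediction <- function(x, ...) {
  tibble::tibble(
    victim_f_m_display = round(x$victim_f_m, 2),
    i_over_ki_display = round(x$i_over_ki),
    predicted_aucr_display = round(x$predicted_aucr, 2)
  )
}
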