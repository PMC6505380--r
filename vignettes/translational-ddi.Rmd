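---
title: "Translational pharmacokinetics and static DDI prediction with transddi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translational pharmacokinetics and static DDI prediction with transddi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transddi)
library(dplyr)
```

## The scientific problem

Humanized-mouse models carrying human cytochrome P450 enzymes make it
possible to study drug–drug interactions (DDIs) in vivo before a clinical
study exists. Translating such animal observations into a quantitative
human prediction requires four connected analyses, and `transddi`
implements all of them over plain tabular data:

1. **Noncompartmental analysis (NCA)** of sparse blood concentration–time
   profiles, giving exposure metrics (Cmax, AUC, terminal half-life,
   apparent oral clearance CL/F).
2. **The static reverse-inhibition DDI model**, the algebra linking a
   victim drug's AUC ratio to the fraction of its clearance through the
   inhibited enzyme ($f_m$) and the inhibitor's potency ($[I]/K_i$).
3. **Body-surface-area dose translation**, converting an animal mg/kg dose
   into its human equivalent.
4. **In vitro enzyme kinetics**: Michaelis–Menten fits with
   extra-sum-of-squares model comparison, percent-of-control inhibition
   and substrate-depletion half-lives.

A seeded synthetic-data module generates every input the pipeline
consumes — sparse oral cohorts and noisy assay tables — with known ground
truth, so each stage's recovery performance is testable.

## The static reverse-inhibition model

For a victim drug with fraction $f_m$ of its oral clearance through one
enzyme, reversible inhibition at relative inhibitor exposure $x = [I]/K_i$
changes exposure by

$$\mathrm{AUCR} \;=\; \frac{1}{(1 - f_m) + \dfrac{f_m}{1 + x}},$$

which is 1 with no inhibitor and saturates at the *complete-inhibition
ceiling* $1/(1-f_m)$ as $x \to \infty$. Two rearrangements close the
algebra:

* **Potency from an observed interaction**
  ($x = f_m / (1/\mathrm{AUCR} - (1-f_m)) - 1$), feasible only for
  $1 < \mathrm{AUCR} < 1/(1-f_m)$; `iki_from_aucr()` raises an
  infeasibility error outside that band rather than returning a negative
  potency.
* **Fraction metabolized at the ceiling** ($f_m = 1 - 1/\mathrm{AUCR}$),
  appropriate when the enzyme is fully inhibited or genetically absent
  (extensive- vs poor-metabolizer comparisons); `fm_from_complete_inhibition()`.

`predict_human_aucr()` chains them: calibrate $[I]/K_i$ on a drug whose
clinical interaction with the same inhibitor is known, then run the
forward model for the victim drug:

```{r}
pred <- predict_human_aucr(f_m_cal = 0.85, aucr_cal = 5.3,
                           victim_f_m = 0.94, round_intermediate = TRUE)
tidy(pred)
```

All computation is unrounded internally. `round_intermediate = TRUE`
rounds the inferred $[I]/K_i$ to the nearest integer before the forward
step, matching how such worked chains are usually quoted; with this
calibration the rounded and unrounded paths agree to two decimals
(`r round(predict_human_aucr(0.85, 5.3, 0.94)$predicted_aucr, 4)` vs
`r round(pred$predicted_aucr, 4)`).

## Noncompartmental analysis

`nca()` takes a validated profile table (`pk_profiles()`) and returns one
row per (subject, analyte). Numerical choices, each the common NCA
convention where the field's commercial tools leave the choice open:

* **Linear trapezoid** for AUC up to the last quantifiable sample
  (lin-log integration is not offered; the package's downstream ratios
  divide trapezoid AUCs, so the shared discretization largely cancels).
* **Terminal slope** $\lambda_z$: ordinary least squares of
  $\ln C$ vs $t$ over every candidate window of the last $k \ge 3$ points
  strictly after Tmax; the window maximizing adjusted $R^2$ wins, ties to
  more points. A profile with no negatively-sloped window reports the
  terminal phase as undefined; AUC_all is still returned.
* **BLQ policy**: below-quantification samples before the first
  quantifiable one count as concentration zero; later ones are dropped
  from both AUC and the terminal fit.
* **Cmax ties** go to the earliest time.
* **AUC ratios between arms** (`group_aucr()`) divide arithmetic group
  means.

CL/F is dose divided by AUC$_\infty$ with the units resolved to
ml/h per kg regardless of whether concentrations arrived in ng/ml or
ug/ml (the two units the bioanalytical tables use; conversion is the
exact factor 1000).

## Dose translation between species

`human_equivalent_dose()` uses the standard body-surface-area
normalisation constants (the "Km factor": body weight over surface area;
mouse 3, adult human 37 at 70 kg reference weight — `km_factor_table()`
carries the usual laboratory species). `total_human_dose()` multiplies by
body weight and rounds, by default to the nearest 10 mg, the granularity
at which such equivalences are quoted; the unrounded value is always
reported alongside. These constants and that rounding are the unique
combination reproducing both quoted mouse equivalences (30 mg/kg → 170 mg
and 35 mg/kg → 200 mg per 70 kg) from a single table.

```{r}
total_human_dose(c(30, 35), "mouse")
```

## Enzyme kinetics

`fit_michaelis_menten()` fits $V = V_{max}[S]/(K_m+[S])$ by
Levenberg–Marquardt least squares, with standard errors from the
Gauss–Newton curvature at the optimum. Default starts are
$V_{max}^0 = \max V$ and $K_m^0$ interpolated at half of it, which is
reliable on any design spanning the Km. The default is unweighted,
matching the typical default of the commercial fitters this replaces;
`weighting = "inv_v"` and `"inv_v2"` (relative weighting) are available.

`compare_fits_f_test()` asks whether two preparations share kinetic
parameters via the extra-sum-of-squares F-test. Because it is ambiguous
whether such comparisons concern affinity alone or the full parameter
pair, both are reported: a shared-(Km, Vmax) test (Δdf = 2) and a
shared-Km / free-Vmax test (Δdf = 1). Vmax tracks expression level, so
equal affinity with different expression is a meaningful intermediate
outcome.

**Calibration caveat.** With measurement error proportional to the signal
— the realistic model for bioanalytical velocities, and the one the
simulator uses — the *unweighted* F-test is mildly anticonservative,
because velocities near Vmax carry most of the variance. Matching the
variance model with `weighting = "inv_v2"` restores the nominal type-I
error (verified by simulation in the test suite at 1000 replicates).
Under homoscedastic noise the unweighted test is exactly calibrated. Use
relative weighting whenever the assay's error is proportional.

`percent_of_control()` and `depletion_half_life()` cover the two simpler
in vitro stages: single-concentration inhibition panels, and
microsomal-stability incubations where a non-negative log-slope is
reported as "stable" (mirroring a no-cofactor control) rather than as a
meaningless negative rate.

## What the simulator emulates — and what it does not

`simulate_profile()` draws from a one-compartment first-order
absorption/elimination model,

$$C(t) = 1000\,D\,\frac{F}{V}\,\frac{k_a}{k_a-k_e}
  \left(e^{-k_e t} - e^{-k_a t}\right),$$

with multiplicative lognormal noise (unit mean, chosen CV) so simulated
concentrations stay positive; the $k_a = k_e$ limit is handled
analytically and flip-flop kinetics are allowed. Defaults emulate a
sparse oral rodent study: dose 10 mg/kg, $k_a = 3\,h^{-1}$,
$k_e = 0.4\,h^{-1}$ (half-life 1.7 h), $F/V = 0.003$ (ml/kg)$^{-1}$ —
giving Cmax near 20 ug/ml and CL/F near 130 ml/h per kg, the scale of the
oral probe-drug studies this package targets — sampled at 8 points from
0.25 to 24 h.

`simulate_ddi_cohorts()` adds lognormal between-subject variability on
$k_e$ and $F/V$ and scales the treated arm's elimination mechanistically:
by $(1-f_m) + f_m/(1+[I]/K_i)$ under inhibition — so the true AUC ratio
equals `aucr_forward()` exactly — or by $(1-f_m) + f_m \cdot \text{fold}$
under induction. A single integer seed drives all subjects in a fixed
order, so cohorts are bit-reproducible.

The simulator deliberately omits: multi-compartment disposition,
enterohepatic recirculation, gut-wall first-pass, time-varying inhibitor
exposure (the static model's constant-$[I]$ assumption is built in), and
below-limit-of-quantification censoring. Passing recovery tests therefore
demonstrates that the analysis chain is unbiased *under the one-compartment
static-exposure model with lognormal variability* — not that it is robust
to model misspecification in real animal data.

## Performance contracts checked by the test suite

Problem sizes were chosen as the smallest designs at which the Monte
Carlo error of a median is comfortably below each tolerance:

* Static-model round-trips (potency ↔ AUCR, $f_m$ ↔ ceiling AUCR) hold to
  1e-10 relative tolerance over 1000 random draws.
* On noiseless one-compartment profiles, NCA recovers $k_e$ within 2% and
  AUC$_\infty$ / CL/F within 5%.
* End-to-end (simulate → NCA → AUCR → invert): with 8 subjects per arm
  and 10% between-subject CV, the median over 200 seeded replicates
  recovers $f_m$ within 0.02 (complete-inhibition arms) and $[I]/K_i$
  within 15% (moderate-potency arms). The residual bias is trapezoid
  discretization on the sparse 8-point grid, shared by real sparse
  designs.
* Michaelis–Menten medians are within 5% of truth at 5% CV over 500
  replicates; the F-test's type-I error is within 2 binomial SE of 5%
  over 1000 replicates under a matched variance model.

## Known limitations

* AUC to the last observation is reported in the WinNonlin sense of
  "AUC_all" over observed samples; partial and urinary AUC metrics are
  out of scope.
* The static DDI model covers reversible inhibition of a single enzyme
  only; mechanism-based inactivation, induction terms and gut extraction
  are not modeled (the simulator's induction arm scales clearance
  directly, which is the corresponding static assumption).
* Dose translation implements surface-area normalisation only, not
  exponent-based allometric clearance scaling, and the Km table is the
  adult table — no pediatric scaling.
* `iki_from_aucr()` propagates no uncertainty; confidence intervals on
  the chain would require the arm-level AUC variances, which the
  tabulated inputs it is designed for do not always provide.
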