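Package: transddi
Title: Translational Pharmacokinetics and Static Drug-Drug Interaction
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Noncompartmental analysis of sparse oral concentration-time
    profiles (Cmax, AUC, terminal half-life, apparent oral clearance),
    the static reverse-inhibition drug-drug interaction model linking
    AUC ratios, fraction metabolized and inhibitor potency, body-surface-area
    dose translation between species, Michaelis-Menten microsomal kinetics
    with extra-sum-of-squares model comparison, and seeded simulators for
    one-compartment oral cohorts and enzyme assay data with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
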