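#' Body-surface-area (Km-factor) table
#'
#' The standard surface-area normalisation constants (body weight divided
#' by surface area) used for interspecies dose translation, with the usual
#' reference body weights.  Mouse 3, rat 6, adult human 37 (70 kg) are the
#' entries the package's dose equivalences rely on; the remaining common
#' laboratory species are included for completeness.
#'
#' @return A tibble with columns `species`, `km_factor`,
#'   `reference_body_weight_kg`.
#' @export
km_factor_table <- function() {
  tibble::tribble(
    ~species,      ~km_factor, ~reference_body_weight_kg,
    "mouse",        3,          0.02,
    "hamster",      5,          0.08,
    "rat",          6,          0.15,
    "guinea pig",   8,          0.4,
    "rabbit",      12,          1.8,
    "monkey",      12,          3,
    "dog",         20,          10,
    "human",       37,         70
  )
}

.km_factor <- function(species) {
  tab <- km_factor_table()
  i <- match(species, tab$species)
  if (any(is.na(i))) {
    abort(paste0("Unknown species: ",
                 paste(unique(species[is.na(i)]), collapse = ", "),
                 " (see km_factor_table())"),
          class = "transddi_lookup_error")
  }
  tab$km_factor[i]
}

#' Human equivalent dose by body-surface-area normalisation
#'
#' Converts an animal mg/kg dose to the human mg/kg dose giving the same
#' dose per unit body surface area:
#' `HED = dose * Km_animal / Km_human`.
#'
#' @param dose_mg_per_kg Animal dose, mg/kg, > 0.
#' @param species Animal species, a row of [km_factor_table()].
#' @return Human equivalent dose, mg/kg.
#' @examples
#' human_equivalent_dose(30, "mouse")  # 2.43 mg/kg
#' @export
human_equivalent_dose <- function(dose_mg_per_kg, species) {
  if (any(dose_mg_per_kg <= 0)) {
    abort("dose must be positive", class = "transddi_domain_error")
  }
  dose_mg_per_kg * .km_factor(species) / .km_factor("human")
}

#' Total human dose equivalent to an animal mg/kg dose
#'
#' Human equivalent dose times a reference body weight, with the rounding
#' convention used when such equivalences are quoted (nearest 10 mg by
#' default).  The unrounded value is always reported alongside.
#'
#' @inheritParams human_equivalent_dose
#' @param body_weight_kg Human body weight, kg (default 70).
#' @param round_to_mg Round the total dose to the nearest multiple of this
#'   many mg; `NULL` for no rounding.
#' @return A tibble with `species`, `animal_dose_mg_per_kg`,
#'   `hed_mg_per_kg`, `total_mg_unrounded`, `total_mg`.
#' @examples
#' total_human_dose(35, "mouse")  # 198.6 -> 200 mg / 70 kg
#' total_human_dose(30, "mouse")  # 170.3 -> 170 mg / 70 kg
#' @export
total_human_dose <- function(dose_mg_per_kg, species, body_weight_kg = 70,
                             round_to_mg = 10) {
  if (any(body_weight_kg <= 0)) {
    abort("body weight must be positive", class = "transddi_domain_error")
  }
  hed <- human_equivalent_dose(dose_mg_per_kg, species)
  total <- hed * body_weight_kg
  tibble::tibble(
    species = species,
    animal_dose_mg_per_kg = dose_mg_per_kg,
    hed_mg_per_kg = hed,
    total_mg_unrounded = total,
    total_mg = if (is.null(round_to_mg)) total
               else round(total / round_to_mg) * round_to_mg
  )
}
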