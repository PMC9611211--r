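#' Published reference values from the constructed-wetland microcosm study
#'
#' Small tables of printed results from the algae--bacteria constructed-wetland
#' antibiotic-wastewater microcosm experiment the package models: the
#' varimax-rotated factor loading matrix of the six pollutant-removal
#' indicators, the total-variance (eigenvalue) table, the final published
#' indicator weights, the printed final removal rates used to calibrate the
#' synthetic removal generator, and the influent concentrations of the
#' synthetic wastewater.
#'
#' These are inputs, not results computed by this package: they let the
#' weighting chain be rerun exactly as published and give the simulator
#' realistic endpoints. `reference_rotated_loadings()` returns a 6 x 2 matrix
#' (rows: COD, TP, TN, NO3-N, NH4-N, CED removal-rate indicators; columns:
#' rotated factors 1 and 2).
#'
#' @return A matrix (`reference_rotated_loadings`) or tibble (all others).
#' @examples
#' factor_weights(reference_rotated_loadings())
#' @name reference_values
NULL

cw_indicators <- function() c("COD", "TP", "TN", "NO3-N", "NH4-N", "CED")

cw_systems <- function() c("S", "SG", "A", "AG", "AS", "ASG")

#' @rdname reference_values
#' @export
reference_rotated_loadings <- function() {
  m <- matrix(
    c(0.880, 0.350,
      0.309, 0.795,
      0.591, 0.744,
      0.948, 0.126,
      0.017, 0.949,
      0.919, 0.125),
    ncol = 2, byrow = TRUE,
    dimnames = list(cw_indicators(), c("factor1", "factor2"))
  )
  m
}

#' @rdname reference_values
#' @export
reference_variance_table <- function() {
  tibble(
    component = 1:6,
    eigenvalue = c(3.865, 1.336, 0.408, 0.231, 0.135, 0.026),
    variance_pct = c(64.409, 22.264, 6.793, 3.854, 2.249, 0.432),
    cumulative_pct = c(64.409, 86.673, 93.466, 97.320, 99.568, 100.000)
  )
}

#' @rdname reference_values
#' @export
reference_indicator_weights <- function() {
  tibble(
    indicator = cw_indicators(),
    weight = c(0.1856, 0.1588, 0.1955, 0.1649, 0.1349, 0.1603)
  )
}

#' @rdname reference_values
#' @export
reference_final_removals <- function() {
  tibble::tribble(
    ~system, ~pollutant, ~removal,
    "S",   "TP",    0.6336,
    "SG",  "TP",    0.6384,
    "AS",  "TP",    0.6414,
    "ASG", "TP",    0.6595,
    "ASG", "TN",    0.9079,
    "AS",  "TN",    0.8894,
    "SG",  "TN",    0.8880,
    "AG",  "TN",    0.8053,
    "S",   "TN",    0.7763,
    "A",   "TN",    0.7121,
    "A",   "NH4-N", 0.3680,
    "S",   "CED",   0.7569,
    "SG",  "CED",   0.7955,
    "A",   "CED",   0.9876,
    "AG",  "CED",   0.9884,
    "AS",  "CED",   0.9075,
    "ASG", "CED",   0.9240
  )
}

#' @rdname reference_values
#' @export
reference_influent <- function() {
  tibble(
    pollutant = c("COD", "TP", "NO3-N", "NH4-N", "CED"),
    influent_mg_per_L = c(232, 4.76, 23.26, 23.26, 35)
  )
}
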