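#' Chlorella OD680-to-biomass calibration
#'
#' The default linear wet-weight calibration
#' `biomass (mg/L) = 4021.9 * OD680 - 8.6817` (fit r^2 = 0.9995, taken as
#' given). Override the coefficients for other strains or instruments.
#'
#' @param slope mg/L per OD unit (> 0).
#' @param intercept mg/L.
#' @param fit_r2 Metadata only.
#' @return A list of class `cw_biomass_calibration`.
#' @export
biomass_calibration <- function(slope = 4021.9, intercept = -8.6817,
                                fit_r2 = 0.9995) {
  if (slope <= 0) cw_abort("slope must be > 0", "cwevalkit_domain_error")
  structure(list(slope = slope, intercept = intercept, fit_r2 = fit_r2),
            class = "cw_biomass_calibration")
}

#' Convert OD680 to biomass
#'
#' Affine conversion `slope * od + intercept`. Predictions below zero (the
#' negative intercept is a fit artifact, not extrapolable) are clipped to 0
#' with a warning.
#'
#' @param od OD680 value(s), >= 0.
#' @param cal A [biomass_calibration()].
#' @return Biomass in mg/L.
#' @export
od_to_biomass <- function(od, cal = biomass_calibration()) {
  stopifnot(inherits(cal, "cw_biomass_calibration"))
  if (any(od < 0)) cw_abort("od must be >= 0", "cwevalkit_domain_error")
  b <- cal$slope * od + cal$intercept
  if (any(b < 0)) {
    warn(sprintf(
      "%d value(s) below the calibration range; biomass clipped to 0",
      sum(b < 0)))
    b <- pmax(b, 0)
  }
  b
}

#' Convert an OD series to a biomass series
#'
#' @param x An OD series (`system`, `day`, `replicate`, `od680`).
#' @param cal A [biomass_calibration()].
#' @return A tibble `system`, `day`, `replicate`, `biomass_mg_per_L`.
#' @export
biomass_series <- function(x, cal = biomass_calibration()) {
  x <- validate_od_series(x)
  dplyr::transmute(
    x, .data$system, .data$day, .data$replicate,
    biomass_mg_per_L = od_to_biomass(.data$od680, cal)
  )
}

#' Final-day biomass comparison with significance letters
#'
#' One-way ANOVA + Tukey HSD compact-letter display of biomass across
#' systems on a chosen day (default the last). Systems sharing a letter do
#' not differ at `alpha`. Requires >= 2 replicates per system.
#'
#' @param x A biomass series from [biomass_series()].
#' @param day Day to compare (default max).
#' @param alpha Significance level.
#' @return A tibble `system`, `mean_biomass`, `letter` (the letter column is
#'   absent without replication).
#' @export
growth_letters <- function(x, day = max(x$day), alpha = 0.05) {
  cw_assert_cols(x, c("system", "day", "replicate", "biomass_mg_per_L"),
                 "biomass series")
  d <- dplyr::filter(x, .data$day == !!day)
  out <- d |>
    dplyr::group_by(.data$system) |>
    dplyr::summarise(mean_biomass = mean(.data$biomass_mg_per_L),
                     .groups = "drop")
  lt <- tukey_letters(d$biomass_mg_per_L, d$system, alpha)
  if (!is.null(lt)) out$letter <- lt[out$system]
  out
}
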