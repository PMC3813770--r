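# Centralized unit conversions.  Internal bookkeeping convention:
#   - aqueous DOC as concentration, g C mL^-1 of pore water,
#   - sorbed PDOC as g C per g bulk soil,
#   - SOC and MBC as areal densities, g C cm^-2 per layer,
#   - audits and reported totals in g C m^-2 (1 cm^-2 = 1e4 m^-2),
#   - all rates per hour.

#' @rdname units
#' @name units
NULL

#' Unit helpers
#'
#' `per_day_to_per_hour()` converts first-order rate coefficients;
#' `g_m2_to_g_cm2()` / `g_cm2_to_g_m2()` convert areal carbon densities.
#'
#' @param x Numeric.
#' @return Numeric of the same shape.
#' @export
per_day_to_per_hour <- function(x) x / 24

#' @rdname per_day_to_per_hour
#' @export
g_m2_to_g_cm2 <- function(x) x / 1e4

#' @rdname per_day_to_per_hour
#' @export
g_cm2_to_g_m2 <- function(x) x * 1e4

#' Hours in the simulated growing season (May 1 - September 30)
#' @export
SEASON_HOURS <- 153L * 24L
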