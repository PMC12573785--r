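#' Atmospheric pathway of an emitted gas down to oceanic dissolution
#'
#' A substance pathway describes what fraction of an emitted greenhouse gas
#' (CO2, CO or CH4) ends up dissolved in the surface ocean as CO2. CO and CH4
#' first convert to CO2 in the troposphere; the dissolved fraction is further
#' reduced by the small share of carbon buried in sediment. The product of
#' these fractions is the dissolution factor \eqn{DF_i} used throughout the
#' fate model.
#'
#' @param substance_id character, e.g. `"CO2"`.
#' @param f_troposphere fraction in \[0, 1\] of the emission reaching the
#'   troposphere as (or converting to) the CO-stage gas.
#' @param f_conversion fraction in \[0, 1\] converting onward to CO2
#'   (1 for CO2 and CO; 0.95 for CH4).
#' @param f_dissolution fraction in \[0, 1\] of atmospheric CO2 dissolving in
#'   the ocean (default pathway value 0.275).
#' @param f_burial fraction in \[0, 1\] of the dissolved carbon buried in
#'   sediment (default pathway value 0.00225).
#' @param molar_mass_co2 molar mass of CO2 in kg/mol. Only the CO2 molar mass
#'   is used, because all three gases reach the ocean as CO2.
#'
#' @return An object of class `"oa_pathway"`.
#' @seealso [dissolution_factor()], [default_pathways()]
#' @export
substance_pathway <- function(substance_id,
                              f_troposphere,
                              f_conversion,
                              f_dissolution,
                              f_burial,
                              molar_mass_co2 = 4.4e-2) {
  stopifnot(is.character(substance_id), length(substance_id) == 1L)
  fracs <- c(f_troposphere = f_troposphere, f_conversion = f_conversion,
             f_dissolution = f_dissolution, f_burial = f_burial)
  for (nm in names(fracs)) {
    v <- fracs[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("pathway fraction '%s' must be a single value in [0, 1], got %s",
                   nm, format(v)), call. = FALSE)
    }
  }
  if (!is.numeric(molar_mass_co2) || molar_mass_co2 <= 0) {
    stop("'molar_mass_co2' must be a positive number (kg/mol)", call. = FALSE)
  }
  structure(
    list(substance_id = substance_id,
         f_troposphere = f_troposphere,
         f_conversion = f_conversion,
         f_dissolution = f_dissolution,
         f_burial = f_burial,
         molar_mass_co2 = molar_mass_co2),
    class = "oa_pathway"
  )
}

#' @export
print.oa_pathway <- function(x, ...) {
  cat(sprintf("Substance pathway: %s\n", x$substance_id))
  cat(sprintf("  troposphere %.4g x conversion %.4g x dissolution %.4g x (1 - burial %.4g)\n",
              x$f_troposphere, x$f_conversion, x$f_dissolution, x$f_burial))
  cat(sprintf("  dissolution factor DF = %.4f\n", dissolution_factor(x)))
  invisible(x)
}

#' Dissolution factor of a substance pathway
#'
#' The fraction of a unit emission that ultimately dissolves in the ocean as
#' CO2:
#' \deqn{DF = f_{tropo} \times f_{conv} \times f_{diss} \times (1 - f_{burial})}
#' Burial is treated as a sub-fraction of the dissolved pool. The value is
#' returned unrounded; the conventionally quoted two-decimal figures for the
#' default pathways are 0.27 (CO2), 0.24 (CO) and 0.23 (CH4).
#'
#' @param pathway an [substance_pathway()] object.
#' @return The dissolution factor, a single number in \[0, 1\].
#' @export
dissolution_factor <- function(pathway) {
  stopifnot(inherits(pathway, "oa_pathway"))
  pathway$f_troposphere * pathway$f_conversion *
    pathway$f_dissolution * (1 - pathway$f_burial)
}

#' Default substance pathway registry
#'
#' The three gases the model characterizes, with their atmospheric pathway
#' fractions: 27.5\% of atmospheric CO2 dissolves in the ocean and 0.225\% of
#' the dissolved carbon is buried; 87.1\% of emitted CO reaches the
#' troposphere and converts fully to CO2; 87.8\% of emitted CH4 reaches the
#' troposphere, of which 95\% reacts through to CO2.
#'
#' @return A named list of [substance_pathway()] objects (`CO2`, `CO`, `CH4`).
#' @export
default_pathways <- function() {
  list(
    CO2 = substance_pathway("CO2", 1.0,   1.0,  0.275, 0.00225),
    CO  = substance_pathway("CO",  0.871, 1.0,  0.275, 0.00225),
    CH4 = substance_pathway("CH4", 0.878, 0.95, 0.275, 0.00225)
  )
}
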