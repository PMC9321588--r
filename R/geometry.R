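#' Stirred-tank geometry
#'
#' Describes a flat-bottomed cylindrical stirred fermentor with one or more
#' Rushton impellers on a central shaft. The default values describe a
#' 54 m^3 industrial penicillin fermentor: tank diameter 3 m, liquid-filled
#' height 7.7 m, two Rushton impellers of diameter 1.3 m (bottom clearance
#' 1.3 m, mutual spacing 3 m), stirred at 98 RPM, with a Newtonian broth of
#' density 1000 kg/m^3.
#'
#' @param diameter Tank diameter T (m).
#' @param liquid_height Liquid-filled height Hl (m).
#' @param impeller_diameter Impeller diameter D (m).
#' @param clearance Off-bottom clearance of the lowest impeller C (m).
#' @param impeller_spacing Mutual axial spacing between impellers (m); with
#'   `n_impellers = 1` it is ignored.
#' @param n_impellers Number of impellers on the shaft.
#' @param stir_rpm Stirrer speed N (revolutions per minute).
#' @param density Broth density rho_l (kg/m^3); the broth is treated as a
#'   single-phase Newtonian liquid.
#'
#' @return A `tank_geometry` object (a named list) with the fields above plus
#'   the derived liquid volume `volume` (m^3), impeller plane heights
#'   `impeller_heights` (m) and tip speed `tip_speed` (m/s).
#' @examples
#' geo <- tank_geometry()
#' geo$volume # pi * 1.5^2 * 7.7 = 54.4 m^3
#' @export
tank_geometry <- function(diameter = 3, liquid_height = 7.7,
                          impeller_diameter = 1.3, clearance = 1.3,
                          impeller_spacing = 3, n_impellers = 2,
                          stir_rpm = 98, density = 1000) {
  check_positive(diameter, "diameter")
  check_positive(liquid_height, "liquid_height")
  check_positive(impeller_diameter, "impeller_diameter")
  check_positive(clearance, "clearance")
  check_positive(stir_rpm, "stir_rpm")
  check_positive(density, "density")
  n_impellers <- check_count(n_impellers, "n_impellers")
  heights <- clearance + impeller_spacing * (seq_len(n_impellers) - 1L)
  if (max(heights) >= liquid_height) {
    abort_lagcm("impeller planes must lie below the liquid surface",
                class = "lagcm_validation_error")
  }
  structure(
    list(
      diameter = diameter,
      liquid_height = liquid_height,
      volume = pi * (diameter / 2)^2 * liquid_height,
      impeller_diameter = impeller_diameter,
      clearance = clearance,
      impeller_spacing = impeller_spacing,
      n_impellers = n_impellers,
      impeller_heights = heights,
      stir_rpm = stir_rpm,
      tip_speed = pi * impeller_diameter * stir_rpm / 60,
      density = density
    ),
    class = "tank_geometry"
  )
}

#' @export
print.tank_geometry <- function(x, ...) {
  cat(sprintf(
    "<tank_geometry> T = %.2f m, Hl = %.2f m, V = %.1f m^3, %d impeller(s), %.0f RPM\n",
    x$diameter, x$liquid_height, x$volume, x$n_impellers, x$stir_rpm))
  invisible(x)
}
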