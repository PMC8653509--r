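#' Physical constants for osmotic calculations
#'
#' Bundles the constants entering the osmotic pressure / osmolality
#' relations: the gas constant, temperature, the NaCl osmotic coefficient,
#' the bath (equilibration solution) NaCl concentration, the tissue mass
#' density used to convert wet weights to radii, and the viscosity of
#' 0.15 mol/L NaCl (only needed to convert an intrinsic permeability in
#' m^2 to hydraulic form).
#'
#' The osmotic coefficient 0.93 is applied to both tissue and bath ion
#' concentrations, treating sodium bound to proteoglycans like sodium
#' paired with chloride.
#'
#' @param gas_constant Universal gas constant, J/(mol K).
#' @param temperature Absolute temperature, K (room temperature default).
#' @param osmotic_coefficient Dimensionless NaCl osmotic coefficient in (0, 1].
#' @param bath_concentration External NaCl concentration, mol/L.
#' @param tissue_density Tissue mass density, kg/m^3.
#' @param viscosity Dynamic viscosity of 0.15 mol/L NaCl at `temperature`,
#'   Pa s.
#' @return An object of class `"physical_constants"` (a validated list).
#' @examples
#' ct <- physical_constants()
#' bath_osmolality(ct)  # 279 mOsm/kg H2O for 0.15 mol/L NaCl at phi = 0.93
#' @export
physical_constants <- function(gas_constant = 8.314,
                               temperature = 298.15,
                               osmotic_coefficient = 0.93,
                               bath_concentration = 0.15,
                               tissue_density = 1000,
                               viscosity = 8.9e-4) {
  x <- list(gas_constant = gas_constant, temperature = temperature,
            osmotic_coefficient = osmotic_coefficient,
            bath_concentration = bath_concentration,
            tissue_density = tissue_density, viscosity = viscosity)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("physical_constants: '", nm, "' must be a single positive number")
  }
  if (osmotic_coefficient > 1)
    stop("physical_constants: 'osmotic_coefficient' must lie in (0, 1]")
  structure(x, class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants:\n")
  cat(sprintf("  R      = %g J/(mol K)\n", x$gas_constant))
  cat(sprintf("  T      = %g K\n", x$temperature))
  cat(sprintf("  phi    = %g\n", x$osmotic_coefficient))
  cat(sprintf("  c_ext  = %g mol/L NaCl\n", x$bath_concentration))
  cat(sprintf("  rho    = %g kg/m^3\n", x$tissue_density))
  cat(sprintf("  mu     = %g Pa s\n", x$viscosity))
  invisible(x)
}

#' Bath osmotic pressure and osmolality
#'
#' The osmotic pressure of the external 0.15 mol/L NaCl bath is
#' `2 phi c_ext R T` (two ions per formula unit); its osmolality is
#' `2 phi c_ext` expressed in mOsm/kg H2O, identifying mol/m^3 with
#' mmol/L and mOsm/kg for dilute aqueous solutions.
#'
#' @param constants A [physical_constants()] object.
#' @return Pressure in Pa (`bath_osmotic_pressure`) or osmolality in
#'   mOsm/kg H2O (`bath_osmolality`).
#' @export
bath_osmotic_pressure <- function(constants = physical_constants()) {
  2 * constants$osmotic_coefficient * (constants$bath_concentration * 1000) *
    constants$gas_constant * constants$temperature
}

#' @rdname bath_osmotic_pressure
#' @export
bath_osmolality <- function(constants = physical_constants()) {
  2 * constants$osmotic_coefficient * constants$bath_concentration * 1000
}

#' Microdialysis probe and tubing geometry
#'
#' Fixed instrument constants: the membrane inner and outer radii, the
#' membrane length exposed to tissue, and the bore of the tubing along
#' which the water/air meniscus is tracked. Defaults are the probe used
#' for nucleus pulposus work: r1 = 0.113 mm (microscope), r2 = 0.12 mm
#' (manufacturer), L = 5 mm, tubing internal diameter 0.38 mm.
#'
#' @param inner_membrane_radius r1, m.
#' @param outer_membrane_radius r2, m; must exceed r1.
#' @param membrane_length L, m.
#' @param tubing_inner_diameter Tubing bore, m.
#' @return An object of class `"probe_geometry"`.
#' @export
probe_geometry <- function(inner_membrane_radius = 0.113e-3,
                           outer_membrane_radius = 0.12e-3,
                           membrane_length = 5e-3,
                           tubing_inner_diameter = 0.38e-3) {
  if (!is.numeric(inner_membrane_radius) || inner_membrane_radius <= 0)
    stop("probe_geometry: inner_membrane_radius must be positive")
  if (outer_membrane_radius <= inner_membrane_radius)
    stop("probe_geometry: need 0 < r1 < r2")
  if (membrane_length <= 0) stop("probe_geometry: membrane_length must be positive")
  if (tubing_inner_diameter <= 0)
    stop("probe_geometry: tubing_inner_diameter must be positive")
  structure(list(inner_membrane_radius = inner_membrane_radius,
                 outer_membrane_radius = outer_membrane_radius,
                 membrane_length = membrane_length,
                 tubing_inner_diameter = tubing_inner_diameter),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat("Probe geometry:\n")
  cat(sprintf("  r1 (inner membrane) = %g mm\n", x$inner_membrane_radius * 1e3))
  cat(sprintf("  r2 (outer membrane) = %g mm\n", x$outer_membrane_radius * 1e3))
  cat(sprintf("  L  (membrane)       = %g mm\n", x$membrane_length * 1e3))
  cat(sprintf("  tubing ID           = %g mm\n", x$tubing_inner_diameter * 1e3))
  invisible(x)
}

#' Cross-sectional area of the meniscus tubing
#' @param geometry A [probe_geometry()] object.
#' @return Area in m^2.
#' @export
tubing_area <- function(geometry = probe_geometry()) {
  pi * (geometry$tubing_inner_diameter / 2)^2
}

#' Round half away from zero
#'
#' The rounding convention used for published-table comparisons
#' (concentrations to 2 decimals, osmolalities to integers); base
#' [round()] is round-half-even and would turn 0.305 into 0.30.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
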