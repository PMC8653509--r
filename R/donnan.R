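#' Tissue hydration on a total tissue water basis
#'
#' Grams of water per gram of dry tissue, `(wet - dry)/dry`, using the
#' post-flux wet weight and the lyophilized dry weight. All water
#' (extrafibrillar and intrafibrillar) counts: this is the total tissue
#' water (TTW) basis used throughout the package.
#'
#' @param wet Post-flux wet mass, kg.
#' @param dry Dry (lyophilized) mass, kg.
#' @return Hydration, g H2O / g dry weight.
#' @export
hydration <- function(wet, dry) {
  if (any(dry <= 0)) stop("hydration: dry mass must be positive")
  if (any(wet < dry)) stop("hydration: wet mass below dry mass")
  (wet - dry) / dry
}

#' Intra-tissue sodium concentration from an ICP-OES measurement
#'
#' The total moles of sodium measured in a digested sample are normalized
#' to the sample's total tissue water volume, `(wet - dry)` mass of water
#' at density 1000 kg/m^3, i.e. one litre per kilogram.
#'
#' @param na_mol Total sodium in the sample, mol.
#' @param wet,dry Sample wet and dry masses, kg.
#' @return Sodium concentration, mol/L of TTW.
#' @export
sodium_concentration <- function(na_mol, wet, dry) {
  if (any(wet <= dry)) stop("sodium_concentration: wet mass must exceed dry mass")
  if (any(na_mol < 0)) stop("sodium_concentration: negative sodium mass")
  na_mol / (wet - dry)  # kg water == L water at 1000 kg/m^3
}

#' Donnan partition coefficient
#'
#' Ratio of internal to external cation concentration (equal to the
#' external-to-internal anion ratio) at Gibbs-Donnan equilibrium,
#' `k = c_na_int / c_ext`. A fixed negative charge in the tissue makes
#' `k >= 1`; measured sodium below the bath value is physically
#' inconsistent (it would imply negative fixed charge) and draws a
#' warning but is not rejected, so noisy cohorts survive the pipeline.
#'
#' @param c_na_int Intra-tissue sodium, mol/L TTW.
#' @param c_ext Bath NaCl concentration, mol/L.
#' @return Partition coefficient k.
#' @export
partition_coefficient <- function(c_na_int, c_ext = 0.15) {
  if (any(c_na_int <= 0)) stop("partition_coefficient: sodium must be positive")
  if (any(c_na_int < c_ext))
    warning("partition_coefficient: internal sodium below bath concentration ",
            "(implies negative fixed charge density); flagged, not rejected")
  c_na_int / c_ext
}

#' Fixed charge density from intra-tissue sodium
#'
#' Electroneutrality in tissue and bath at Donnan equilibrium gives
#' `c_f = k c_ext - c_ext / k = c_na_int - c_ext^2 / c_na_int`, in mol of
#' monovalent charge per litre of TTW, numerically mEq/g TTW at water
#' density.
#'
#' @inheritParams partition_coefficient
#' @return Fixed charge density c_f, mol/L TTW (mEq/g TTW).
#' @export
fixed_charge_density <- function(c_na_int, c_ext = 0.15) {
  k <- partition_coefficient(c_na_int, c_ext)
  k * c_ext - c_ext / k
}

#' Intra-tissue chloride at Donnan equilibrium
#'
#' Chloride is the measured sodium minus the fixed charge density,
#' equivalently `c_ext^2 / c_na_int` by the Donnan ion product.
#'
#' @inheritParams partition_coefficient
#' @return Chloride concentration, mol/L TTW.
#' @export
intratissue_chloride <- function(c_na_int, c_ext = 0.15) {
  if (any(c_na_int <= 0)) stop("intratissue_chloride: sodium must be positive")
  c_ext^2 / c_na_int
}

#' Total intra-tissue ion concentration
#'
#' Sum of measured sodium and Donnan chloride,
#' `c_na_int + c_ext^2 / c_na_int`; minimized (= 2 c_ext) at zero fixed
#' charge.
#'
#' @inheritParams partition_coefficient
#' @return Total ion concentration, mol/L TTW.
#' @export
total_ion_concentration <- function(c_na_int, c_ext = 0.15) {
  c_na_int + intratissue_chloride(c_na_int, c_ext)
}

#' Ionic (Donnan) swelling pressure from fixed charge density
#'
#' Excess ideal-Donnan osmotic pressure of the tissue ions over the bath,
#' `delta_pi_ion = phi R T (sqrt(c_f^2 + 4 c_ext^2) - 2 c_ext)`,
#' with the same osmotic coefficient applied to tissue and bath ions and
#' concentrations converted to mol/m^3 before multiplying by RT.
#'
#' @param c_f Fixed charge density, mol/L TTW (>= 0).
#' @param constants A [physical_constants()] object.
#' @return Ionic swelling pressure, Pa.
#' @export
ionic_swelling_pressure <- function(c_f, constants = physical_constants()) {
  if (any(c_f < 0)) stop("ionic_swelling_pressure: negative fixed charge density")
  RT <- constants$gas_constant * constants$temperature
  cext <- constants$bath_concentration * 1000  # mol/m^3
  constants$osmotic_coefficient * RT * (sqrt((c_f * 1000)^2 + 4 * cext^2) - 2 * cext)
}

#' Osmolality from total ion concentration
#'
#' `phi * total_ions * 1000`: total ion concentration in mol/L scaled by
#' the osmotic coefficient and expressed in mOsm/kg H2O.
#'
#' @param total_ions Total ion concentration, mol/L TTW.
#' @param phi Osmotic coefficient (default 0.93).
#' @return Osmolality, mOsm/kg H2O.
#' @export
osmolality_from_ions <- function(total_ions, phi = 0.93) {
  if (any(total_ions < 0)) stop("osmolality_from_ions: negative concentration")
  phi * total_ions * 1000
}

#' Fraction of flux swelling accounted for by Donnan swelling
#'
#' Ratio of the ionic (Gibbs-Donnan) to the flux-based swelling above the
#' bath baseline, `(osm_ion - osm_bath)/(osm_flux - osm_bath)`; since
#' both osmolalities share the RT factor this equals the ratio of the two
#' swelling pressures.
#'
#' @param osm_ion Gibbs-Donnan osmolality, mOsm/kg H2O.
#' @param osm_flux Flux-based osmolality, mOsm/kg H2O.
#' @param constants A [physical_constants()] object (sets the bath
#'   osmolality baseline, 279 mOsm/kg H2O at defaults).
#' @return Dimensionless fraction (1 = ionic swelling explains all of the
#'   flux-based swelling).
#' @export
donnan_fraction <- function(osm_ion, osm_flux,
                            constants = physical_constants()) {
  ob <- bath_osmolality(constants)
  if (any(osm_flux <= ob))
    stop("donnan_fraction: flux osmolality at or below bath; fraction undefined")
  (osm_ion - ob) / (osm_flux - ob)
}

#' Full Gibbs-Donnan state for one sample
#'
#' Combines the sodium normalization and the Donnan relations into the
#' per-sample ionic state: sodium, chloride, fixed charge density, total
#' ions, ionic swelling pressure and osmolality, plus TTW hydration.
#'
#' @param record A one-row data frame (or list) with `sample_id`,
#'   `na_mol`, `wet_kg`, `dry_kg`.
#' @param constants A [physical_constants()] object.
#' @param water_fraction Fraction of total tissue water treated as
#'   osmotically available (default 1 = TTW basis). Values below 1
#'   renormalize concentrations to an extrafibrillar-water basis; this is
#'   experimental and off by default since no validated fraction is
#'   shipped.
#' @return One-row data frame: sample_id, hydration, c_na_int, c_cl_int,
#'   fcd, total_ions, delta_pi_ion_Pa, osm_icp_mOsm, donnan_flag (TRUE if
#'   measured sodium fell below the bath concentration).
#' @export
donnan_state <- function(record, constants = physical_constants(),
                         water_fraction = 1) {
  if (water_fraction <= 0 || water_fraction > 1)
    stop("donnan_state: water_fraction must lie in (0, 1]")
  cna <- sodium_concentration(record$na_mol, record$wet_kg, record$dry_kg) /
    water_fraction
  cext <- constants$bath_concentration
  flag <- cna < cext
  ccl <- intratissue_chloride(cna, cext)
  cf <- suppressWarnings(fixed_charge_density(cna, cext))
  data.frame(sample_id = as.character(record$sample_id),
             hydration = hydration(record$wet_kg, record$dry_kg),
             c_na_int = cna, c_cl_int = ccl, fcd = cf,
             total_ions = total_ion_concentration(cna, cext),
             delta_pi_ion_Pa = ionic_swelling_pressure(max(cf, 0), constants),
             osm_icp_mOsm = osmolality_from_ions(total_ion_concentration(cna, cext),
                                                 constants$osmotic_coefficient),
             donnan_flag = flag,
             stringsAsFactors = FALSE)
}

#' Check bath concentration drift over an equilibration
#'
#' Percentage change of the bath ion concentration between start and end
#' of equilibration; the Donnan relations assume the bath stays at its
#' nominal concentration, so drift beyond `threshold` percent draws a
#' warning.
#'
#' @param c_start,c_end Bath concentrations, mol/L.
#' @param threshold Warning threshold, percent (default 1).
#' @return Percent change (signed), invisibly warning if `|change|`
#'   exceeds the threshold.
#' @export
bath_drift <- function(c_start, c_end, threshold = 1) {
  if (any(c_start <= 0)) stop("bath_drift: non-positive starting concentration")
  pct <- 100 * (c_end - c_start) / c_start
  if (any(abs(pct) > threshold))
    warning("bath_drift: bath concentration changed by more than ",
            threshold, "% during equilibration")
  pct
}
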