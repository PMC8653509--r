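#' Perfusion radius from a measured flux
#'
#' The fluid perfused during a measurement of duration `t` is assumed to
#' occupy a cylindrical annulus of tissue around the membrane, so the
#' outer perfusion radius r3 follows from the volume balance
#' `pi L (r3^2 - r2^2) = q t`.
#'
#' @param q Volumetric flux, m^3/s (>= 0).
#' @param t Perfusion time, s (default 300, i.e. the 5 min protocol).
#' @param geometry A [probe_geometry()] object.
#' @return Perfusion radius r3, m (>= r2).
#' @export
perfusion_radius <- function(q, t = 300, geometry = probe_geometry()) {
  if (any(q < 0)) stop("perfusion_radius: negative flux (sign convention)")
  if (t <= 0) stop("perfusion_radius: perfusion time must be positive")
  r2 <- geometry$outer_membrane_radius
  sqrt(q * t / (pi * geometry$membrane_length) + r2^2)
}

#' Radial stretch ratio from wet masses
#'
#' Pressure is applied isotropically by equilibrium dialysis, so tissue
#' compaction is taken as radial: the stretch ratio is the ratio of
#' equivalent spherical radii at post-equilibration and post-excision wet
#' mass, at fixed tissue density, i.e. `lambda = (mf/m0)^(1/3)`.
#'
#' @param m0 Excision wet mass, kg.
#' @param mf Post-equilibration wet mass, kg.
#' @return Stretch ratio lambda (dimensionless).
#' @export
radial_stretch <- function(m0, mf) {
  if (any(m0 <= 0) || any(mf <= 0))
    stop("radial_stretch: masses must be positive")
  (mf / m0)^(1 / 3)
}

#' Strain-dependent hydraulic permeability of nucleus pulposus tissue
#'
#' Empirical confined-compression law for bovine nucleus pulposus,
#' `K(lambda) = 1.59e-15 ((lambda - 0.2)/0.8)^1.13 exp(-0.02 (lambda^2 - 1)^2)`,
#' evaluated at the radial stretch ratio. At `lambda = 1` (no strain) it
#' equals 1.59e-15 m^4/(N s) exactly; it vanishes as `lambda -> 0.2+`
#' where the pore space closes, and is undefined below.
#'
#' @param lambda Stretch ratio; must exceed 0.2.
#' @return Hydraulic tissue permeability, m^4/(N s).
#' @export
tissue_permeability <- function(lambda) {
  if (any(lambda <= 0.2))
    stop("tissue_permeability: undefined for lambda <= 0.2 (pore closure)")
  1.59e-15 * ((lambda - 0.2) / 0.8)^1.13 * exp(-0.02 * (lambda^2 - 1)^2)
}

#' Effective series permeability of membrane plus tissue annulus
#'
#' Radial flow crosses the membrane annulus (r1, r2) then the perfused
#' tissue annulus (r2, r3); the resistances add, giving the
#' log-weighted harmonic average
#' `K_total = ln(r3/r1) / (ln(r2/r1)/K_mem + ln(r3/r2)/K_tissue)`.
#'
#' @param K_mem Membrane hydraulic permeability, m^4/(N s).
#' @param K_tissue Tissue hydraulic permeability, m^4/(N s).
#' @param r3 Perfusion radius, m (>= r2).
#' @param geometry A [probe_geometry()] object.
#' @return Effective permeability K_total, m^4/(N s); lies between
#'   `K_mem` and `K_tissue`, and equals `K_mem` when `r3 = r2`.
#' @export
effective_total_permeability <- function(K_mem, K_tissue, r3,
                                         geometry = probe_geometry()) {
  if (any(K_mem <= 0) || any(K_tissue <= 0))
    stop("effective_total_permeability: permeabilities must be positive")
  r1 <- geometry$inner_membrane_radius
  r2 <- geometry$outer_membrane_radius
  if (any(r3 < r2))
    stop("effective_total_permeability: r3 < r2 (perfusion radius inside membrane)")
  log(r3 / r1) / (log(r2 / r1) / K_mem + log(r3 / r2) / K_tissue)
}

#' Swelling pressure from a measured flux
#'
#' Inverts the radial Darcy law,
#' `q = 2 pi L K_total (pi_tissue - pi_probe) / ln(r3/r1)`,
#' for the osmotic pressure difference between tissue and the
#' 0.15 mol/L NaCl probe filling. The hydrostatic pressure gradient was
#' measured to be three orders of magnitude below the osmotic one and is
#' dropped; `hydrostatic_offset` lets a transducer-paired measurement add
#' it back.
#'
#' @param q Mean volumetric flux, m^3/s.
#' @param K_total Effective permeability from
#'   [effective_total_permeability()], m^4/(N s).
#' @param r3 Perfusion radius, m (> r1).
#' @param geometry A [probe_geometry()] object.
#' @param hydrostatic_offset Optional hydrostatic pressure difference
#'   `P_tissue - P_air`, Pa, subtracted from the Darcy pressure drop.
#' @return Swelling pressure `delta_pi = pi_tissue - pi_probe`, Pa.
#' @export
swelling_pressure_from_flux <- function(q, K_total, r3,
                                        geometry = probe_geometry(),
                                        hydrostatic_offset = 0) {
  if (any(K_total <= 0))
    stop("swelling_pressure_from_flux: non-positive effective permeability")
  r1 <- geometry$inner_membrane_radius
  if (any(r3 <= r1)) stop("swelling_pressure_from_flux: r3 must exceed r1")
  q * log(r3 / r1) / (2 * pi * geometry$membrane_length * K_total) -
    hydrostatic_offset
}

#' Osmolality from a swelling pressure (and back)
#'
#' Total osmotic pressure in the tissue is the swelling pressure plus the
#' bath osmotic pressure; dividing by RT converts it to total osmotically
#' active solute concentration in mol/m^3, identified with mOsm/kg H2O
#' for dilute aqueous solutions. At `delta_pi = 0` this returns the bath
#' osmolality (279 mOsm/kg H2O at the defaults).
#'
#' @param delta_pi Swelling pressure relative to the bath, Pa.
#' @param osmolality Osmolality, mOsm/kg H2O (for the inverse).
#' @param constants A [physical_constants()] object.
#' @return Osmolality in mOsm/kg H2O, or swelling pressure in Pa for
#'   `pressure_from_osmolality`.
#' @export
osmolality_from_pressure <- function(delta_pi,
                                     constants = physical_constants()) {
  RT <- constants$gas_constant * constants$temperature
  osm <- (delta_pi + bath_osmotic_pressure(constants)) / RT
  if (any(osm < 0))
    stop("osmolality_from_pressure: negative osmolality (delta_pi below -pi_bath)")
  osm
}

#' @rdname osmolality_from_pressure
#' @export
pressure_from_osmolality <- function(osmolality,
                                     constants = physical_constants()) {
  RT <- constants$gas_constant * constants$temperature
  osmolality * RT - bath_osmotic_pressure(constants)
}

#' Infer swelling pressure and osmolality for one tissue sample
#'
#' Chains the full flux-based inference for a single tissue flux record:
#' average the triplicate fluxes, compute the radial stretch from wet
#' masses, evaluate the strain-dependent tissue permeability, obtain the
#' perfusion radius from the volume balance, combine membrane and tissue
#' permeabilities in series, invert the radial Darcy law for the swelling
#' pressure, and convert to osmolality.
#'
#' @param record A one-row data frame (or list) with fields `sample_id`,
#'   `applied_pressure_Pa`, `m0_kg`, `mf_kg`, `post_flux_wet_kg`,
#'   `dry_kg`, fluxes `q1_m3s`..`q3_m3s` (NA allowed beyond the first),
#'   and optionally `t_s` (default 300) and `probe_id`.
#' @param K_mem Membrane hydraulic permeability for the probe used,
#'   m^4/(N s).
#' @param geometry A [probe_geometry()] object.
#' @param constants A [physical_constants()] object.
#' @param hydrostatic_offset See [swelling_pressure_from_flux()].
#' @return A one-row data frame: sample_id, applied_pressure_Pa, q_mean,
#'   lambda, r3, K_mem, K_tissue, K_total, delta_pi_Pa, pi_tissue_Pa
#'   (absolute, i.e. delta_pi plus bath pressure), osm_flux_mOsm,
#'   perfused_fraction (perfused water volume over TTW volume).
#' @export
infer_sample <- function(record, K_mem, geometry = probe_geometry(),
                         constants = physical_constants(),
                         hydrostatic_offset = 0) {
  qs <- unlist(record[intersect(c("q1_m3s", "q2_m3s", "q3_m3s"), names(record))],
               use.names = FALSE)
  qs <- qs[!is.na(qs)]
  if (length(qs) < 1L) stop("infer_sample: no flux measurements in record")
  q <- mean(qs)
  t <- if (!is.null(record$t_s) && !is.na(record$t_s)) record$t_s else 300
  lambda <- radial_stretch(record$m0_kg, record$mf_kg)
  Kt <- tissue_permeability(lambda)
  r3 <- perfusion_radius(q, t, geometry)
  Ktot <- effective_total_permeability(K_mem, Kt, r3, geometry)
  dpi <- swelling_pressure_from_flux(q, Ktot, r3, geometry, hydrostatic_offset)
  ttw_vol <- (record$post_flux_wet_kg - record$dry_kg) / 1000  # m^3 at 1000 kg/m^3
  data.frame(sample_id = as.character(record$sample_id),
             applied_pressure_Pa = record$applied_pressure_Pa,
             q_mean = q, lambda = lambda, r3 = r3,
             K_mem = K_mem, K_tissue = Kt, K_total = Ktot,
             delta_pi_Pa = dpi,
             pi_tissue_Pa = dpi + bath_osmotic_pressure(constants),
             osm_flux_mOsm = osmolality_from_pressure(dpi, constants),
             perfused_fraction = if (ttw_vol > 0) q * t / ttw_vol else NA_real_,
             stringsAsFactors = FALSE)
}
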