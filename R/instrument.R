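#' Convert a meniscus displacement series to volumetric flux
#'
#' The water/air interface in the probe tubing is photographed at fixed
#' intervals; its displacement rate times the tubing cross-sectional area
#' gives the volumetric flux through the probe membrane. The rate is the
#' ordinary least-squares slope of position against time over all frames
#' (endpoint differencing is available for two-frame diagnostics).
#'
#' Positive flux means fluid leaving the tubing into the tissue or bath.
#'
#' @param times Frame times, s; strictly increasing, length >= 2.
#' @param positions Meniscus positions along the tubing, m.
#' @param geometry A [probe_geometry()] object (supplies the tubing bore).
#' @param method `"ols"` (default) or `"endpoint"` (two-point difference
#'   between last and first frame).
#' @return Volumetric flux q, m^3/s.
#' @examples
#' g <- probe_geometry()
#' # 1 mm/min displacement in 0.38 mm tubing
#' displacement_to_flux(0:5 * 60, 0:5 * 1e-3, g)
#' @export
displacement_to_flux <- function(times, positions, geometry = probe_geometry(),
                                 method = c("ols", "endpoint")) {
  method <- match.arg(method)
  if (length(times) < 2L || length(positions) != length(times))
    stop("displacement_to_flux: need >= 2 (time, position) pairs of equal length")
  if (any(!is.finite(times)) || any(!is.finite(positions)))
    stop("displacement_to_flux: non-finite values in series")
  if (any(diff(times) <= 0))
    stop("displacement_to_flux: times must be strictly increasing")
  slope <- if (method == "endpoint") {
    (positions[length(positions)] - positions[1L]) / (times[length(times)] - times[1L])
  } else {
    tc <- times - mean(times)
    sum(tc * (positions - mean(positions))) / sum(tc^2)
  }
  slope * tubing_area(geometry)
}

#' PEG virial osmotic pressure
#'
#' Osmotic pressure of a 20 kDa polyethylene glycol solution as a virial
#' polynomial in mass concentration:
#' `pi(c) = a1 c + a2 c^2 + a3 c^3 + ...` with c in g/mL and coefficients
#' in Pa per (g/mL)^k. Used to assign the known osmotic load in probe
#' calibration and equilibrium dialysis.
#'
#' @param concentration PEG mass concentration, g/mL, in \[0, 0.30\].
#' @param coefficients Numeric vector `(a1, a2, ...)`; defaults to
#'   [peg_virial_default()].
#' @return Osmotic pressure, Pa (vectorized over `concentration`).
#' @export
peg_osmotic_pressure <- function(concentration,
                                 coefficients = peg_virial_default()) {
  if (is.null(coefficients) || length(coefficients) == 0L)
    stop("peg_osmotic_pressure: virial coefficients missing; supply them or ",
         "give applied pressures directly")
  if (any(concentration < 0))
    stop("peg_osmotic_pressure: concentration must be non-negative")
  if (any(concentration > 0.30))
    stop("peg_osmotic_pressure: concentration above calibrated range (0.30 g/mL)")
  p <- vapply(concentration, function(ci)
    sum(coefficients * ci^seq_along(coefficients)), numeric(1))
  if (any(p < 0))
    stop("peg_osmotic_pressure: coefficient set yields negative pressure")
  p
}

#' Default 20 kDa PEG virial coefficients (placeholder)
#'
#' A cubic coefficient set (zero intercept) least-squares fitted to the
#' nominal concentration/pressure pairs of the equilibrium-dialysis design
#' (0.05--0.25 g/mL spanning 0.03--0.57 MPa). It reproduces that working
#' range and is monotone on \[0, 0.25\] g/mL, but it is NOT an
#' authoritative literature virial expansion: users with measured
#' coefficients should supply their own (or record applied pressures
#' directly in the calibration table, which bypasses the polynomial).
#'
#' @return Numeric vector `(a1, a2, a3)` in Pa per (g/mL)^k.
#' @export
peg_virial_default <- function() {
  c(195749.7, 7766233.8, 2314049.6)
}

#' Membrane hydraulic permeability from a calibration measurement
#'
#' During calibration the probe sits directly in a PEG bath, so the whole
#' pressure drop `pi_peg` acts across the membrane annulus alone and the
#' radial Darcy law inverts to
#' `K_mem = q ln(r2/r1) / (2 pi L pi_peg)`.
#'
#' All permeabilities in this package are hydraulic, `K = k/mu`, with
#' units m^4/(N s): the viscosity of the 0.15 mol/L NaCl permeant is
#' absorbed and never re-enters downstream equations.
#'
#' @param q Volumetric flux through the membrane, m^3/s (>= 0).
#' @param pi_peg Applied PEG osmotic pressure, Pa (> 0).
#' @param geometry A [probe_geometry()] object.
#' @return Hydraulic membrane permeability K_mem, m^4/(N s).
#' @export
membrane_permeability_from_calibration <- function(q, pi_peg,
                                                   geometry = probe_geometry()) {
  if (any(pi_peg <= 0))
    stop("membrane_permeability_from_calibration: pi_peg must be positive")
  if (any(q < 0))
    stop("membrane_permeability_from_calibration: negative flux; check the ",
         "sign convention (positive = out of tubing)")
  r1 <- geometry$inner_membrane_radius
  r2 <- geometry$outer_membrane_radius
  q * log(r2 / r1) / (2 * pi * geometry$membrane_length * pi_peg)
}

# forward membrane-only flux at known K_mem; used by calibration round-trips
# and by the simulator's calibration records
membrane_flux <- function(K_mem, pi_peg, geometry = probe_geometry()) {
  r1 <- geometry$inner_membrane_radius
  r2 <- geometry$outer_membrane_radius
  2 * pi * geometry$membrane_length * K_mem * pi_peg / log(r2 / r1)
}

#' Calibrate probe membranes from a long-format displacement table
#'
#' Takes per-frame calibration records (one row per photograph) and
#' returns one membrane permeability per (probe, applied pressure)
#' combination. The applied pressure is taken from `applied_pressure_Pa`
#' when present, otherwise computed from `peg_conc_g_per_mL` via
#' [peg_osmotic_pressure()].
#'
#' Probes are calibrated at every pressure they were measured under
#' because membrane permeability itself falls with osmotic load; the
#' inference step looks permeabilities up by (probe, pressure) and falls
#' back to the nearest calibrated pressure with a warning.
#'
#' @param calibration Data frame with columns `probe_id`, `t_s`,
#'   `position_m`, and `applied_pressure_Pa` and/or `peg_conc_g_per_mL`.
#' @param geometry A [probe_geometry()] object.
#' @param coefficients PEG virial coefficients, used only when a record
#'   carries a concentration but no direct pressure.
#' @return Data frame with columns `probe_id`, `applied_pressure_Pa`,
#'   `flux_m3s`, `K_mem`.
#' @export
calibrate_probes <- function(calibration, geometry = probe_geometry(),
                             coefficients = peg_virial_default()) {
  need <- c("probe_id", "t_s", "position_m")
  miss <- setdiff(need, names(calibration))
  if (length(miss))
    stop("calibrate_probes: missing column(s): ", paste(miss, collapse = ", "))
  has_p <- "applied_pressure_Pa" %in% names(calibration)
  has_c <- "peg_conc_g_per_mL" %in% names(calibration)
  if (!has_p && !has_c)
    stop("calibrate_probes: need applied_pressure_Pa or peg_conc_g_per_mL")

  # resolve one applied pressure per record
  pressure <- if (has_p) calibration$applied_pressure_Pa else rep(NA_real_, nrow(calibration))
  if (has_c) {
    fill <- is.na(pressure)
    if (any(fill))
      pressure[fill] <- peg_osmotic_pressure(calibration$peg_conc_g_per_mL[fill],
                                             coefficients)
  }
  if (anyNA(pressure))
    stop("calibrate_probes: records without pressure or concentration present")

  key <- interaction(calibration$probe_id, pressure, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(calibration)), key), function(i) {
    ord <- i[order(calibration$t_s[i])]
    q <- displacement_to_flux(calibration$t_s[ord], calibration$position_m[ord],
                              geometry)
    p <- pressure[ord][1L]
    data.frame(probe_id = as.character(calibration$probe_id[ord][1L]),
               applied_pressure_Pa = p, flux_m3s = q,
               K_mem = membrane_permeability_from_calibration(q, p, geometry),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$probe_id, out$applied_pressure_Pa), , drop = FALSE]
}

# look up K_mem for one probe at one pressure, nearest-pressure fallback
lookup_membrane_permeability <- function(calib, probe_id, applied_pressure,
                                         tol = 1e-6) {
  rows <- calib[calib$probe_id == probe_id, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no membrane calibration for probe '", probe_id, "'")
  d <- abs(rows$applied_pressure_Pa - applied_pressure)
  i <- which.min(d)
  if (d[i] > tol * max(1, applied_pressure))
    warning(sprintf(
      "probe '%s': no calibration at %.3g Pa; using nearest (%.3g Pa)",
      probe_id, applied_pressure, rows$applied_pressure_Pa[i]))
  rows$K_mem[i]
}

#' Flag anomalously permeable probes
#'
#' Marks calibrations whose log permeability lies more than `z` robust
#' standard deviations (median absolute deviation scale) from the median
#' of the other probes at comparable pressure. A torn or otherwise
#' defective membrane shows up as a large positive outlier; flagged
#' probes are reported, never silently excluded.
#'
#' @param calib Output of [calibrate_probes()].
#' @param z Robust z-score threshold (default 3).
#' @return `calib` with a logical `outlier` column appended.
#' @export
flag_permeability_outliers <- function(calib, z = 3) {
  lk <- log(calib$K_mem)
  out <- logical(nrow(calib))
  for (p in unique(calib$applied_pressure_Pa)) {
    i <- which(calib$applied_pressure_Pa == p)
    if (length(i) < 3L) next
    med <- stats::median(lk[i]); s <- stats::mad(lk[i])
    # zero MAD (most probes identical): flag anything >5-fold off the median
    out[i] <- if (s > 0) abs(lk[i] - med) / s > z else abs(lk[i] - med) > log(5)
  }
  calib$outlier <- out
  calib
}
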