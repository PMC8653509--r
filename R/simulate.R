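#' Forward flux through membrane and tissue at known swelling pressure
#'
#' Solves the implicit forward problem that the inference chain inverts:
#' the flux obeys `q = 2 pi L K_total(r3) delta_pi / ln(r3/r1)` while the
#' perfusion radius obeys `r3 = sqrt(q t / (pi L) + r2^2)`, so q appears
#' on both sides. The unique positive root is found by bracketed root
#' finding; `q = 0` solves the system exactly when `delta_pi = 0`.
#'
#' @param delta_pi Swelling pressure, Pa (>= 0).
#' @param K_mem Membrane hydraulic permeability, m^4/(N s).
#' @param lambda Radial stretch ratio (> 0.2), sets the tissue
#'   permeability via [tissue_permeability()].
#' @param t Perfusion time, s.
#' @param geometry A [probe_geometry()] object.
#' @param tol Relative convergence tolerance on q (default 1e-12).
#' @return Volumetric flux q, m^3/s.
#' @export
forward_flux <- function(delta_pi, K_mem, lambda, t = 300,
                         geometry = probe_geometry(), tol = 1e-12) {
  if (delta_pi < 0) stop("forward_flux: delta_pi must be non-negative")
  if (delta_pi == 0) return(0)
  K_tis <- tissue_permeability(lambda)
  r1 <- geometry$inner_membrane_radius
  L <- geometry$membrane_length
  # residual: flux predicted by Darcy at the r3 implied by q, minus q
  f <- function(q) {
    r3 <- perfusion_radius(q, t, geometry)
    Ktot <- effective_total_permeability(K_mem, K_tis, r3, geometry)
    2 * pi * L * Ktot * delta_pi / log(r3 / r1) - q
  }
  # upper bound: membrane-only flux (tissue adds resistance, never removes it)
  hi <- membrane_flux(K_mem, delta_pi, geometry) * 1.0001
  lo <- hi * 1e-12
  if (f(lo) <= 0 || f(hi) >= 0)
    stop("forward_flux: no sign change in bracket [", lo, ", ", hi,
         "]; residuals ", f(lo), " / ", f(hi))
  u <- stats::uniroot(f, c(lo, hi), tol = hi * tol)
  u$root
}

#' Simulation design for a synthetic micro-osmometry cohort
#'
#' Collects the experimental design and noise model for
#' [simulate_cohort()]. Defaults reproduce the equilibrium-dialysis
#' design behind the method's validation: five applied pressures
#' (0.03--0.57 MPa from 5--25% 20 kDa PEG), five samples per group, and
#' multiplicative lognormal measurement noise on flux, sodium and mass.
#'
#' Ground truth ties the tissue swelling pressure exactly to the applied
#' pressure (the equilibrium the method validates), so any departure of
#' recovered concordance from 1 measures pipeline noise.
#'
#' @param applied_pressures Applied osmotic pressures, Pa, sorted.
#' @param samples_per_group Samples per pressure group.
#' @param flux_rel_sd,sodium_rel_sd,mass_rel_sd Relative (lognormal sigma)
#'   SDs of flux, sodium and mass measurement noise.
#' @param membrane_K_ref Membrane permeability at the lowest pressure,
#'   m^4/(N s); per-probe values decline with pressure as
#'   `(P/P_min)^membrane_K_exponent` with lognormal scatter
#'   `membrane_K_rel_sd`.
#' @param membrane_K_exponent,membrane_K_rel_sd See `membrane_K_ref`.
#' @param excision_hydration Hydration (g/g) of freshly excised tissue,
#'   used with the hydration-versus-pressure line to place wet masses.
#' @param dry_mass_kg Nominal dry mass per sample, kg.
#' @param hydration_endpoints Hydration at the lowest and highest default
#'   pressures (g/g); the generator interpolates linearly in pressure.
#' @param perfusion_time Flux measurement duration, s.
#' @param seed Integer RNG seed recorded in the output.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(applied_pressures = c(0.03, 0.10, 0.21, 0.37, 0.57) * 1e6,
                       samples_per_group = 5,
                       flux_rel_sd = 0.05,
                       sodium_rel_sd = 0.08,
                       mass_rel_sd = 0.01,
                       membrane_K_ref = 1e-17,
                       membrane_K_exponent = -0.25,
                       membrane_K_rel_sd = 0.10,
                       excision_hydration = 5.4,
                       dry_mass_kg = 35e-6,
                       hydration_endpoints = c(4.96, 1.64),
                       perfusion_time = 300,
                       seed = 1L) {
  if (is.unsorted(applied_pressures, strictly = TRUE) || any(applied_pressures <= 0))
    stop("sim_config: applied_pressures must be positive and strictly increasing")
  if (samples_per_group < 0) stop("sim_config: samples_per_group must be >= 0")
  sds <- c(flux_rel_sd, sodium_rel_sd, mass_rel_sd, membrane_K_rel_sd)
  if (any(sds < 0)) stop("sim_config: relative SDs must be >= 0")
  structure(list(applied_pressures = applied_pressures,
                 samples_per_group = as.integer(samples_per_group),
                 flux_rel_sd = flux_rel_sd, sodium_rel_sd = sodium_rel_sd,
                 mass_rel_sd = mass_rel_sd,
                 membrane_K_ref = membrane_K_ref,
                 membrane_K_exponent = membrane_K_exponent,
                 membrane_K_rel_sd = membrane_K_rel_sd,
                 excision_hydration = excision_hydration,
                 dry_mass_kg = dry_mass_kg,
                 hydration_endpoints = hydration_endpoints,
                 perfusion_time = perfusion_time,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# hydration line through the design endpoints, pressure in Pa
sim_hydration <- function(P, config) {
  p_mpa <- P / 1e6
  h <- config$hydration_endpoints
  h[1] + (h[2] - h[1]) / (0.57 - 0.03) * (p_mpa - 0.03)
}

# lognormal multiplicative noise with unit median
lnoise <- function(n, rel_sd) if (rel_sd > 0) exp(stats::rnorm(n, 0, rel_sd)) else rep(1, n)

#' Simulate a full synthetic cohort
#'
#' Forward-simulates the three measurement tables the analysis pipeline
#' consumes — probe calibration displacement series, tissue flux records,
#' and ICP-OES sodium records — together with the per-sample ground
#' truth, so the whole inference chain can be tested without laboratory
#' data.
#'
#' For each applied pressure P the generating truth is: swelling pressure
#' `delta_pi = P` (the equilibrium the method validates); osmolality
#' `279 + P/RT`; intra-tissue sodium backed out from total ions via the
#' Donnan ion product; hydration on the design line; wet masses from
#' hydration at the nominal dry mass; radial stretch from the wet-mass
#' ratio; flux from [forward_flux()]. Measurement noise is multiplicative
#' lognormal, applied after the noise-free truth is recorded.
#'
#' @param config A [sim_config()] object.
#' @param constants A [physical_constants()] object.
#' @return A list of class `"sim_cohort"` with data frames `calibration`
#'   (long-format displacement frames), `flux`, `icp`, `truth`, and the
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            constants = physical_constants()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  RT <- constants$gas_constant * constants$temperature
  cext <- constants$bath_concentration
  phi <- constants$osmotic_coefficient
  geometry <- probe_geometry()
  npress <- length(config$applied_pressures)
  n <- config$samples_per_group

  cal_rows <- list(); flux_rows <- list(); icp_rows <- list(); truth_rows <- list()
  frame_times <- seq(0, config$perfusion_time, by = 60)

  for (gi in seq_len(npress)) {
    P <- config$applied_pressures[gi]
    osm_true <- bath_osmolality(constants) + P / RT            # mOsm/kg
    total_ions_true <- osm_true / (1000 * phi)                 # mol/L
    if (total_ions_true < 2 * cext)
      stop("simulate_cohort: infeasible osmolality below bath at P = ", P)
    # invert total = c_na + cext^2/c_na for the Donnan-consistent sodium
    c_na_true <- (total_ions_true + sqrt(total_ions_true^2 - 4 * cext^2)) / 2
    h_true <- sim_hydration(P, config)
    if (h_true <= 0) stop("simulate_cohort: hydration line non-positive at P = ", P)

    for (si in seq_len(n)) {
      sample_id <- sprintf("P%02d_S%02d", gi, si)
      probe_id <- sprintf("probe%02d", si)  # one probe per animal, reused across pressures
      K_mem <- config$membrane_K_ref *
        (P / config$applied_pressures[1])^config$membrane_K_exponent *
        lnoise(1, config$membrane_K_rel_sd)

      dry <- config$dry_mass_kg * lnoise(1, config$mass_rel_sd)
      mf <- dry * (1 + h_true)
      m0 <- dry * (1 + config$excision_hydration)
      lambda <- radial_stretch(m0, mf)

      q_true <- forward_flux(P, K_mem, lambda, config$perfusion_time, geometry)
      q_obs <- q_true * lnoise(3, config$flux_rel_sd)

      # calibration displacement series at this (probe, pressure), noise-free
      # in position (flux noise is carried by the tissue triplicates)
      q_cal <- membrane_flux(K_mem, P, geometry)
      pos <- q_cal / tubing_area(geometry) * frame_times
      cal_rows[[length(cal_rows) + 1L]] <- data.frame(
        probe_id = probe_id, applied_pressure_Pa = P,
        t_s = frame_times, position_m = pos, stringsAsFactors = FALSE)

      # masses as recorded (post-flux wet ~ post-equilibration wet; the
      # perfused volume is a fraction of a percent of TTW)
      flux_rows[[length(flux_rows) + 1L]] <- data.frame(
        sample_id = sample_id, probe_id = probe_id, applied_pressure_Pa = P,
        m0_kg = m0, mf_kg = mf, post_flux_wet_kg = mf, dry_kg = dry,
        q1_m3s = q_obs[1], q2_m3s = q_obs[2], q3_m3s = q_obs[3],
        t_s = config$perfusion_time, stringsAsFactors = FALSE)

      c_na_obs <- c_na_true * lnoise(1, config$sodium_rel_sd)
      icp_rows[[length(icp_rows) + 1L]] <- data.frame(
        sample_id = sample_id, na_mol = c_na_obs * (mf - dry),
        wet_kg = mf, dry_kg = dry, stringsAsFactors = FALSE)

      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample_id = sample_id, applied_pressure_Pa = P,
        delta_pi_Pa = P, osm_mOsm = osm_true, c_na_molL = c_na_true,
        total_ions_molL = total_ions_true, hydration = h_true,
        lambda = lambda, K_mem = K_mem, q_m3s = q_true,
        stringsAsFactors = FALSE)
    }
  }

  empty <- function(cols) as.data.frame(stats::setNames(
    rep(list(numeric(0)), length(cols)), cols))
  structure(list(
    calibration = if (length(cal_rows)) do.call(rbind, cal_rows) else
      empty(c("probe_id", "applied_pressure_Pa", "t_s", "position_m")),
    flux = if (length(flux_rows)) do.call(rbind, flux_rows) else
      empty(c("sample_id", "probe_id", "applied_pressure_Pa", "m0_kg", "mf_kg",
              "post_flux_wet_kg", "dry_kg", "q1_m3s", "q2_m3s", "q3_m3s", "t_s")),
    icp = if (length(icp_rows)) do.call(rbind, icp_rows) else
      empty(c("sample_id", "na_mol", "wet_kg", "dry_kg")),
    truth = if (length(truth_rows)) do.call(rbind, truth_rows) else
      empty(c("sample_id", "applied_pressure_Pa", "delta_pi_Pa", "osm_mOsm",
              "c_na_molL", "total_ions_molL", "hydration", "lambda", "K_mem",
              "q_m3s")),
    config = config), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic micro-osmometry cohort\n")
  cat(sprintf("  %d pressure group(s) x %d sample(s), seed %d\n",
              length(x$config$applied_pressures), x$config$samples_per_group,
              x$config$seed))
  cat(sprintf("  applied pressures: %s MPa\n",
              paste(x$config$applied_pressures / 1e6, collapse = ", ")))
  invisible(x)
}

#' Write a simulated cohort to CSV files
#'
#' Writes `calibration.csv`, `flux.csv`, `icp.csv`, `ground_truth.csv`
#' and a `metadata.json`-style sidecar (plain text key-value, written
#' without external dependencies) recording the seed and design, so a run
#' is reproducible from the directory alone.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(calibration = "calibration.csv", flux = "flux.csv",
             icp = "icp.csv", truth = "ground_truth.csv")
  for (nm in names(files))
    utils::write.csv(cohort[[nm]], file.path(dir, files[[nm]]), row.names = FALSE)
  cfg <- cohort$config
  meta <- c(sprintf("seed: %d", cfg$seed),
            sprintf("applied_pressures_Pa: %s",
                    paste(cfg$applied_pressures, collapse = ",")),
            sprintf("samples_per_group: %d", cfg$samples_per_group),
            sprintf("flux_rel_sd: %g", cfg$flux_rel_sd),
            sprintf("sodium_rel_sd: %g", cfg$sodium_rel_sd),
            sprintf("mass_rel_sd: %g", cfg$mass_rel_sd))
  writeLines(meta, file.path(dir, "metadata.yaml"))
  invisible(file.path(dir, c(files, "metadata.yaml")))
}
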