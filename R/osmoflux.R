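#' Fit the micro-osmometry model to a measurement cohort
#'
#' The central fitting function: takes the probe calibration table, the
#' tissue flux table and (optionally) the ICP-OES sodium table, runs the
#' flux-based radial-Darcy inference and the Gibbs-Donnan ionic
#' computation for every sample, and fits the cohort-level relations —
#' the osmolality-versus-applied-pressure regression and the concordance
#' between applied and inferred swelling pressure.
#'
#' Membrane permeabilities are looked up per (probe, applied pressure);
#' when a probe lacks a calibration at a sample's pressure the nearest
#' calibrated pressure is used with a warning.
#'
#' @param flux Tissue flux data frame (see [read_flux_csv()] for the
#'   schema) or path to its CSV.
#' @param calibration Probe calibration data frame
#'   ([read_calibration_csv()] schema) or CSV path.
#' @param icp Optional ICP-OES data frame ([read_icp_csv()] schema) or
#'   CSV path; enables the Donnan side of the analysis.
#' @param geometry A [probe_geometry()] object.
#' @param constants A [physical_constants()] object.
#' @param virial_coefficients Passed to [calibrate_probes()] for records
#'   specifying PEG concentration instead of pressure.
#' @param hydrostatic_offset See [swelling_pressure_from_flux()].
#' @param group_means Logical; fit the osmolality-versus-pressure
#'   regression on per-group means instead of per-sample values.
#' @return An object of class `"osmoflux"`: list with `samples` (the
#'   per-sample table: flux inference columns, and Donnan columns when
#'   `icp` is given), `calibration` (per-probe permeabilities with
#'   outlier flags), `groups` (the [summarize_groups()] table), `fit`
#'   (linear [ols_fit()] of flux osmolality on applied pressure),
#'   `concordance` (Lin's rho_c of inferred vs applied swelling
#'   pressure), `donnan` (the [donnan_vs_flux_report()], or NULL),
#'   `geometry`, `constants`, `call`.
#' @examples
#' coh <- simulate_cohort(sim_config(samples_per_group = 2, seed = 7))
#' fit <- osmoflux(coh$flux, coh$calibration, coh$icp)
#' print(fit)
#' coef(fit)
#' predict(fit, pressure = c(0.2e6, 0.6e6))
#' @export
osmoflux <- function(flux, calibration, icp = NULL,
                     geometry = probe_geometry(),
                     constants = physical_constants(),
                     virial_coefficients = peg_virial_default(),
                     hydrostatic_offset = 0,
                     group_means = FALSE) {
  cl <- match.call()
  if (is.character(flux)) flux <- read_flux_csv(flux)
  if (is.character(calibration)) calibration <- read_calibration_csv(calibration)
  if (is.character(icp)) icp <- read_icp_csv(icp)

  calib <- flag_permeability_outliers(
    calibrate_probes(calibration, geometry, virial_coefficients))

  samples <- do.call(rbind, lapply(seq_len(nrow(flux)), function(i) {
    rec <- flux[i, , drop = FALSE]
    K_mem <- lookup_membrane_permeability(calib, rec$probe_id,
                                          rec$applied_pressure_Pa)
    infer_sample(rec, K_mem, geometry, constants, hydrostatic_offset)
  }))

  donnan <- NULL
  if (!is.null(icp)) {
    dstates <- do.call(rbind, lapply(seq_len(nrow(icp)), function(i)
      donnan_state(icp[i, , drop = FALSE], constants)))
    donnan <- donnan_vs_flux_report(dstates, samples, constants)
    samples <- donnan$samples
  }

  groups <- summarize_groups(samples)
  fit <- if (group_means) {
    ols_fit(groups$applied_pressure_Pa, groups$osm_flux_mOsm_mean, "linear")
  } else {
    ols_fit(samples$applied_pressure_Pa, samples$osm_flux_mOsm, "linear")
  }
  concordance <- lins_concordance(samples$applied_pressure_Pa,
                                  samples$delta_pi_Pa)

  structure(list(samples = samples, calibration = calib, groups = groups,
                 fit = fit, concordance = concordance, donnan = donnan,
                 geometry = geometry, constants = constants,
                 group_means = group_means, call = cl),
            class = "osmoflux")
}

#' @export
print.osmoflux <- function(x, ...) {
  cat("Micro-osmometry fit\n")
  cat(sprintf("  %d sample(s) in %d pressure group(s)%s\n",
              nrow(x$samples), nrow(x$groups),
              if (is.null(x$donnan)) "" else " (with ICP-OES Donnan analysis)"))
  b <- x$fit$coefficients
  cat(sprintf("  osmolality ~ pressure: %.1f + %.1f mOsm/(kg MPa), R^2 = %.3f\n",
              b[1], b[2] * 1e6, x$fit$r_squared))
  cat(sprintf("  concordance (applied vs inferred pressure): rho_c = %.3f\n",
              x$concordance))
  invisible(x)
}

#' Summarize a micro-osmometry fit
#'
#' @param object An [osmoflux()] fit.
#' @param digits Significant digits for printing.
#' @param ... Unused.
#' @return An object of class `"summary.osmoflux"` holding the group
#'   table, fit, concordance, diurnal bounds and Donnan trend.
#' @export
summary.osmoflux <- function(object, digits = 4, ...) {
  structure(list(groups = object$groups, fit = object$fit,
                 concordance = object$concordance,
                 diurnal = diurnal_extrapolation(object$fit),
                 donnan_trend = if (!is.null(object$donnan))
                   object$donnan$trend else NA_real_,
                 donnan_groups = if (!is.null(object$donnan))
                   object$donnan$groups else NULL,
                 outliers = sum(object$calibration$outlier),
                 digits = digits),
            class = "summary.osmoflux")
}

#' @export
print.summary.osmoflux <- function(x, ...) {
  cat("Group summary (mean across samples):\n")
  g <- x$groups
  disp <- data.frame(`P (MPa)` = g$applied_pressure_Pa / 1e6, n = g$n,
                     check.names = FALSE)
  if ("hydration_mean" %in% names(g)) disp$hydration <- round(g$hydration_mean, 2)
  if ("c_na_int_mean" %in% names(g)) disp$`Na+ (mol/L)` <- round(g$c_na_int_mean, 2)
  if ("total_ions_mean" %in% names(g)) disp$`ions (mol/L)` <- round(g$total_ions_mean, 2)
  if ("fcd_mean" %in% names(g)) disp$`FCD (mEq/g)` <- round(g$fcd_mean, 2)
  if ("osm_icp_mOsm_mean" %in% names(g)) disp$`osm ICP` <- round(g$osm_icp_mOsm_mean)
  disp$`osm flux` <- round(g$osm_flux_mOsm_mean)
  print(disp, row.names = FALSE)
  cat(sprintf("\nOsmolality vs pressure: intercept %.1f, slope %.1f mOsm/(kg MPa), R^2 = %.3f\n",
              x$fit$coefficients[1], x$fit$coefficients[2] * 1e6, x$fit$r_squared))
  cat(sprintf("Concordance applied vs inferred pressure: rho_c = %.3f\n",
              x$concordance))
  d <- x$diurnal
  cat(sprintf("Diurnal bounds (0.2-0.6 MPa): %.0f to %.0f mOsm/kg (magnitude %.0f)\n",
              d["osm_low"], d["osm_high"], d["magnitude"]))
  if (!is.na(x$donnan_trend))
    cat(sprintf("Donnan fraction trend vs pressure: Spearman rho = %.2f\n",
                x$donnan_trend))
  if (x$outliers > 0)
    cat(sprintf("Note: %d calibration(s) flagged as permeability outliers\n",
                x$outliers))
  invisible(x)
}

#' @export
coef.osmoflux <- function(object, ...) {
  b <- object$fit$coefficients
  c(intercept = b[1], slope = b[2])
}

#' Predict tissue osmolality at new applied pressures
#'
#' Evaluates the fitted osmolality-versus-pressure line; with the default
#' pressures this is the diurnal extrapolation to 0.2 and 0.6 MPa.
#'
#' @param object An [osmoflux()] fit.
#' @param pressure Applied pressures, Pa.
#' @param ... Unused.
#' @return Predicted osmolalities, mOsm/kg H2O.
#' @export
predict.osmoflux <- function(object, pressure = c(0.2e6, 0.6e6), ...) {
  b <- object$fit$coefficients
  stats::setNames(b[1] + b[2] * pressure, paste0(pressure / 1e6, "MPa"))
}

#' @export
residuals.osmoflux <- function(object, type = c("fit", "concordance"), ...) {
  type <- match.arg(type)
  if (type == "fit") stats::residuals(object$fit$lm)
  else object$samples$delta_pi_Pa - object$samples$applied_pressure_Pa
}

#' Simulate replicate cohorts from a fitted model
#'
#' Parametric re-simulation: generates new synthetic cohorts at the
#' fitted object's applied pressures using the ground-truth relation
#' `delta_pi = P` and the default noise model, for parameter-recovery
#' and power exploration.
#'
#' @param object An [osmoflux()] fit.
#' @param nsim Number of cohorts.
#' @param seed Integer seed for the first cohort (incremented per
#'   replicate).
#' @param ... Passed to [sim_config()].
#' @return List of `"sim_cohort"` objects (length `nsim`).
#' @export
simulate.osmoflux <- function(object, nsim = 1, seed = 1L, ...) {
  pressures <- sort(unique(object$samples$applied_pressure_Pa))
  n <- max(table(object$samples$applied_pressure_Pa))
  lapply(seq_len(nsim), function(i)
    simulate_cohort(sim_config(applied_pressures = pressures,
                               samples_per_group = n,
                               seed = as.integer(seed) + i - 1L, ...),
                    object$constants))
}

#' Diagnostic plots for a micro-osmometry fit
#'
#' Two base-graphics panels: concordance of inferred against applied
#' swelling pressure (with the identity line), and osmolality against
#' applied pressure with the fitted line and, when ICP-OES data are
#' present, the Gibbs-Donnan osmolalities for comparison.
#'
#' @param x An [osmoflux()] fit.
#' @param which Integer subset of panels (1 = concordance,
#'   2 = osmolality).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.osmoflux <- function(x, which = 1:2, ...) {
  s <- x$samples
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  if (1 %in% which) {
    graphics::plot(s$applied_pressure_Pa / 1e6, s$delta_pi_Pa / 1e6,
                   xlab = "Applied pressure (MPa)",
                   ylab = "Inferred swelling pressure (MPa)",
                   main = sprintf("Concordance (rho_c = %.2f)", x$concordance),
                   ...)
    graphics::abline(0, 1, lty = 2)
  }
  if (2 %in% which) {
    graphics::plot(s$applied_pressure_Pa / 1e6, s$osm_flux_mOsm,
                   xlab = "Applied pressure (MPa)",
                   ylab = "Osmolality (mOsm/kg H2O)",
                   main = "Tissue osmolality", ...)
    b <- x$fit$coefficients
    graphics::abline(b[1], b[2] * 1e6, lty = 1)
    if (!is.null(x$donnan)) {
      graphics::points(s$applied_pressure_Pa / 1e6, s$osm_icp_mOsm, pch = 2)
      graphics::legend("topleft", pch = c(1, 2), bty = "n",
                       legend = c("flux", "Gibbs-Donnan"))
    }
  }
  invisible(x)
}

#' Write the per-sample results of a fit to CSV
#'
#' @param object An [osmoflux()] fit.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(object, path) {
  stopifnot(inherits(object, "osmoflux"))
  utils::write.csv(object$samples, path, row.names = FALSE)
  invisible(path)
}
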