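#' Per-pressure group summaries of osmotic properties
#'
#' Builds the cohort summary table: per applied-pressure group, the mean
#' and SD of hydration, intra-tissue sodium, total ions, fixed charge
#' density, ICP-OES osmolality and flux osmolality, plus the per-sample
#' flux-osmolality change from a reference pressure group (by default
#' 0.21 MPa) averaged within group.
#'
#' @param samples Per-sample data frame carrying `applied_pressure_Pa`
#'   and any of the columns `hydration`, `c_na_int`, `total_ions`, `fcd`,
#'   `osm_icp_mOsm`, `osm_flux_mOsm`.
#' @param reference_pressure Reference pressure for the delta-osmolality
#'   column, Pa; the nearest present group is used.
#' @return Data frame, one row per pressure group (ascending), with
#'   `<var>_mean` / `<var>_sd` columns, `n`, and
#'   `delta_osm_mean`/`delta_osm_sd` when flux osmolality is present.
#'   Groups with a single sample get SD 0 and `sd_flagged = TRUE`.
#' @export
summarize_groups <- function(samples, reference_pressure = 0.21e6) {
  if (!"applied_pressure_Pa" %in% names(samples))
    stop("summarize_groups: samples must carry applied_pressure_Pa")
  vars <- intersect(c("hydration", "c_na_int", "total_ions", "fcd",
                      "osm_icp_mOsm", "osm_flux_mOsm"), names(samples))
  pressures <- sort(unique(samples$applied_pressure_Pa))

  delta <- NULL
  if ("osm_flux_mOsm" %in% vars) {
    ref_p <- pressures[which.min(abs(pressures - reference_pressure))]
    ref_mean <- mean(samples$osm_flux_mOsm[samples$applied_pressure_Pa == ref_p])
    delta <- samples$osm_flux_mOsm - ref_mean
  }

  rows <- lapply(pressures, function(p) {
    i <- samples$applied_pressure_Pa == p
    n <- sum(i)
    row <- data.frame(applied_pressure_Pa = p, n = n)
    for (v in vars) {
      x <- samples[[v]][i]
      row[[paste0(v, "_mean")]] <- mean(x)
      row[[paste0(v, "_sd")]] <- if (n > 1) stats::sd(x) else 0
    }
    if (!is.null(delta)) {
      row$delta_osm_mean <- mean(delta[i])
      row$delta_osm_sd <- if (n > 1) stats::sd(delta[i]) else 0
    }
    row$sd_flagged <- n < 2
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Least-squares fit (linear or quadratic)
#'
#' Thin wrapper around [stats::lm()] returning the fit pieces the
#' reporting layer uses: coefficients, R^2, the slope p-value from its t
#' statistic, and n.
#'
#' @param x,y Numeric vectors of equal length.
#' @param form `"linear"` or `"quadratic"`.
#' @return An object of class `"osmo_fit"`: list with `form`,
#'   `coefficients` (intercept first), `r_squared`, `p_slope`, `n`, and
#'   the underlying `lm` object.
#' @export
ols_fit <- function(x, y, form = c("linear", "quadratic")) {
  form <- match.arg(form)
  if (length(x) != length(y)) stop("ols_fit: x and y lengths differ")
  n <- length(x)
  need <- if (form == "linear") 3L else 4L
  if (n < need) stop("ols_fit: need at least ", need, " points for a ", form, " fit")
  fit <- if (form == "linear") stats::lm(y ~ x) else stats::lm(y ~ x + I(x^2))
  if (any(is.na(stats::coef(fit)))) stop("ols_fit: rank-deficient design")
  sm <- suppressWarnings(summary(fit))
  # constant response: nothing to explain, R^2 is 0 by convention (and
  # summary.lm's ratio of rounding residuals is meaningless)
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
  structure(list(form = form,
                 coefficients = unname(stats::coef(fit)),
                 r_squared = r2,
                 p_slope = sm$coefficients["x", "Pr(>|t|)"],
                 n = n, lm = fit),
            class = "osmo_fit")
}

#' @export
print.osmo_fit <- function(x, ...) {
  cat(sprintf("%s least-squares fit (n = %d)\n", x$form, x$n))
  cat("  coefficients:", paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  cat(sprintf("  R^2 = %.4f, slope p = %.3g\n", x$r_squared, x$p_slope))
  invisible(x)
}

#' Diurnal osmolality bounds by extrapolating a linear fit
#'
#' Evaluates a linear osmolality-versus-pressure fit at the pressures
#' conventionally used to simulate the diurnal loading cycle (0.2 and
#' 0.6 MPa) and returns both endpoints and the cycle magnitude (their
#' difference).
#'
#' @param fit A linear [ols_fit()] result with pressure in Pa on x.
#' @param p_low,p_high Evaluation pressures, Pa.
#' @return Named numeric vector `c(osm_low, osm_high, magnitude)`,
#'   mOsm/kg H2O.
#' @export
diurnal_extrapolation <- function(fit, p_low = 0.2e6, p_high = 0.6e6) {
  if (!inherits(fit, "osmo_fit") || fit$form != "linear")
    stop("diurnal_extrapolation: need a linear ols_fit")
  b <- fit$coefficients
  lo <- b[1] + b[2] * p_low
  hi <- b[1] + b[2] * p_high
  c(osm_low = lo, osm_high = hi, magnitude = hi - lo)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' computed with population (1/n) moments — the standard definition.
#' Unlike Pearson correlation it penalizes location and scale shifts, so
#' `rho_c = 1` only when y equals x exactly. Implemented directly from
#' the definition.
#'
#' @param x,y Paired numeric vectors, length >= 2.
#' @return rho_c in \[-1, 1\].
#' @export
lins_concordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("lins_concordance: need paired vectors of length >= 2")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  denom <- vx + vy + (mx - my)^2
  if (denom == 0)
    stop("lins_concordance: zero variance with equal means; rho_c undefined")
  2 * cxy / denom
}

#' Spearman rank correlation
#'
#' Pearson correlation of (average-tie) ranks, delegated to
#' [stats::cor()]. Errors on constant input, where the coefficient is
#' undefined.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return rho in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("spearman_rho: need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_rho: constant vector; correlation undefined")
  stats::cor(x, y, method = "spearman")
}

#' Compare Donnan and flux swelling per sample and per group
#'
#' Joins per-sample Gibbs-Donnan states with flux-based swelling results
#' on sample id, computes each sample's Donnan fraction (ionic share of
#' the flux-based swelling above bath), and summarizes by pressure
#' group, with a Spearman trend test of fraction against applied
#' pressure.
#'
#' @param donnan Per-sample data frame from [donnan_state()] rows
#'   (carrying `sample_id`, `osm_icp_mOsm`).
#' @param swelling Per-sample data frame from [infer_sample()] rows
#'   (carrying `sample_id`, `applied_pressure_Pa`, `osm_flux_mOsm`).
#' @param constants A [physical_constants()] object.
#' @return List with `samples` (joined table plus `donnan_fraction`),
#'   `groups` (per-pressure mean/SD of the fraction), and `trend`
#'   (Spearman rho of fraction vs pressure, NA when fewer than 3 distinct
#'   samples).
#' @export
donnan_vs_flux_report <- function(donnan, swelling,
                                  constants = physical_constants()) {
  if (!all(donnan$sample_id %in% swelling$sample_id) ||
      !all(swelling$sample_id %in% donnan$sample_id))
    stop("donnan_vs_flux_report: sample ids do not match between tables")
  joined <- merge(swelling, donnan, by = "sample_id", sort = TRUE)
  joined$donnan_fraction <- donnan_fraction(joined$osm_icp_mOsm,
                                            joined$osm_flux_mOsm, constants)
  groups <- summarize_groups(
    joined[, c("applied_pressure_Pa", "osm_icp_mOsm", "osm_flux_mOsm")])
  fr <- stats::aggregate(donnan_fraction ~ applied_pressure_Pa, joined,
                         function(z) c(mean = mean(z),
                                       sd = if (length(z) > 1) stats::sd(z) else 0))
  groups$donnan_fraction_mean <- fr$donnan_fraction[, "mean"]
  groups$donnan_fraction_sd <- fr$donnan_fraction[, "sd"]
  trend <- if (nrow(joined) >= 3 &&
               length(unique(joined$applied_pressure_Pa)) > 1 &&
               stats::sd(joined$donnan_fraction) > 0)
    spearman_rho(joined$applied_pressure_Pa, joined$donnan_fraction)
  else NA_real_
  list(samples = joined, groups = groups, trend = trend)
}
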