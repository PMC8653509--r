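#' Read a measurement CSV with schema validation
#'
#' Shared reader for the three measurement tables. Headers are matched
#' case-insensitively against the schema; missing required columns raise
#' a schema error naming the column; rows with non-numeric entries in
#' numeric columns are dropped and reported as warnings with their line
#' numbers, so one corrupt row does not sink a run.
#'
#' @param path CSV file path (comma-separated, UTF-8, '.' decimal;
#'   scientific notation accepted).
#' @param required,optional Character vectors of column names; columns
#'   not named `probe_id`/`sample_id` are coerced to numeric.
#' @return Data frame with canonical column names.
#' @keywords internal
read_checked_csv <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  canon <- c(required, optional)
  idx <- match(tolower(canon), tolower(names(raw)))
  missing_req <- canon[seq_along(required)][is.na(idx[seq_along(required)])]
  if (length(missing_req))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing_req, collapse = ", "))
  have <- !is.na(idx)
  out <- raw[, idx[have], drop = FALSE]
  names(out) <- canon[have]
  if (nrow(out) == 0L) return(out)

  id_cols <- intersect(c("probe_id", "sample_id"), names(out))
  num_cols <- setdiff(names(out), id_cols)
  bad <- rep(FALSE, nrow(out))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    blank <- !nzchar(trimws(out[[cc]])) | is.na(out[[cc]])
    bad <- bad | (is.na(v) & !blank)
    out[[cc]] <- v
  }
  if (any(bad)) {
    warning("dropped ", sum(bad), " malformed row(s) in ", basename(path),
            " (data line ", paste(which(bad), collapse = ", "), ")")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read the probe calibration table
#'
#' Long format, one row per meniscus photograph: `probe_id`, `t_s`,
#' `position_m`, and `applied_pressure_Pa` and/or `peg_conc_g_per_mL`.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_calibration_csv <- function(path) {
  out <- read_checked_csv(path, required = c("probe_id", "t_s", "position_m"),
                          optional = c("applied_pressure_Pa", "peg_conc_g_per_mL"))
  if (!any(c("applied_pressure_Pa", "peg_conc_g_per_mL") %in% names(out)))
    stop("schema error in ", basename(path),
         ": need applied_pressure_Pa or peg_conc_g_per_mL")
  out
}

#' Read the tissue flux table
#'
#' One row per tissue sample: identifiers, applied pressure, the four
#' weights (excision, post-equilibration, post-flux, dry) and up to three
#' flux measurements, with an optional perfusion time column.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_flux_csv <- function(path) {
  read_checked_csv(path,
    required = c("sample_id", "probe_id", "applied_pressure_Pa",
                 "m0_kg", "mf_kg", "post_flux_wet_kg", "dry_kg", "q1_m3s"),
    optional = c("q2_m3s", "q3_m3s", "t_s"))
}

#' Read the ICP-OES sodium table
#'
#' One row per digested sample: `sample_id`, total sodium `na_mol`, and
#' the sample wet and dry masses used for TTW normalization.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_icp_csv <- function(path) {
  read_checked_csv(path, required = c("sample_id", "na_mol", "wet_kg", "dry_kg"))
}

#' Load a YAML run configuration
#'
#' Reads constants and geometry overrides, optional virial coefficients
#' and an optional hydrostatic offset from a YAML file, validating every
#' override through [physical_constants()] / [probe_geometry()] so an
#' out-of-range value fails at load time, not mid-pipeline.
#'
#' Recognized top-level keys: `constants` (any argument of
#' [physical_constants()]), `geometry` (any argument of
#' [probe_geometry()]), `virial_coefficients` (numeric list),
#' `hydrostatic_offset_Pa`.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return List with `constants`, `geometry`, `virial_coefficients`,
#'   `hydrostatic_offset`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  constants <- do.call(physical_constants, as.list(raw$constants))
  geometry <- do.call(probe_geometry, as.list(raw$geometry))
  coeffs <- if (!is.null(raw$virial_coefficients))
    as.numeric(unlist(raw$virial_coefficients)) else peg_virial_default()
  list(constants = constants, geometry = geometry,
       virial_coefficients = coeffs,
       hydrostatic_offset = if (!is.null(raw$hydrostatic_offset_Pa))
         as.numeric(raw$hydrostatic_offset_Pa) else 0)
}
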