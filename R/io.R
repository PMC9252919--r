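#' Read a pH-rate profile from CSV
#'
#' Expected schema (header mandatory): `ph, k_obs_per_s, ci95_per_s,
#' replicates`. Rows are validated before any computation; malformed rows
#' are reported with their line numbers.
#'
#' @param path Path to a CSV file.
#' @param compound,temperature Metadata attached to the profile.
#' @return A [ph_rate_profile()].
#' @export
read_ph_profile <- function(path, compound = "",
                            temperature = body_temperature) {
  d <- .read_csv_checked(path, c("ph", "k_obs_per_s", "ci95_per_s",
                                 "replicates"))
  bad <- which(!is.finite(d$k_obs_per_s) | d$k_obs_per_s <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-numeric k_obs_per_s at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  ph_rate_profile(d$ph, d$k_obs_per_s, d$ci95_per_s, d$replicates,
                  compound = compound, temperature = temperature)
}

#' Write a pH-rate profile to CSV
#'
#' @param profile A [ph_rate_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ph_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ph_rate_profile"))
  d <- profile$points
  names(d) <- c("ph", "k_obs_per_s", "ci95_per_s", "replicates")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a kinetic time course from CSV
#'
#' Expected schema: `time, time_unit, value, replicate, observable_kind`.
#' Times may mix units across rows (`s`, `min`, `h`); they are normalized
#' to seconds internally.
#'
#' @param path Path to a CSV file.
#' @return A [time_course()].
#' @export
read_timecourse <- function(path) {
  d <- .read_csv_checked(path, c("time", "time_unit", "value", "replicate",
                                 "observable_kind"))
  kinds <- unique(as.character(d$observable_kind))
  if (length(kinds) != 1) {
    stop("observable_kind must be constant within one file; found: ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  time_course(d$time, d$value, d$replicate, time_unit = d$time_unit,
              observable_kind = kinds)
}

#' Write a kinetic time course to CSV
#'
#' Times are written in seconds.
#'
#' @param tc A [time_course()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  d <- data.frame(time = tc$records$time, time_unit = "s",
                  value = tc$records$value, replicate = tc$records$replicate,
                  observable_kind = tc$observable_kind)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a microspecies network definition from CSV
#'
#' Expected schema: `label, n_protons, charge, log_beta, reactive,
#' barrier_kcal_mol` (the barrier may be empty for non-reactive species).
#'
#' @param path Path to a CSV file.
#' @param molecule,temperature Metadata for the network.
#' @return A [microspecies_network()].
#' @export
read_network <- function(path, molecule = "custom",
                         temperature = body_temperature) {
  d <- .read_csv_checked(path, c("label", "n_protons", "charge", "log_beta",
                                 "reactive", "barrier_kcal_mol"),
                         numeric_cols = c("n_protons", "charge", "log_beta"))
  d$reactive <- as.logical(d$reactive)
  d$barrier_kcal_mol <- suppressWarnings(as.numeric(d$barrier_kcal_mol))
  microspecies_network(d, molecule = molecule, temperature = temperature)
}

#' Write a microspecies network definition to CSV
#'
#' @param network A [microspecies_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "microspecies_network"))
  d <- network$species[, c("label", "n_protons", "charge", "log_beta",
                           "reactive", "barrier_kcal_mol")]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# shared CSV reader: checks existence, required columns, numeric fields
.read_csv_checked <- function(path, required,
                              numeric_cols = intersect(
                                required, c("ph", "k_obs_per_s", "ci95_per_s",
                                            "replicates", "time", "value"))) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !(is.na(d[[col]]) | d[[col]] == ""))
    if (length(bad) > 0) {
      stop("non-numeric '", col, "' at line(s) ",
           paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
    }
    d[[col]] <- v
  }
  d
}

#' Write a machine-readable fit report
#'
#' Serializes a [fit_ph_profile()] or [fit_first_order()] result to JSON
#' with full numeric precision: parameters and uncertainties, chi-square
#' and \eqn{R^2} where available, residuals, the seed (if any) and the
#' package version. The file round-trips through [read_fit_report()].
#'
#' @param fit A `ph_rate_fit` or `kinetic_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  if (inherits(fit, "ph_rate_fit")) {
    rec <- list(
      type = "ph_rate_fit",
      parameters = fit$free_parameters,
      fixed_rates = as.list(fit$fixed_rates),
      chi_square = fit$chi_square,
      chi_square_reduced = fit$chi_square_reduced,
      r_square = fit$r_square,
      residuals = fit$residuals,
      converged = fit$converged,
      iterations = fit$iterations,
      seed = fit$seed,
      weighting = fit$weighting,
      log_scale = fit$log_scale
    )
  } else if (inherits(fit, "kinetic_fit")) {
    rec <- list(
      type = "kinetic_fit",
      model = fit$model,
      rate = fit$rate, rate_se = fit$rate_se,
      rate_ci = as.list(fit$rate_ci),
      conf_level = fit$conf_level,
      half_life_h = fit$half_life_h,
      amplitude = fit$amplitude, baseline = fit$baseline,
      residuals = fit$residuals,
      converged = fit$converged
    )
  } else {
    stop("fit must be a ph_rate_fit or kinetic_fit object", call. = FALSE)
  }
  rec$package_version <- as.character(utils::packageVersion("quinrelease"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fit report written by [write_fit_report()]
#'
#' @param path Path to the JSON report.
#' @return A list mirroring the serialized fields.
#' @export
read_fit_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
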