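#' Read and write concentration-time arm tables
#'
#' The arms CSV dialect has columns `arm_id`, `dose_g`, `time_min`,
#' `conc_mM` and optionally `sd_mM`, `n` - the format produced by
#' [generate_serum_profiles()] and consumed by [fit_pk_model()].
#'
#' @param path File path.
#' @return `read_arms_csv` returns the validated data frame.
#' @export
read_arms_csv <- function(path) {
  arms <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_arms(arms)
  arms
}

#' @rdname read_arms_csv
#' @param arms Arms data frame.
#' @export
write_arms_csv <- function(arms, path) {
  utils::write.csv(arms, path, row.names = FALSE)
  invisible(path)
}

#' Read and write model parameters as flat JSON
#'
#' The JSON layout is flat keys `CL`, `C0`, `ka`, `Km_prime`, `Vd`, `Vmax`,
#' `molar_mass` plus a `units` string documenting the unit system
#' (amounts mmol, concentrations mM, volumes L, time min).
#'
#' @param path File path.
#' @return `read_pk_params` returns a [pk_params] object.
#' @export
read_pk_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pk_params(CL = x$CL, C0 = x$C0, ka = x$ka, Km_prime = x$Km_prime,
            Vd = x$Vd, Vmax = x$Vmax,
            molar_mass = if (!is.null(x$molar_mass)) x$molar_mass else HB_MOLAR_MASS)
}

#' @rdname read_pk_params
#' @param params A [pk_params] object.
#' @export
write_pk_params <- function(params, path) {
  validate_pk_params(params)
  out <- c(unclass(params)[c("CL", "C0", "ka", "Km_prime", "Vd", "Vmax",
                             "molar_mass")],
           list(units = "CL L/min; C0 mM; ka 1/min; Km_prime mmol; Vd L; Vmax mmol/min; molar_mass g/mol"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a simulated profile as CSV
#'
#' Columns `time_min`, `gut_mmol`, `conc_mM`.
#'
#' @param profile A `sim_profile` from [pk_simulate()].
#' @param path File path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile[, c("time_min", "gut_mmol", "conc_mM")], path,
                   row.names = FALSE)
  invisible(path)
}
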