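# Run configuration: YAML or JSON, validated against a fixed key schema
# (unknown keys are rejected so typos fail loudly), merged over defaults.

.CONFIG_SCHEMA <- list(
  scheme = c("flip_angle", "repetition_time", "n_transients", "t_first",
             "excluded_indices"),
  kinetics = c("k_fwd", "k_rev", "r1_sub", "r1_prod", "m0_sub", "m0_prod"),
  noise = c("cv", "obs_noise_frac", "fum_obs_noise_frac", "polarisation_cv"),
  substrates = c("pyruvate_mm", "fumarate_mm"),
  spectrum = c("spectral_width", "n_points", "carrier_frequency",
               "center_ppm", "noise_sd", "linewidth"),
  schedule = c("timepoints", "kp_scale", "kf_true", "nadh_scale",
               "apoptotic_frac", "necrotic_frac"),
  cohort = c("n_per_group", "kp_base", "n_cytometry_events"),
  seed = NULL, output = NULL)

#' Default run configuration
#'
#' The cell-suspension experiment defaults: 6 degree flip, 1 s repetition,
#' 240 transients; T1 30 s both pools; 75 mM pyruvate and 20 mM fumarate;
#' 10\% rate-constant CV and 2\% observation noise.
#'
#' @return Nested named list in the run-config layout.
#' @export
defaultRunConfig <- function() {
  list(
    scheme = list(flip_angle = 6, repetition_time = 1, n_transients = 240L,
                  t_first = 1, excluded_indices = integer()),
    kinetics = list(k_fwd = 0.075, k_rev = 0, r1_sub = 1 / 30,
                    r1_prod = 1 / 30, m0_sub = 75, m0_prod = 0),
    noise = list(cv = 0.10, obs_noise_frac = 0.02, fum_obs_noise_frac = 0.004,
                 polarisation_cv = 0.15),
    substrates = list(pyruvate_mm = 75, fumarate_mm = 20),
    spectrum = list(spectral_width = 32000, n_points = 32768L,
                    carrier_frequency = 100, center_ppm = 177,
                    noise_sd = 0, linewidth = 20),
    cohort = list(n_per_group = 4L, kp_base = 0.075,
                  n_cytometry_events = 2000L),
    seed = 1L)
}

#' Read and validate a run configuration
#'
#' Reads YAML (.yaml/.yml) or JSON (.json), rejects unknown keys, and
#' merges the result over \code{\link{defaultRunConfig}}.
#'
#' @param path config file.
#' @return Validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validateRunConfig(cfg)
  base <- defaultRunConfig()
  for (sec in names(cfg)) {
    if (is.list(cfg[[sec]]) && is.list(base[[sec]]))
      for (k in names(cfg[[sec]])) base[[sec]][[k]] <- cfg[[sec]][[k]]
    else base[[sec]] <- cfg[[sec]]
  }
  base
}

#' Validate a run-config list against the published key schema
#'
#' @param cfg nested list.
#' @return TRUE invisibly; errors on unknown keys.
#' @export
validateRunConfig <- function(cfg) {
  unknown <- setdiff(names(cfg), names(.CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    allowed <- .CONFIG_SCHEMA[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Build model objects from a run config
#'
#' @param cfg validated config list.
#' @return \code{configScheme}: an \linkS4class{AcquisitionScheme};
#'   \code{configParameters}: an \linkS4class{ExchangeParameters};
#'   \code{configSchedule}: a \linkS4class{TreatmentSchedule} (the default
#'   cell schedule when the config has no schedule section).
#' @export
configScheme <- function(cfg) {
  s <- cfg$scheme
  AcquisitionScheme(s$flip_angle, s$repetition_time, s$n_transients,
                    tFirst = if (is.null(s$t_first)) s$repetition_time
                             else s$t_first,
                    excludedIndices = as.integer(unlist(s$excluded_indices)))
}

#' @rdname configScheme
#' @export
configParameters <- function(cfg) {
  k <- cfg$kinetics
  ExchangeParameters(k$k_fwd, k$k_rev, k$r1_sub, k$r1_prod, k$m0_sub,
                     k$m0_prod)
}

#' @rdname configScheme
#' @export
configSchedule <- function(cfg) {
  if (is.null(cfg$schedule)) return(cellSchedule())
  s <- cfg$schedule
  TreatmentSchedule(unlist(s$timepoints), unlist(s$kp_scale),
                    unlist(s$kf_true), unlist(s$nadh_scale),
                    unlist(s$apoptotic_frac), unlist(s$necrotic_frac))
}
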