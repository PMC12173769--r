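# Flat config keys <-> constructor arguments.  Keys follow the circuit
# literature's symbols (W_LA_BAf etc.); everything unspecified falls back
# to the calibrated defaults.
.config_keys <- list(
  circuit = c(W_LA_BAf = "w_la_baf", W_BA_inhib = "w_ba_inhib",
              W_LA_inhib = "w_la_inhib", W_BAf_CeA = "w_baf_cea",
              W_LA_CeA = "w_la_cea", W_BAe_CeA = "w_bae_cea",
              W_CeA_inhib = "w_cea_inhib", Dr_BA = "dr_ba",
              Dr_LA = "dr_la", Dr_CeA = "dr_cea", tau = "tau"),
  response = c(Ex = "gain", Th = "threshold"),
  noise = c(noise_mean = "mean", noise_sd = "sd", noise_enabled = "enabled"),
  integration = c(dt = "dt", steps_trial = "steps_trial",
                  steps_intertrial = "steps_intertrial"),
  session = c(condition = "condition", n_acq = "n_acq", n_rest = "n_rest",
              n_ext = "n_ext", I_Thal = "i_thal", I_Hip = "i_hip",
              I_PFC = "i_pfc", crit_acq = "crit_acq", crit_ext = "crit_ext",
              readout_steps = "readout_steps", seed = "seed"),
  learning = c(alpha = "alpha"),
  init = c(W_Thal_LA_init = "w_thal_la", W_Hip_BAf_init = "w_hip_baf",
           W_PFC_BAe_init = "w_pfc_bae"))

#' Load a session configuration from a flat YAML/JSON file
#'
#' Keys are named after the model's symbols (e.g. `W_CeA_inhib`, `Dr_CeA`,
#' `tau`, `alpha`, `Ex`, `Th`, `noise_mean`, `noise_sd`, `dt`,
#' `steps_trial`, `steps_intertrial`, `I_Hip`, `crit_acq`, ...).  Any key
#' left out falls back to the calibrated default; unknown keys are
#' rejected; invariant violations (e.g. a negative weight) fail with a
#' descriptive error from the corresponding constructor.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file; an empty file
#'   yields the full default configuration.
#' @return A [session_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a flat key/value mapping",
                          call. = FALSE)
  session_config_from_list(cfg)
}

#' Build a session configuration from a flat named list
#'
#' The programmatic equivalent of [load_config()].
#'
#' @param cfg Named list of flat config keys.
#' @return A [session_config()].
#' @export
session_config_from_list <- function(cfg) {
  known <- unlist(lapply(.config_keys, names), use.names = FALSE)
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pick <- function(group) {
    keys <- .config_keys[[group]]
    present <- intersect(names(keys), names(cfg))
    setNames(cfg[present], keys[present])
  }
  response <- do.call(response_params, pick("response"))
  circuit <- do.call(circuit_params, c(pick("circuit"),
                                       list(response = response)))
  args <- pick("session")
  args$params <- circuit
  args$learning <- do.call(learning_params, pick("learning"))
  args$noise <- do.call(noise_spec, pick("noise"))
  args$integration <- do.call(integration_spec, pick("integration"))
  args$init_weights <- do.call(plastic_weights, pick("init"))
  do.call(session_config, args)
}

#' Flatten a session configuration to config keys
#'
#' Inverse of [session_config_from_list()]; used for run manifests.
#'
#' @param config A [session_config()].
#' @return A named list of flat config keys.
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "session_config"))
  out <- list()
  grab <- function(group, obj) {
    keys <- .config_keys[[group]]
    for (k in names(keys)) out[[k]] <<- obj[[keys[[k]]]]
  }
  grab("circuit", config$params_base)  # pre-overlay base values
  grab("response", config$params_base$response)
  grab("noise", config$noise)
  grab("integration", config$integration)
  grab("learning", config$learning)
  grab("init", as.list(config$init_weights))
  grab("session", config)
  out$condition <- config$condition$name
  out[!vapply(out, is.null, logical(1))]
}

#' Write session / ensemble results to disk
#'
#' Writes, into `out_dir`: one trial-by-trial CSV per session
#' (`session_<i>.csv`, columns trial, phase, the five mean activities, the
#' three plastic weights and the prediction error), a `summary.json` with
#' per-criterion statistics, and a `manifest.json` (flat config snapshot,
#' seeds, package version, timestamp) sufficient to reproduce the run.
#'
#' @param x A `session_result` or `ensemble_summary`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  record_cols <- c(trial = "trial", phase = "phase",
                   U_LA = "u_la", U_BAf = "u_baf", U_BAe = "u_bae",
                   U_CeAOn = "u_on", U_CeAOff = "u_off",
                   W_Thal_LA = "w_thal_la", W_Hip_BAf = "w_hip_baf",
                   W_PFC_BAe = "w_pfc_bae", ERR = "err")
  write_session_csv <- function(res, file) {
    df <- res$records[, record_cols]
    names(df) <- names(record_cols)
    write.csv(df, file, row.names = FALSE)
    file
  }
  if (inherits(x, "session_result")) {
    paths <- c(paths, write_session_csv(x, file.path(out_dir, "session_1.csv")))
    summary <- list(
      condition = x$config$condition$name,
      trials_to_acquisition = x$trials_to_acquisition,
      trials_to_extinction = x$trials_to_extinction,
      reactivations = reactivation_count(x))
    config <- x$config
  } else if (inherits(x, "ensemble_summary")) {
    if (!is.null(x$sessions))
      for (i in seq_along(x$sessions))
        paths <- c(paths, write_session_csv(
          x$sessions[[i]], file.path(out_dir, sprintf("session_%d.csv", i))))
    summary <- list(
      condition = x$condition, n_sessions = x$n_sessions,
      base_seed = x$base_seed,
      acquisition = x$acquisition, extinction = x$extinction,
      reactivation_total = x$reactivation_total,
      per_session = x$counts)
    config <- NULL
  } else stop("unsupported result type", call. = FALSE)
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  manifest <- list(
    package = "amyfear",
    version = as.character(packageVersion("amyfear")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    schema = "amyfear-results-1",
    config = if (!is.null(config)) config_to_list(config) else NULL)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sp, mp))
}
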