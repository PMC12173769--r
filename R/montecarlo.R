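#' Run an ensemble of independent sessions
#'
#' Simulates `n_sessions` sessions with seeds `base_seed`,
#' `base_seed + 1`, ... and aggregates the two trials-to-criterion
#' statistics.  Sessions that never reach a criterion are excluded from
#' that criterion's mean/SD and reported as a failure fraction.
#'
#' @param config A [session_config()]; its own `seed` is ignored.
#' @param n_sessions Number of sessions (default 100).
#' @param base_seed First session seed.
#' @param keep_sessions If `TRUE`, attach the list of `session_result`s.
#' @return An object of class `ensemble_summary` with per-session counts,
#'   means, SDs, failure fractions and reactivation totals.
#' @export
run_ensemble <- function(config, n_sessions = 100, base_seed = 1,
                         keep_sessions = FALSE) {
  stopifnot(inherits(config, "session_config"), n_sessions >= 1)
  acq <- integer(n_sessions)
  ext <- integer(n_sessions)
  react <- integer(n_sessions)
  sessions <- if (keep_sessions) vector("list", n_sessions) else NULL
  for (i in seq_len(n_sessions)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + i - 1)
    res <- run_session(cfg)
    acq[i] <- res$trials_to_acquisition
    ext[i] <- res$trials_to_extinction
    react[i] <- reactivation_count(res)
    if (keep_sessions) sessions[[i]] <- res
  }
  summarise <- function(x) {
    ok <- x[!is.na(x)]
    list(mean = if (length(ok)) mean(ok) else NA_real_,
         sd = if (length(ok) > 1) sd(ok) else if (length(ok) == 1) 0 else NA_real_,
         n = length(ok),
         failure_fraction = mean(is.na(x)))
  }
  structure(list(condition = config$condition$name,
                 n_sessions = n_sessions,
                 base_seed = base_seed,
                 acquisition = summarise(acq),
                 extinction = summarise(ext),
                 counts = data.frame(session = seq_len(n_sessions),
                                     seed = base_seed + seq_len(n_sessions) - 1,
                                     trials_to_acquisition = acq,
                                     trials_to_extinction = ext,
                                     reactivations = react),
                 reactivation_total = sum(react),
                 sessions = sessions),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary>", x$condition, "-", x$n_sessions, "sessions\n")
  cat(sprintf("  acquisition: %.2f trials (SD %.2f, %d reached, %.0f%% failed)\n",
              x$acquisition$mean, x$acquisition$sd, x$acquisition$n,
              100 * x$acquisition$failure_fraction))
  cat(sprintf("  extinction:  %.2f trials (SD %.2f, %d reached, %.0f%% failed)\n",
              x$extinction$mean, x$extinction$sd, x$extinction$n,
              100 * x$extinction$failure_fraction))
  cat("  post-extinction reactivation trials:", x$reactivation_total, "\n")
  invisible(x)
}

#' Sweep a circuit parameter over a grid
#'
#' For each grid value, overrides the named parameter in the session's
#' (post-overlay) circuit parameters, runs an ensemble and records the
#' criteria plus the mean extinction-phase activities of the five
#' populations.  `alpha` may also be swept.
#'
#' @param config A [session_config()].
#' @param param Name of a `circuit_params` field (e.g. `"w_cea_inhib"`)
#'   or `"alpha"`.
#' @param grid Strictly monotone numeric vector of values.
#' @param n_sessions Sessions per grid point.
#' @param base_seed First session seed (shared across grid points).
#' @return An object of class `sweep_result`: a data.frame with one row
#'   per grid point.
#' @export
parameter_sweep <- function(config, param, grid, n_sessions = 10,
                            base_seed = 1) {
  stopifnot(inherits(config, "session_config"),
            is.numeric(grid), length(grid) >= 1)
  if (length(grid) > 1 && !(all(diff(grid) > 0) || all(diff(grid) < 0)))
    stop("`grid` must be strictly monotone", call. = FALSE)
  valid <- c(setdiff(names(unclass(config$params)), "response"), "alpha")
  if (!param %in% valid)
    stop("unknown parameter name: ", param, call. = FALSE)
  rows <- lapply(grid, function(v) {
    cfg <- config
    if (param == "alpha") {
      cfg$learning <- learning_params(alpha = v)
    } else {
      cfg$params <- apply_condition(cfg$params, setNames(list(v), param))
    }
    ens <- run_ensemble(cfg, n_sessions = n_sessions, base_seed = base_seed,
                        keep_sessions = TRUE)
    ext_means <- colMeans(do.call(rbind, lapply(ens$sessions, function(s) {
      ext <- s$records[s$records$phase == "extinction",
                       c("u_la", "u_baf", "u_bae", "u_on", "u_off")]
      colMeans(ext)
    })))
    data.frame(param = param, value = v,
               acq_mean = ens$acquisition$mean, acq_sd = ens$acquisition$sd,
               ext_mean = ens$extinction$mean, ext_sd = ens$extinction$sd,
               acq_failed = ens$acquisition$failure_fraction,
               ext_failed = ens$extinction$failure_fraction,
               ext_u_la = ext_means[["u_la"]], ext_u_baf = ext_means[["u_baf"]],
               ext_u_bae = ext_means[["u_bae"]], ext_u_on = ext_means[["u_on"]],
               ext_u_off = ext_means[["u_off"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Compare the three conditions with matched ensembles
#'
#' Runs naive, acute and chronic ensembles with identical settings and
#' returns the mean and SD of trials to acquisition and extinction for
#' each.
#'
#' @param n_sessions Sessions per condition (default 100).
#' @param base_seed First session seed (shared across conditions).
#' @param config Base [session_config()]; the condition field is replaced.
#' @return A data.frame with one row per condition (class
#'   `condition_comparison`).
#' @export
compare_conditions <- function(n_sessions = 100, base_seed = 1,
                               config = session_config()) {
  rows <- lapply(c("naive", "acute", "chronic"), function(cond) {
    cfg <- session_config(
      condition = cond,
      params = config$params_base,
      n_acq = config$n_acq, n_rest = config$n_rest, n_ext = config$n_ext,
      learning = config$learning, integration = config$integration,
      noise = config$noise,
      i_thal = config$i_thal, i_hip = config$i_hip, i_pfc = config$i_pfc,
      init_weights = config$init_weights,
      crit_acq = config$crit_acq, crit_ext = config$crit_ext,
      readout_steps = config$readout_steps)
    ens <- run_ensemble(cfg, n_sessions = n_sessions, base_seed = base_seed)
    data.frame(condition = cond,
               acq_mean = ens$acquisition$mean, acq_sd = ens$acquisition$sd,
               ext_mean = ens$extinction$mean, ext_sd = ens$extinction$sd,
               acq_failed = ens$acquisition$failure_fraction,
               ext_failed = ens$extinction$failure_fraction,
               reactivations = ens$reactivation_total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("condition_comparison", "data.frame")
  out
}
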