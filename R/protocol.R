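#' Session configuration
#'
#' Bundles everything needed to simulate one conditioning session:
#' trial counts for the three phases, the condition overlay, circuit /
#' learning / integration / noise parameters, the input levels of the
#' three afferents when active, initial plastic weights, the two
#' trials-to-criterion thresholds, and the RNG seed.
#'
#' Phase structure (defaults): 15 acquisition trials (CS + context on,
#' US = 1), 10 home-cage rest trials (all inputs off, plasticity frozen),
#' 35 extinction trials (CS + mPFC on, context off, US = 0).  Each trial is
#' `steps_trial` Euler steps of stimulus followed by `steps_intertrial`
#' steps of relaxation.
#'
#' Calibration constants: the active input levels (`i_thal = 1`,
#' `i_hip = 0.4`, `i_pfc = 0.75`), the initial plastic weight (0.22) and
#' the acquisition criterion (0.8) were fixed once on the naive condition
#' to reproduce its trial-count statistics and late-extinction firing
#' rates; the alcohol conditions are then pure predictions.  See the
#' package vignette.
#'
#' @param condition Condition name or a [condition_overlay()].
#' @param n_acq,n_rest,n_ext Trial counts per phase.
#' @param params Base [circuit_params()] (the overlay is applied on top).
#' @param learning A [learning_params()] object.
#' @param integration An [integration_spec()] object.
#' @param noise A [noise_spec()] object.
#' @param i_thal,i_hip,i_pfc Input levels when the corresponding afferent
#'   is active.
#' @param init_weights Initial [plastic_weights()].
#' @param crit_acq Acquisition criterion on trial-averaged CeAOn (default 0.8).
#' @param crit_ext Extinction criterion on trial-averaged CeAOn (default 0.1).
#' @param readout_steps Terminal steps averaged for the CeAOn readout.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return An object of class `session_config`.
#' @export
session_config <- function(condition = "naive",
                           n_acq = 15, n_rest = 10, n_ext = 35,
                           params = circuit_params(),
                           learning = learning_params(),
                           integration = integration_spec(),
                           noise = noise_spec(),
                           i_thal = 1.0, i_hip = 0.4, i_pfc = 0.75,
                           init_weights = plastic_weights(),
                           crit_acq = 0.8, crit_ext = 0.1,
                           readout_steps = 10,
                           seed = NULL) {
  if (is.character(condition)) condition <- condition_overlay(condition)
  stopifnot(inherits(condition, "condition_overlay"),
            n_acq >= 0, n_rest >= 0, n_ext >= 0,
            inherits(params, "circuit_params"),
            inherits(learning, "learning_params"),
            inherits(integration, "integration_spec"),
            inherits(noise, "noise_spec"),
            i_thal >= 0, i_thal <= 1, i_hip >= 0, i_hip <= 1,
            i_pfc >= 0, i_pfc <= 1,
            inherits(init_weights, "plastic_weights"),
            crit_acq > 0, crit_acq < 1, crit_ext > 0, crit_ext < 1)
  structure(list(condition = condition,
                 n_acq = as.integer(n_acq), n_rest = as.integer(n_rest),
                 n_ext = as.integer(n_ext),
                 params = apply_condition(params, condition),
                 params_base = params,
                 learning = learning, integration = integration,
                 noise = noise,
                 i_thal = i_thal, i_hip = i_hip, i_pfc = i_pfc,
                 init_weights = init_weights,
                 crit_acq = crit_acq, crit_ext = crit_ext,
                 readout_steps = as.integer(readout_steps),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "session_config")
}

#' Build the ordered trial schedule of a session
#'
#' Acquisition trials present the CS (thalamic input) and context
#' (hippocampal input) with US = 1; rest trials present nothing and freeze
#' plasticity; extinction trials present the CS and the mPFC input in a new
#' context (hippocampal input silent) with US = 0.
#'
#' @param config A [session_config()].
#' @return A data.frame of class `session_schedule`, one row per trial,
#'   with columns `trial` (0-based index), `phase`, `i_thal`, `i_hip`,
#'   `i_pfc`, `us`, `stimulus_steps`, `intertrial_steps`, `plasticity_on`.
#' @export
build_schedule <- function(config) {
  stopifnot(inherits(config, "session_config"))
  phases <- rep(c("acquisition", "rest", "extinction"),
                c(config$n_acq, config$n_rest, config$n_ext))
  n <- length(phases)
  sched <- data.frame(
    trial = seq_len(n) - 1L,
    phase = phases,
    i_thal = ifelse(phases == "rest", 0, config$i_thal),
    i_hip = ifelse(phases == "acquisition", config$i_hip, 0),
    i_pfc = ifelse(phases == "extinction", config$i_pfc, 0),
    us = as.integer(phases == "acquisition"),
    stimulus_steps = config$integration$steps_trial,
    intertrial_steps = config$integration$steps_intertrial,
    plasticity_on = phases != "rest",
    stringsAsFactors = FALSE)
  class(sched) <- c("session_schedule", "data.frame")
  sched
}

#' Run a single trial
#'
#' Integrates the stimulus period with the trial's inputs, records
#' stimulus-period mean activities and the terminal CeAOn readout,
#' computes the prediction error, applies (if plasticity is on) the
#' trial-end weight updates using trial-averaged postsynaptic rates, and
#' finally relaxes through the intertrial interval with inputs off.
#'
#' @param state Current [circuit_state()].
#' @param weights Current [plastic_weights()].
#' @param trial One row of a [build_schedule()] data.frame (as a list or
#'   1-row data.frame).
#' @param config The [session_config()].
#' @return A list with the advanced `state`, updated `weights`, and a
#'   one-row `record` data.frame.
#' @export
run_trial <- function(state, weights, trial, config) {
  inputs <- input_vector(i_thal = trial$i_thal, i_hip = trial$i_hip,
                         i_pfc = trial$i_pfc, us = trial$us)
  stim <- integrate_block(state, weights, config$params, inputs,
                          n_steps = trial$stimulus_steps,
                          dt = config$integration$dt,
                          noise = config$noise,
                          readout_steps = config$readout_steps)
  err <- prediction_error(trial$us, stim$readout)
  if (isTRUE(trial$plasticity_on)) {
    alpha <- config$learning$alpha
    inc <- c(
      fear_pathway_update(err, trial$us, alpha, trial$i_thal, stim$mean[1]),
      fear_pathway_update(err, trial$us, alpha, trial$i_hip, stim$mean[2]),
      extinction_pathway_update(err, alpha, trial$i_pfc, stim$mean[3]))
    weights <- apply_updates(weights, inc)
  }
  state <- settle(stim$state, weights, config$params,
                  n_steps = trial$intertrial_steps,
                  dt = config$integration$dt, noise = config$noise)
  record <- data.frame(
    trial = trial$trial, phase = trial$phase,
    u_la = stim$mean[1], u_baf = stim$mean[2], u_bae = stim$mean[3],
    u_on = stim$mean[4], u_off = stim$mean[5],
    readout = stim$readout, err = err,
    w_thal_la = weights[["w_thal_la"]],
    w_hip_baf = weights[["w_hip_baf"]],
    w_pfc_bae = weights[["w_pfc_bae"]],
    stringsAsFactors = FALSE)
  list(state = state, weights = weights, record = record)
}

#' Run a full conditioning session
#'
#' Runs the whole schedule sequentially, carrying state and plastic
#' weights across trials, and computes the two trials-to-criterion counts.
#'
#' @param config A [session_config()].
#' @return An object of class `session_result`: a list with `records`
#'   (one-row-per-trial data.frame), `trials_to_acquisition`,
#'   `trials_to_extinction` (integer or `NA`), and the `config`.
#' @examples
#' \donttest{
#' res <- run_session(session_config("naive", seed = 1))
#' res$trials_to_acquisition
#' }
#' @export
run_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  sched <- build_schedule(config)
  state <- circuit_state()
  weights <- config$init_weights
  records <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    out <- run_trial(state, weights, sched[i, ], config)
    state <- out$state
    weights <- out$weights
    records[[i]] <- out$record
  }
  records <- do.call(rbind, records)
  res <- structure(list(records = records, config = config),
                   class = "session_result")
  res$trials_to_acquisition <- trials_to_acquisition(res)
  res$trials_to_extinction <- trials_to_extinction(res)
  res
}

#' Trials to the fear-acquisition criterion
#'
#' The 1-based count of acquisition trials elapsed until the first trial
#' whose stimulus-period mean CeAOn activity reaches `threshold`.
#'
#' @param result A `session_result`.
#' @param threshold Criterion on mean CeAOn (default the session's
#'   `crit_acq`).
#' @return Integer count, or `NA_integer_` if never reached.
#' @export
trials_to_acquisition <- function(result,
                                  threshold = result$config$crit_acq) {
  stopifnot(threshold > 0, threshold < 1)
  acq <- result$records[result$records$phase == "acquisition", ]
  hit <- which(acq$u_on >= threshold)
  if (length(hit)) hit[1] else NA_integer_
}

#' Trials to the fear-extinction criterion
#'
#' The count of extinction trials elapsed, starting at the recall trial
#' (the first post-rest trial), until the first extinction trial whose
#' stimulus-period mean CeAOn activity falls to `threshold` or below.
#'
#' @param result A `session_result`.
#' @param threshold Criterion on mean CeAOn (default the session's
#'   `crit_ext`).
#' @return Integer count, or `NA_integer_` if never reached.
#' @export
trials_to_extinction <- function(result,
                                 threshold = result$config$crit_ext) {
  stopifnot(threshold > 0, threshold < 1)
  ext <- result$records[result$records$phase == "extinction", ]
  if (nrow(ext) == 0L) return(NA_integer_)
  hit <- which(ext$u_on <= threshold)
  if (length(hit)) hit[1] else NA_integer_
}

#' Post-extinction reactivation trials
#'
#' Counts extinction trials in which the fear response returns (mean CeAOn
#' above `threshold`) after extinction has been established, i.e. after at
#' least two consecutive sub-criterion trials.  Under chronic alcohol the
#' weak CeAOff equilibrium lets noise switch the CeA back to the fear
#' state in occasional trials; in the naive condition this does not
#' happen.
#'
#' @param result A `session_result`.
#' @param threshold Reactivation threshold on mean CeAOn (default 0.5).
#' @return Integer count of reactivation trials.
#' @export
reactivation_count <- function(result, threshold = 0.5) {
  ext <- result$records[result$records$phase == "extinction", ]
  if (nrow(ext) < 3L) return(0L)
  low <- ext$u_on <= result$config$crit_ext
  established <- FALSE
  n <- 0L
  for (i in seq_len(nrow(ext))) {
    if (established && ext$u_on[i] > threshold) n <- n + 1L
    if (i >= 2L && low[i] && low[i - 1L]) established <- TRUE
  }
  n
}

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result> condition:", x$config$condition$name, "\n")
  cat("  trials:", nrow(x$records),
      sprintf("(%d acq / %d rest / %d ext)\n",
              x$config$n_acq, x$config$n_rest, x$config$n_ext))
  cat("  trials to acquisition:", x$trials_to_acquisition, "\n")
  cat("  trials to extinction: ", x$trials_to_extinction, "\n")
  invisible(x)
}
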