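#' Net synaptic inputs to the five populations
#'
#' Internal helper assembling each population's net input (before noise and
#' the response function):
#' LA receives its own inhibition and the thalamic CS; BAf receives BAe
#' inhibition, LA excitation and the hippocampal context; BAe receives BAf
#' inhibition and the mPFC input; CeAOn receives BAf and LA excitation and
#' CeAOff inhibition; CeAOff receives BAe excitation and CeAOn inhibition.
#'
#' @noRd
net_inputs <- function(state, plastic, params, inputs) {
  c(la  = -params$w_la_inhib * state[["u_la"]] +
          plastic[["w_thal_la"]] * inputs[["i_thal"]] + params$dr_la,
    baf = -params$w_ba_inhib * state[["u_bae"]] +
          params$w_la_baf * state[["u_la"]] +
          plastic[["w_hip_baf"]] * inputs[["i_hip"]] + params$dr_ba,
    bae = -params$w_ba_inhib * state[["u_baf"]] +
          plastic[["w_pfc_bae"]] * inputs[["i_pfc"]] + params$dr_ba,
    on  = params$w_baf_cea * state[["u_baf"]] +
          params$w_la_cea * state[["u_la"]] -
          params$w_cea_inhib * state[["u_off"]] + params$dr_cea,
    off = params$w_bae_cea * state[["u_bae"]] -
          params$w_cea_inhib * state[["u_on"]] + params$dr_cea)
}

#' Time derivatives of the circuit state
#'
#' Evaluates \eqn{dU/dt = (F(\mathrm{net} + \eta) - U)/\tau} for each of the
#' five populations, with the net inputs of the full circuit.
#'
#' @param state A [circuit_state()] vector.
#' @param plastic A [plastic_weights()] vector.
#' @param params A [circuit_params()] object.
#' @param inputs An [input_vector()].
#' @param eta Optional per-population noise (length 5, default 0).
#' @return Named numeric vector of derivatives (per second), order
#'   LA, BAf, BAe, CeAOn, CeAOff.
#' @export
derivatives <- function(state, plastic, params, inputs,
                        eta = rep(0, 5)) {
  net <- net_inputs(state, plastic, params, inputs)
  f <- response(net + eta, params$response)
  setNames((f - as.numeric(state)) / params$tau, names(state))
}

#' Single Euler step (R reference implementation)
#'
#' Advances the state by one step of size `dt`, drawing (if enabled) one
#' N(mean, sd) noise value per population, and clamping the result to
#' \[0, 1\].  The compiled integrator [integrate_block()] performs the same
#' update; with identical RNG state the two produce identical trajectories.
#'
#' @inheritParams derivatives
#' @param dt Step size in seconds.
#' @param noise A [noise_spec()] object.
#' @return The new `circuit_state`.
#' @export
euler_step <- function(state, plastic, params, inputs, dt = 0.015,
                       noise = noise_spec(enabled = FALSE)) {
  eta <- if (noise$enabled) rnorm(5, noise$mean, noise$sd) else rep(0, 5)
  u <- as.numeric(state) + dt * derivatives(state, plastic, params, inputs, eta)
  structure(setNames(pmin(1, pmax(0, u)), names(state)),
            class = "circuit_state")
}

#' Integrate a block of steps with constant inputs (compiled core)
#'
#' Runs `n_steps` clamped Euler steps with fixed inputs and plastic
#' weights, returning the final state, the per-population mean activity
#' over the block, and the mean CeAOn activity over the terminal
#' `readout_steps` steps (the US-prediction readout).
#'
#' @inheritParams euler_step
#' @param n_steps Number of steps (>= 0).
#' @param readout_steps Terminal averaging window for the CeAOn readout
#'   (default 10).
#' @param record If `TRUE`, also return the full `n_steps` x 5 trajectory.
#' @return A list with `state`, `mean`, `readout` and optionally
#'   `trajectory`.
#' @export
integrate_block <- function(state, plastic, params, inputs, n_steps,
                            dt = 0.015, noise = noise_spec(),
                            readout_steps = 10, record = FALSE) {
  stopifnot(n_steps >= 0)
  if (n_steps == 0)
    return(list(state = state, mean = as.numeric(state),
                readout = state[["u_on"]]))
  p <- unclass(params)
  p$gain <- params$response$gain
  p$threshold <- params$response$threshold
  res <- cpp_integrate(as.numeric(state), as.numeric(plastic), p,
                       as.numeric(inputs)[1:3], as.integer(n_steps),
                       dt, noise$enabled, noise$mean, noise$sd,
                       as.integer(readout_steps), record)
  res$state <- structure(setNames(res$state, names(state)),
                         class = "circuit_state")
  if (record)
    colnames(res$trajectory) <- c("u_la", "u_baf", "u_bae", "u_on", "u_off")
  res
}

#' Relax the circuit with all inputs off
#'
#' Applies `n_steps` Euler steps with zero inputs and no US (intertrial
#' relaxation); noise stays on if enabled.  With noise off and the default
#' parameters all activities settle within 1e-3 of the spontaneous baseline
#' F(0).
#'
#' @inheritParams integrate_block
#' @return The relaxed `circuit_state`.
#' @export
settle <- function(state, plastic, params, n_steps = 500, dt = 0.015,
                   noise = noise_spec()) {
  if (n_steps == 0) return(state)
  integrate_block(state, plastic, params, input_vector(), n_steps,
                  dt = dt, noise = noise)$state
}
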