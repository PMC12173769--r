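#' Fixed circuit parameters
#'
#' All non-plastic synaptic weights, internal drives and time constant of
#' the five-population amygdala circuit, plus the shared response function.
#' Defaults are the calibrated naive-condition values; weights are in
#' normalized synaptic-weight units (1 unit of resulting input corresponds
#' to roughly 100 pA), `tau` in seconds.
#'
#' @param w_la_baf Excitatory LA -> BAf weight (default 0.49).
#' @param w_ba_inhib Inhibitory weight between BAf and BAe (default 0.13).
#' @param w_la_inhib Inhibitory self-weight within LA (default 1.0).
#' @param w_baf_cea Excitatory BAf -> CeAOn weight (default 0.65).
#' @param w_la_cea Excitatory LA -> CeAOn weight (default 0.65).
#' @param w_bae_cea Excitatory BAe -> CeAOff weight (default 0.98).
#' @param w_cea_inhib Inhibitory weight between CeAOn and CeAOff (default 1.5).
#' @param dr_ba,dr_la,dr_cea Internal drives (defaults 0; drives may be
#'   negative, e.g. the chronic-alcohol CeA drive of -0.5).
#' @param tau Time constant of all populations in seconds (default 0.05).
#' @param response A [response_params()] object.
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(w_la_baf = 0.49, w_ba_inhib = 0.13,
                           w_la_inhib = 1.0, w_baf_cea = 0.65,
                           w_la_cea = 0.65, w_bae_cea = 0.98,
                           w_cea_inhib = 1.5,
                           dr_ba = 0, dr_la = 0, dr_cea = 0,
                           tau = 0.05, response = response_params()) {
  w <- c(w_la_baf = w_la_baf, w_ba_inhib = w_ba_inhib,
         w_la_inhib = w_la_inhib, w_baf_cea = w_baf_cea,
         w_la_cea = w_la_cea, w_bae_cea = w_bae_cea,
         w_cea_inhib = w_cea_inhib)
  if (any(!is.finite(w)) || any(w < 0))
    stop("synaptic weights must be finite and non-negative", call. = FALSE)
  stopifnot(is.finite(tau), tau > 0,
            is.finite(dr_ba), is.finite(dr_la), is.finite(dr_cea),
            inherits(response, "response_params"))
  structure(list(w_la_baf = w_la_baf, w_ba_inhib = w_ba_inhib,
                 w_la_inhib = w_la_inhib, w_baf_cea = w_baf_cea,
                 w_la_cea = w_la_cea, w_bae_cea = w_bae_cea,
                 w_cea_inhib = w_cea_inhib,
                 dr_ba = dr_ba, dr_la = dr_la, dr_cea = dr_cea,
                 tau = tau, response = response),
            class = "circuit_params")
}

#' Additive input noise specification
#'
#' Gaussian noise added inside the response function's argument,
#' independently per population per Euler step: eta ~ N(mean, sd).
#' The defaults (mean 0.03, sd 0.1 = 10% of maximal activity) are the
#' standard simulation conditions.
#'
#' @param mean Noise mean in normalized activity units (default 0.03).
#' @param sd Noise standard deviation (default 0.1).
#' @param enabled Logical; `FALSE` turns noise off for deterministic runs.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mean = 0.03, sd = 0.1, enabled = TRUE) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, is.logical(enabled))
  structure(list(mean = mean, sd = sd, enabled = isTRUE(enabled)),
            class = "noise_spec")
}

#' Euler integration settings
#'
#' @param dt Step size in seconds (default 0.015, i.e. 15 ms).
#' @param steps_trial Steps per stimulus period (default 1000, i.e. 15 s).
#' @param steps_intertrial Steps per intertrial relaxation (default 500,
#'   i.e. 7.5 s with the default `dt`).
#' @return An object of class `integration_spec`.
#' @export
integration_spec <- function(dt = 0.015, steps_trial = 1000,
                             steps_intertrial = 500) {
  stopifnot(is.finite(dt), dt > 0,
            steps_trial >= 1, steps_intertrial >= 0)
  structure(list(dt = dt,
                 steps_trial = as.integer(steps_trial),
                 steps_intertrial = as.integer(steps_intertrial)),
            class = "integration_spec")
}

#' Circuit state constructor
#'
#' Instantaneous normalized firing rates of the five populations, each in
#' \[0, 1\]. Order: LA, BAf, BAe, CeAOn, CeAOff.
#'
#' @param u_la,u_baf,u_bae,u_on,u_off Rates in \[0, 1\] (default 0).
#' @return Named numeric vector of class `circuit_state`.
#' @export
circuit_state <- function(u_la = 0, u_baf = 0, u_bae = 0,
                          u_on = 0, u_off = 0) {
  u <- c(u_la = u_la, u_baf = u_baf, u_bae = u_bae,
         u_on = u_on, u_off = u_off)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("state components must lie in [0, 1]", call. = FALSE)
  structure(u, class = "circuit_state")
}

#' Input vector constructor
#'
#' External inputs to the circuit: thalamic CS rate (`i_thal`), hippocampal
#' context rate (`i_hip`), infralimbic-mPFC rate (`i_pfc`), each in
#' \[0, 1\], and the binary aversive US flag.
#'
#' @param i_thal,i_hip,i_pfc Input rates in \[0, 1\].
#' @param us US flag, 0 or 1.
#' @return Named numeric vector of class `input_vector`.
#' @export
input_vector <- function(i_thal = 0, i_hip = 0, i_pfc = 0, us = 0) {
  v <- c(i_thal = i_thal, i_hip = i_hip, i_pfc = i_pfc)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("input rates must lie in [0, 1]", call. = FALSE)
  if (!us %in% c(0, 1)) stop("`us` must be 0 or 1", call. = FALSE)
  structure(c(v, us = us), class = "input_vector")
}

# --- condition overlays ---------------------------------------------------

.acute_overrides <- list(w_ba_inhib = 0.25, w_la_inhib = 1.5,
                         w_baf_cea = 0.4, w_bae_cea = 0.6,
                         w_cea_inhib = 2.5)
.chronic_overrides <- list(w_cea_inhib = 2.5, dr_cea = -0.5,
                           w_la_baf = 0.6)

#' Alcohol condition overlay
#'
#' Returns the named set of parameter overrides representing a condition:
#' `"naive"` (no change), `"acute"` (raised BA/LA/CeA inhibition, reduced
#' BLA->CeA excitation) or `"chronic"` (raised CeA inhibition, negative CeA
#' drive, raised LA->BAf excitation).
#'
#' @param name One of `"naive"`, `"acute"`, `"chronic"`.
#' @return An object of class `condition_overlay` with elements `name` and
#'   `overrides` (a named list of `circuit_params` fields).
#' @export
condition_overlay <- function(name = c("naive", "acute", "chronic")) {
  name <- match.arg(name)
  overrides <- switch(name,
                      naive = list(),
                      acute = .acute_overrides,
                      chronic = .chronic_overrides)
  structure(list(name = name, overrides = overrides),
            class = "condition_overlay")
}

#' Apply a condition overlay to circuit parameters
#'
#' Replaces exactly the overlay's overridden fields; everything else is kept
#' from `base`.
#'
#' @param base A [circuit_params()] object.
#' @param overlay A [condition_overlay()] object, or a named list of
#'   overrides.
#' @return A new `circuit_params` object.
#' @export
apply_condition <- function(base, overlay) {
  stopifnot(inherits(base, "circuit_params"))
  overrides <- if (inherits(overlay, "condition_overlay"))
    overlay$overrides else overlay
  if (length(overrides) == 0L) return(base)
  valid <- setdiff(names(unclass(base)), "response")
  bad <- setdiff(names(overrides), valid)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- modifyList(unclass(base)[valid], overrides)
  args$response <- base$response
  do.call(circuit_params, args)
}
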