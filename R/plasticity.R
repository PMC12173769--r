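#' Plastic input weights
#'
#' The three input synapses trained by the conditioning protocol: thalamic
#' CS -> LA, hippocampal context -> BAf, and infralimbic mPFC -> BAe.  All
#' other weights are fixed in [circuit_params()].  The default initial
#' value 0.22 is the calibrated bootstrap strength; it keeps pre-training
#' activities low (about 0.06) while letting the Hebbian positive feedback
#' ignite on the observed timescale.
#'
#' @param w_thal_la,w_hip_baf,w_pfc_bae Non-negative weights.
#' @return Named numeric vector of class `plastic_weights`.
#' @export
plastic_weights <- function(w_thal_la = 0.22, w_hip_baf = 0.22,
                            w_pfc_bae = 0.22) {
  w <- c(w_thal_la = w_thal_la, w_hip_baf = w_hip_baf,
         w_pfc_bae = w_pfc_bae)
  if (any(!is.finite(w)) || any(w < 0))
    stop("plastic weights must be finite and non-negative", call. = FALSE)
  structure(w, class = "plastic_weights")
}

#' Learning-rate parameters
#'
#' @param alpha Plasticity rate constant (default 1).
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(alpha = 1) {
  stopifnot(is.finite(alpha), alpha >= 0)
  structure(list(alpha = alpha), class = "learning_params")
}

#' Prediction error
#'
#' The trial-end US prediction error: the actual US (0 or 1) minus the
#' CeAOn readout, the network's prediction of the shock.  Positive for an
#' unexpected shock, negative for an unexpected omission.
#'
#' @param us Binary US flag.
#' @param u_on_readout CeAOn readout in \[0, 1\].
#' @return Error in \[-1, 1\].
#' @export
prediction_error <- function(us, u_on_readout) {
  if (!us %in% c(0, 1)) stop("`us` must be 0 or 1", call. = FALSE)
  stopifnot(is.finite(u_on_readout), u_on_readout >= 0, u_on_readout <= 1)
  us - u_on_readout
}

#' Fear-pathway weight increment
#'
#' Hebbian, US-gated update for the thalamic->LA and hippocampal->BAf
#' synapses: the product of prediction error, US, learning rate, and the
#' pre- and postsynaptic rates.  It vanishes without a shock, so these
#' weights never change during extinction.
#'
#' @param err Prediction error.
#' @param us Binary US flag.
#' @param alpha Learning rate.
#' @param i_pre Presynaptic input rate in \[0, 1\].
#' @param u_post Postsynaptic rate in \[0, 1\].
#' @return The weight increment.
#' @export
fear_pathway_update <- function(err, us, alpha, i_pre, u_post) {
  stopifnot(is.finite(err), is.finite(alpha),
            i_pre >= 0, i_pre <= 1, u_post >= 0, u_post <= 1)
  err * us * alpha * i_pre * u_post
}

#' Extinction-pathway weight increment
#'
#' Update for the mPFC->BAe synapse: minus the prediction error times
#' learning rate and pre/postsynaptic rates.  Positive when the shock is
#' omitted but still predicted (err < 0), so extinction is learned by
#' potentiating this alternative pathway, not by depressing the fear
#' pathways.
#'
#' @inheritParams fear_pathway_update
#' @param i_pfc Presynaptic mPFC rate in \[0, 1\].
#' @param u_bae Postsynaptic BAe rate in \[0, 1\].
#' @return The weight increment.
#' @export
extinction_pathway_update <- function(err, alpha, i_pfc, u_bae) {
  stopifnot(is.finite(err), is.finite(alpha),
            i_pfc >= 0, i_pfc <= 1, u_bae >= 0, u_bae <= 1)
  -err * alpha * i_pfc * u_bae
}

#' Apply trial-end weight increments
#'
#' Adds the increments and floors each weight at zero (no synapse becomes
#' negative; the model has no depression rule).
#'
#' @param weights A [plastic_weights()] vector.
#' @param increments Named or positional numeric vector of length 3
#'   (thalamic->LA, hippocampal->BAf, mPFC->BAe).
#' @return Updated `plastic_weights`.
#' @export
apply_updates <- function(weights, increments) {
  stopifnot(inherits(weights, "plastic_weights"), length(increments) == 3L)
  w <- pmax(0, as.numeric(weights) + as.numeric(increments))
  structure(setNames(w, names(weights)), class = "plastic_weights")
}
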