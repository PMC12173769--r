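#' Sigmoidal response function parameters
#'
#' The neural response function is shared by all five populations:
#' \deqn{F(x) = \frac{1}{1 + e^{-\mathrm{gain}\,(x - \mathrm{threshold})}}}
#' `gain` is the excitability (slope) and `threshold` the activation
#' midpoint, in normalized net-input units (one unit of net input
#' corresponds to roughly 100 pA of synaptic current).
#'
#' @param gain Positive slope of the sigmoid (default 10).
#' @param threshold Activation midpoint in (0, 1) (default 0.5).
#' @return An object of class `response_params`.
#' @examples
#' rp <- response_params()
#' response(0.5, rp)  # 0.5 at the midpoint
#' @export
response_params <- function(gain = 10, threshold = 0.5) {
  stopifnot(is.numeric(gain), length(gain) == 1L, is.finite(gain), gain > 0,
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  structure(list(gain = gain, threshold = threshold),
            class = "response_params")
}

#' Sigmoidal population response
#'
#' Maps net synaptic input to a normalized firing rate in (0, 1).
#'
#' @param x Net input (numeric vector, finite).
#' @param params A [response_params()] object.
#' @return Firing rate(s) in (0, 1), strictly increasing in `x`.
#' @export
response <- function(x, params = response_params()) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("net input `x` must be finite numeric", call. = FALSE)
  1 / (1 + exp(-params$gain * (x - params$threshold)))
}
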