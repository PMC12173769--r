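#' Reduced two-variable CeA subsystem
#'
#' Freezes the BLA rates (LA, BAf, BAe) at given values and keeps only the
#' mutually inhibiting CeAOn / CeAOff pair as dynamical variables.  The
#' defaults are the naive late-extinction rates (BAf 0.15, BAe 0.9,
#' LA 0.8) with Table-style naive weights.
#'
#' @param u_baf,u_bae,u_la Frozen BLA rates in \[0, 1\].
#' @param params A [circuit_params()] supplying the CeA weights, drive,
#'   time constant and response function.
#' @return An object of class `reduced_system_spec`.
#' @export
reduced_system_spec <- function(u_baf = 0.15, u_bae = 0.9, u_la = 0.8,
                                params = circuit_params()) {
  u <- c(u_baf, u_bae, u_la)
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1))
    stop("frozen rates must lie in [0, 1]", call. = FALSE)
  stopifnot(inherits(params, "circuit_params"))
  structure(list(u_baf = u_baf, u_bae = u_bae, u_la = u_la,
                 w_baf_cea = params$w_baf_cea, w_la_cea = params$w_la_cea,
                 w_bae_cea = params$w_bae_cea,
                 w_cea_inhib = params$w_cea_inhib,
                 dr_cea = params$dr_cea, tau = params$tau,
                 response = params$response),
            class = "reduced_system_spec")
}

#' CeAOff nullcline
#'
#' The locus dU_Off/dt = 0: `u_off = F(w_bae_cea * u_bae -
#' w_cea_inhib * u_on + dr_cea)`.  Strictly decreasing in `u_on` whenever
#' the mutual inhibition is positive.
#'
#' @param u_on CeAOn value(s) in \[0, 1\].
#' @param spec A [reduced_system_spec()].
#' @return The CeAOff value(s) on the nullcline.
#' @export
off_nullcline <- function(u_on, spec) {
  stopifnot(inherits(spec, "reduced_system_spec"))
  response(spec$w_bae_cea * spec$u_bae - spec$w_cea_inhib * u_on +
             spec$dr_cea, spec$response)
}

#' CeAOn nullcline
#'
#' The locus dU_On/dt = 0: `u_on = F(w_baf_cea * u_baf + w_la_cea * u_la -
#' w_cea_inhib * u_off + dr_cea)`.
#'
#' @param u_off CeAOff value(s) in \[0, 1\].
#' @param spec A [reduced_system_spec()].
#' @return The CeAOn value(s) on the nullcline.
#' @export
on_nullcline <- function(u_off, spec) {
  stopifnot(inherits(spec, "reduced_system_spec"))
  response(spec$w_baf_cea * spec$u_baf + spec$w_la_cea * spec$u_la -
             spec$w_cea_inhib * u_off + spec$dr_cea, spec$response)
}

#' Equilibria of the reduced CeA subsystem
#'
#' Locates all intersections of the two nullclines by sign-change
#' bracketing of `g(u_on) = u_on - on_nullcline(off_nullcline(u_on))` on a
#' fine grid followed by bisection, and classifies stability from the
#' eigenvalues of the 2x2 Jacobian of the noise-free reduced vector field.
#'
#' @param spec A [reduced_system_spec()].
#' @param grid_n Number of grid points for bracketing (default 2000).
#' @param tol Root tolerance (default 1e-10).
#' @return A data.frame with columns `u_on`, `u_off`, `stable`.
#' @export
find_equilibria <- function(spec, grid_n = 2000, tol = 1e-10) {
  stopifnot(inherits(spec, "reduced_system_spec"))
  g <- function(u_on) u_on - on_nullcline(off_nullcline(u_on, spec), spec)
  xs <- seq(0, 1, length.out = grid_n)
  gs <- g(xs)
  roots <- xs[gs == 0]
  idx <- which(gs[-1] * gs[-grid_n] < 0)
  for (i in idx)
    roots <- c(roots, uniroot(g, c(xs[i], xs[i + 1]), tol = tol)$root)
  roots <- sort(unique(roots))
  if (length(roots) == 0L)
    return(data.frame(u_on = numeric(0), u_off = numeric(0),
                      stable = logical(0)))
  out <- do.call(rbind, lapply(roots, function(on) {
    off <- off_nullcline(on, spec)
    data.frame(u_on = on, u_off = off, stable = .reduced_stable(on, off, spec))
  }))
  rownames(out) <- NULL
  out
}

# Jacobian eigenvalue test; zero real parts are reported as unstable.
.reduced_stable <- function(u_on, u_off, spec) {
  gain <- spec$response$gain
  fp <- function(x) {
    f <- response(x, spec$response)
    gain * f * (1 - f)
  }
  a_on <- spec$w_baf_cea * spec$u_baf + spec$w_la_cea * spec$u_la -
    spec$w_cea_inhib * u_off + spec$dr_cea
  a_off <- spec$w_bae_cea * spec$u_bae - spec$w_cea_inhib * u_on +
    spec$dr_cea
  J <- matrix(c(-1, -fp(a_on) * spec$w_cea_inhib,
                -fp(a_off) * spec$w_cea_inhib, -1),
              2, 2, byrow = TRUE) / spec$tau
  all(Re(eigen(J, only.values = TRUE)$values) < 0)
}

#' Simulate the reduced CeA subsystem
#'
#' Clamped Euler integration of the two-variable system with the same
#' additive-in-F Gaussian noise model as the full circuit.
#'
#' @param spec A [reduced_system_spec()].
#' @param n_steps Number of Euler steps.
#' @param dt Step size in seconds (default 0.015).
#' @param noise A [noise_spec()].
#' @param init Initial `c(u_on, u_off)` (default both 0).
#' @param seed Optional RNG seed.
#' @return A data.frame with columns `step`, `u_on`, `u_off`.
#' @export
simulate_reduced <- function(spec, n_steps = 1000, dt = 0.015,
                             noise = noise_spec(), init = c(0, 0),
                             seed = NULL) {
  stopifnot(inherits(spec, "reduced_system_spec"), n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  on <- min(1, max(0, init[1])); off <- min(1, max(0, init[2]))
  a <- dt / spec$tau
  drive_on <- spec$w_baf_cea * spec$u_baf + spec$w_la_cea * spec$u_la +
    spec$dr_cea
  drive_off <- spec$w_bae_cea * spec$u_bae + spec$dr_cea
  out <- matrix(NA_real_, n_steps, 2)
  for (s in seq_len(n_steps)) {
    eta <- if (noise$enabled) rnorm(2, noise$mean, noise$sd) else c(0, 0)
    f_on <- response(drive_on - spec$w_cea_inhib * off + eta[1],
                     spec$response)
    f_off <- response(drive_off - spec$w_cea_inhib * on + eta[2],
                      spec$response)
    on <- min(1, max(0, on + a * (f_on - on)))
    off <- min(1, max(0, off + a * (f_off - off)))
    out[s, ] <- c(on, off)
  }
  data.frame(step = seq_len(n_steps), u_on = out[, 1], u_off = out[, 2])
}

#' Right-hand side of the extinction-robustness inequality
#'
#' Extinction is robust when the CeA mutual inhibition exceeds
#' `(w_baf_cea * u_baf + w_la_cea * u_la + dr_cea - threshold) / u_off`;
#' this function evaluates that right-hand side.  The margin
#' `w_cea_inhib - rhs` is positive in the extinction regime.  With the
#' naive weights at full activation (all rates 1) the value is 0.8.
#'
#' @param spec A [reduced_system_spec()] (supplies weights, drive and the
#'   response threshold).
#' @param u_baf,u_la,u_off Activation levels; `u_off` must be positive.
#' @return The right-hand-side value; `Inf` (with a warning) if
#'   `u_off == 0`, where extinction is unreachable.
#' @export
robustness_rhs <- function(spec, u_baf = 1, u_la = 1, u_off = 1) {
  stopifnot(inherits(spec, "reduced_system_spec"), u_off >= 0)
  num <- spec$w_baf_cea * u_baf + spec$w_la_cea * u_la + spec$dr_cea -
    spec$response$threshold
  if (u_off == 0) {
    warning("u_off = 0: extinction unreachable (infinite rhs)", call. = FALSE)
    return(Inf)
  }
  num / u_off
}

#' Harvest frozen BLA rates from a full simulation
#'
#' Averages the LA, BAf and BAe stimulus-period rates over the last
#' `window` extinction trials of a session (the settled late-extinction
#' levels), to supply condition-specific frozen rates for the reduced
#' subsystem.  For a naive session these reproduce the reference triple
#' (BAf ~0.15, BAe ~0.9, LA ~0.8).
#'
#' @param result A `session_result`.
#' @param window Number of trials to average (default 5).
#' @return A named list with `u_baf`, `u_bae`, `u_la`.
#' @export
harvest_frozen_rates <- function(result, window = 5) {
  ext <- result$records[result$records$phase == "extinction", ]
  stopifnot(nrow(ext) >= 1)
  rows <- ext[max(1, nrow(ext) - window + 1):nrow(ext), ]
  list(u_baf = mean(rows$u_baf), u_bae = mean(rows$u_bae),
       u_la = mean(rows$u_la))
}
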