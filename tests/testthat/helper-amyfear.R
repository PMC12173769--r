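# Shared helpers for the test suite.

# A session configuration with shorter trials (5 s stimulus, 2.5 s
# intertrial) for mechanics tests where absolute trial counts do not
# matter; the stability analysis shows the dynamics are insensitive to
# trial duration in this range.
fast_config <- function(condition = "naive", ...) {
  session_config(condition,
                 integration = integration_spec(dt = 0.015,
                                                steps_trial = 334,
                                                steps_intertrial = 167),
                 ...)
}

# Independent fixed-point oracle: damped Newton iteration on
# g(U) = F(net(U)) - U = 0 with a finite-difference Jacobian.  Shares no
# code path with the Euler integrator.
newton_fixed_point <- function(start, plastic, params, inputs,
                               tol = 1e-12, max_iter = 200) {
  g <- function(u) {
    st <- structure(setNames(pmin(1, pmax(0, u)),
                             c("u_la", "u_baf", "u_bae", "u_on", "u_off")),
                    class = "circuit_state")
    params$tau * derivatives(st, plastic, params, inputs)
  }
  u <- as.numeric(start)
  for (i in seq_len(max_iter)) {
    gu <- g(u)
    if (max(abs(gu)) < tol) break
    J <- matrix(0, 5, 5)
    h <- 1e-7
    for (k in 1:5) {
      up <- u; up[k] <- up[k] + h
      J[, k] <- (g(up) - gu) / h
    }
    step <- tryCatch(solve(J, -gu), error = function(e) -gu)
    # damping keeps the iterate in the unit cube
    lambda <- 1
    repeat {
      cand <- u + lambda * step
      if (all(cand >= -0.1 & cand <= 1.1) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    u <- pmin(1, pmax(0, u + lambda * step))
  }
  u
}

# Brute-force equilibrium search for the reduced CeA system: residual
# minimisation on an exhaustive 2-D grid, then local refinement.
grid_equilibria <- function(spec, res = 1e-3) {
  on <- seq(0, 1, by = res)
  off <- seq(0, 1, by = res)
  r_on <- outer(on, off, function(x, y) abs(on_nullcline(y, spec) - x))
  r_off <- outer(on, off, function(x, y) abs(off_nullcline(x, spec) - y))
  resid <- pmax(r_on, r_off)
  # local minima below grid tolerance
  hits <- which(resid < 2 * res, arr.ind = TRUE)
  if (nrow(hits) == 0) return(data.frame(u_on = numeric(0), u_off = numeric(0)))
  pts <- data.frame(u_on = on[hits[, 1]], u_off = off[hits[, 2]],
                    resid = resid[hits])
  # cluster nearby hits, keep the best per cluster
  pts <- pts[order(pts$resid), ]
  keep <- list()
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    dup <- any(vapply(keep, function(q)
      abs(q$u_on - p$u_on) < 0.05 && abs(q$u_off - p$u_off) < 0.05,
      logical(1)))
    if (!dup) keep[[length(keep) + 1]] <- p
  }
  out <- do.call(rbind, keep)
  out[order(out$u_on), c("u_on", "u_off")]
}
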