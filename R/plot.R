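#' Plot a session's trial-by-trial course
#'
#' Three stacked panels: (A) mean BLA activities (LA, BAf, BAe), (B) mean
#' CeA activities (CeAOn, CeAOff), (C) plastic synaptic weights, all per
#' trial, with the rest period shaded and the recall trial (first
#' extinction trial) marked by a dashed line.
#'
#' @param result A `session_result`.
#' @return A ggplot object (facetted panels).
#' @export
plot_session <- function(result) {
  stopifnot(inherits(result, "session_result"))
  rec <- result$records
  long <- rbind(
    data.frame(trial = rec$trial, panel = "A: BLA activity",
               series = rep(c("LA", "BAf", "BAe"), each = nrow(rec)),
               value = c(rec$u_la, rec$u_baf, rec$u_bae)),
    data.frame(trial = rec$trial, panel = "B: CeA activity",
               series = rep(c("CeAOn", "CeAOff"), each = nrow(rec)),
               value = c(rec$u_on, rec$u_off)),
    data.frame(trial = rec$trial, panel = "C: plastic weights",
               series = rep(c("Thal->LA", "Hip->BAf", "PFC->BAe"),
                            each = nrow(rec)),
               value = c(rec$w_thal_la, rec$w_hip_baf, rec$w_pfc_bae)))
  rest <- range(rec$trial[rec$phase == "rest"])
  recall <- min(rec$trial[rec$phase == "extinction"])
  p <- ggplot2::ggplot(long, ggplot2::aes(x = trial, y = value,
                                          colour = series))
  if (all(is.finite(rest)))
    p <- p + ggplot2::annotate("rect", xmin = rest[1] - 0.5,
                               xmax = rest[2] + 0.5, ymin = -Inf, ymax = Inf,
                               alpha = 0.15, fill = "grey40")
  if (is.finite(recall))
    p <- p + ggplot2::geom_vline(xintercept = recall, linetype = "dashed",
                                 colour = "grey30")
  p +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL, colour = NULL,
                  title = paste("Condition:", result$config$condition$name)) +
    ggplot2::theme_minimal()
}

#' Plot the reduced CeA phase plane
#'
#' Both nullclines, the located equilibria (solid = stable, open =
#' unstable) and, optionally, a noisy trajectory.
#'
#' @param spec A [reduced_system_spec()].
#' @param trajectory Optional data.frame from [simulate_reduced()].
#' @param n Points per nullcline (default 200).
#' @return A ggplot object.
#' @export
plot_phaseplane <- function(spec, trajectory = NULL, n = 200) {
  stopifnot(inherits(spec, "reduced_system_spec"))
  u <- seq(0, 1, length.out = n)
  nc <- rbind(
    data.frame(u_on = u, u_off = off_nullcline(u, spec),
               curve = "dU_Off/dt = 0"),
    data.frame(u_on = on_nullcline(u, spec), u_off = u,
               curve = "dU_On/dt = 0"))
  eq <- find_equilibria(spec)
  p <- ggplot2::ggplot(nc, ggplot2::aes(x = u_on, y = u_off)) +
    ggplot2::geom_path(ggplot2::aes(colour = curve), linewidth = 0.7)
  if (!is.null(trajectory))
    p <- p + ggplot2::geom_path(data = trajectory, colour = "grey55",
                                alpha = 0.7, linewidth = 0.3)
  if (nrow(eq))
    p <- p + ggplot2::geom_point(data = eq,
                                 ggplot2::aes(shape = stable),
                                 size = 3, colour = "black") +
      ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                  labels = c(`TRUE` = "stable",
                                             `FALSE` = "unstable"),
                                  name = NULL)
  p +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "U_CeAOn", y = "U_CeAOff", colour = NULL) +
    ggplot2::theme_minimal()
}
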