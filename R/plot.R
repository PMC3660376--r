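#' Plot a recorded trajectory
#'
#' Stacked base-graphics panels of population-mean copy number, elimination
#' coefficient and chromosome number against iteration.
#'
#' @param sim A `mac_sim` object or a summary data frame.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the summary data frame plotted.
#' @export
plot_trajectory <- function(sim, ...) {
  s <- if (inherits(sim, "mac_sim")) sim$summary else sim
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4.5, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$iteration, s$mean_X, type = "l", xlab = "iteration",
                 ylab = "mean copy number X", ...)
  graphics::plot(s$iteration, s$mean_E, type = "l", xlab = "iteration",
                 ylab = "mean elimination E", ylim = c(0, 1), ...)
  graphics::abline(h = 0.98, lty = 2, col = "grey50")
  graphics::plot(s$iteration, s$mean_N, type = "l", xlab = "iteration",
                 ylab = "mean chromosome number N", ...)
  invisible(s)
}
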