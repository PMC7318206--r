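#' Cost-effectiveness plane
#'
#' Scatter of replicate (incremental QALY, incremental cost) pairs from a
#' bootstrap or probabilistic sensitivity analysis, with the axes through
#' the origin and optional willingness-to-pay rays.
#'
#' @param replicates Data frame with `delta_cost` and `delta_qaly`
#'   columns ([bootstrap_cea()] output, or the `draws` element of a
#'   [run_psa()] result).
#' @param thresholds Willingness-to-pay thresholds drawn as rays through
#'   the origin (pounds per QALY); `NULL` for none.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `replicates`.
#' @export
plot_cep <- function(replicates, thresholds = c(20000, 30000), ...) {
  stopifnot(all(c("delta_cost", "delta_qaly") %in% names(replicates)))
  graphics::plot(replicates$delta_qaly, replicates$delta_cost,
    pch = 16, cex = 0.4, col = grDevices::adjustcolor("steelblue", 0.4),
    xlab = "Incremental QALYs", ylab = "Incremental cost (£)", ...
  )
  graphics::abline(h = 0, v = 0, col = "grey40")
  for (lambda in thresholds) {
    graphics::abline(a = 0, b = lambda, lty = 2, col = "grey60")
  }
  invisible(replicates)
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the intervention is cost-effective as a function of
#' the willingness-to-pay threshold, from a replicate cloud.
#'
#' @inheritParams plot_cep
#' @param threshold_grid Thresholds (pounds per QALY) at which the curve
#'   is evaluated.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, the data frame of the curve.
#' @export
plot_ceac <- function(replicates, threshold_grid = seq(0, 50000, by = 500), ...) {
  curve <- ceac(replicates, threshold_grid)
  graphics::plot(curve$threshold, curve$probability,
    type = "l", lwd = 2, col = "steelblue", ylim = c(0, 1),
    xlab = "Willingness to pay (£ per QALY)",
    ylab = "Probability cost-effective", ...
  )
  graphics::abline(h = c(0, 1), col = "grey80")
  invisible(curve)
}
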