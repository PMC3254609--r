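#' Raster plot of an activity trace
#'
#' PN activity (two glomeruli) above LN activity, one row per neuron, with
#' the stimulus schedule marked under the abscissa.
#'
#' @param x an `mgc_trace`.
#' @param ... unused.
#' @return invisibly, `x`.
#' @export
plot.mgc_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  pal <- grDevices::gray.colors(64, start = 1, end = 0)
  graphics::image(x$times, seq_len(nrow(x$pn)), t(x$pn),
    col = pal, zlim = c(0, 1),
    xlab = "", ylab = "PN", main = sprintf(
      "%s network, ratio %.2f", x$regime, x$stim$ratio
    )
  )
  graphics::abline(h = nrow(x$pn) / 2 + 0.5, col = "red", lty = 2)
  graphics::image(x$times, seq_len(nrow(x$ln)), t(x$ln),
    col = pal, zlim = c(0, 1), xlab = "time (ms)", ylab = "LN"
  )
  if (nrow(x$stim$pulses) > 0) {
    graphics::segments(x$stim$pulses[, 1], 0.6, x$stim$pulses[, 2], 0.6,
      lwd = 4, col = "blue"
    )
  }
  invisible(x)
}

#' Image plot of a correlation or classification map
#'
#' @param map matrix from [cross_correlation_map()] or
#'   [cross_classification_map()].
#' @param zlim colour range (default the map range).
#' @param main title.
#' @return invisibly, `map`.
#' @export
plot_response_map <- function(map, zlim = NULL, main = "") {
  tt_ref <- as.numeric(rownames(map))
  tt_test <- as.numeric(colnames(map))
  pal <- grDevices::hcl.colors(64, "viridis")
  graphics::image(tt_test, tt_ref, t(map),
    col = pal, zlim = zlim %||% range(map),
    xlab = "test time (ms)", ylab = "reference time (ms)", main = main
  )
  invisible(map)
}
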