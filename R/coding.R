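#' Bin PN activity into a response matrix
#'
#' Partitions the PN traces into contiguous time bins of `delta_t` ms and
#' averages each neuron's activity within each bin, producing the
#' `n_pn x n_bins` response matrix that is the unit of all downstream
#' analyses.  Bins are left-closed: the bin starting at time `b` averages
#' samples with `b <= t < b + delta_t`.
#'
#' @param trace an `mgc_trace` from [simulate_network()].
#' @param delta_t bin width in ms (default 10); must divide the window.
#' @param window `c(start, end)` in trace time (ms); default the whole trace.
#' @param neurons `"pn"` (default) or `"ln"`.
#' @return an object of class `mgc_response`: matrix `R`, `delta_t`,
#'   `bin_start` times (ms, trace clock), and `onset` (stimulus onset used
#'   for alignment; `NA` if the stimulus had no pulses).
#' @export
#' @examples
#' net <- build_network(network_spec("FPA", seed = 1))
#' tr <- simulate_network(net, make_pulse_train(0.4), sim_config(seed = 2))
#' resp <- bin_responses(tr)
#' dim(resp$R)
bin_responses <- function(trace, delta_t = 10, window = NULL,
                          neurons = c("pn", "ln")) {
  if (!inherits(trace, "mgc_trace")) stopf("`trace` must be an mgc_trace")
  neurons <- match.arg(neurons)
  act <- trace[[neurons]]
  tmax <- max(trace$times)
  window <- window %||% c(0, tmax)
  if (length(window) != 2 || window[1] < 0 || window[2] > tmax ||
      window[2] <= window[1]) {
    stopf("`window` must lie within the trace")
  }
  width <- window[2] - window[1]
  n_bins <- width / delta_t
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stopf("`delta_t` must divide the window width")
  }
  n_bins <- round(n_bins)
  bin_start <- window[1] + (seq_len(n_bins) - 1) * delta_t
  # sample index range per bin (left-closed, right-open)
  dt <- trace$config$dt
  R <- vapply(seq_len(n_bins), function(j) {
    keep <- trace$times >= bin_start[j] & trace$times < bin_start[j] + delta_t
    rowMeans(act[, keep, drop = FALSE])
  }, numeric(nrow(act)))
  dimnames(R) <- list(NULL, sprintf("%g", bin_start))
  structure(
    list(
      R = R, delta_t = delta_t, bin_start = bin_start,
      onset = trace$onset, neurons = neurons,
      ratio = trace$stim$ratio, regime = trace$regime
    ),
    class = "mgc_response"
  )
}

#' Pearson correlation between two spatial activity patterns
#'
#' The similarity measure between instantaneous population vectors.  A
#' zero-variance pattern (for example an all-silent pre-stimulus bin) has no
#' defined correlation; such pairs return 0 with attribute
#' `degenerate = TRUE` rather than failing, because response maps routinely
#' include silent bins.
#'
#' @param r,r2 numeric vectors of equal length.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
correlate_patterns <- function(r, r2) {
  if (length(r) != length(r2)) stopf("patterns must have equal length")
  if (stats::sd(r) == 0 || stats::sd(r2) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  stats::cor(r, r2)
}

#' Cross-correlation map between two response matrices
#'
#' Correlates every instantaneous spatial pattern (column) of a reference
#' response with every pattern of a test response.  `map[i, j]` is the
#' Pearson correlation between reference bin `i` and test bin `j`; rows
#' therefore index the reference stimulus (conventionally the single 500 ms
#' pulse) and columns the test stimulus.  Zero-variance bins contribute 0.
#'
#' @param r_ref,r_test `mgc_response` objects with the same PN dimension.
#' @return matrix of correlations with bin-start times as dimnames.
#' @seealso [average_maps()] for averaging over stimuli or networks.
#' @export
cross_correlation_map <- function(r_ref, r_test) {
  R1 <- r_ref$R
  R2 <- r_test$R
  if (nrow(R1) != nrow(R2)) stopf("responses must share the PN dimension")
  sd1 <- apply(R1, 2, stats::sd)
  sd2 <- apply(R2, 2, stats::sd)
  # cor() on matrices correlates columns: [ncol(R1) x ncol(R2)] = [ref x test]
  map <- suppressWarnings(stats::cor(R1, R2))
  map[sd1 == 0, ] <- 0
  map[, sd2 == 0] <- 0
  dimnames(map) <- list(colnames(R1), colnames(R2))
  attr(map, "delta_t") <- r_ref$delta_t
  map
}

#' Average a list of equally shaped maps
#'
#' Arithmetic mean of correlation or accuracy maps across stimuli or network
#' realizations.
#'
#' @param maps list of numeric matrices of identical dimension.
#' @return the elementwise mean matrix.
#' @export
average_maps <- function(maps) {
  if (!length(maps)) stopf("`maps` must be non-empty")
  Reduce(`+`, maps) / length(maps)
}

#' Flatten a response matrix into a spatiotemporal code vector
#'
#' Concatenates the binned PN patterns from stimulus onset up to
#' `code_length` ms into a single vector with one dimension per PN per bin.
#' Order is PN-major (PN index varies fastest within a bin), fixed so that
#' vectors are comparable across runs and invertible via
#' [unflatten_response()].
#'
#' @param resp an `mgc_response`.
#' @param code_length ms of response, measured from stimulus onset, to
#'   include; default all bins from onset to the end of the response.
#' @return numeric vector of length `n_pn * code_length / delta_t` with
#'   attributes `n_pn`, `delta_t` and `code_length`.
#' @export
flatten_response <- function(resp, code_length = NULL) {
  if (!inherits(resp, "mgc_response")) stopf("`resp` must be an mgc_response")
  onset <- if (is.na(resp$onset)) 0 else resp$onset
  rel <- resp$bin_start - onset
  code_length <- code_length %||% (max(rel) + resp$delta_t)
  keep <- rel >= 0 & rel < code_length
  if (!any(keep)) stopf("no bins fall inside the requested code length")
  v <- as.vector(resp$R[, keep, drop = FALSE])
  structure(v,
    n_pn = nrow(resp$R), delta_t = resp$delta_t,
    code_length = code_length
  )
}

#' Rebuild a response matrix from a flattened code vector
#'
#' @param v a vector from [flatten_response()], or any numeric vector.
#' @param n_pn number of PNs; default taken from the vector's attributes.
#' @return an `n_pn x n_bins` matrix.
#' @export
unflatten_response <- function(v, n_pn = NULL) {
  n_pn <- n_pn %||% attr(v, "n_pn")
  if (is.null(n_pn)) stopf("`n_pn` required to unflatten")
  if (length(v) %% n_pn != 0) stopf("length not divisible by `n_pn`")
  matrix(as.numeric(v), nrow = n_pn)
}

#' @export
print.mgc_response <- function(x, ...) {
  cat(sprintf(
    "Binned %s response: %d neurons x %d bins of %g ms (ratio %.3f, %s)\n",
    toupper(x$neurons), nrow(x$R), ncol(x$R), x$delta_t, x$ratio, x$regime
  ))
  invisible(x)
}
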