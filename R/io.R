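#' Write a network to a JSON archive
#'
#' Serializes every weight block as a named 2-D numeric array together with a
#' metadata header (spec echo, seed, regime), in a single JSON document.
#'
#' @param net an `mgc_network`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_network <- function(net, file) {
  doc <- list(
    meta = list(
      format = "mgcratio-network", version = 1L,
      regime = net$regime, seed = net$spec$seed,
      spec = unclass(net$spec)
    ),
    arrays = list(
      W_pn_pn = net$W_pn_pn, W_ln_pn = net$W_ln_pn,
      W_pn_ln = net$W_pn_ln, W_ln_ln = net$W_ln_ln,
      A_orn_pn = net$A_orn_pn, A_orn_ln = net$A_orn_ln
    ),
    glomerulus = net$glomerulus
  )
  jsonlite::write_json(doc, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' Read a network from a JSON archive
#'
#' @param file path written by [write_network()].
#' @return an `mgc_network`.
#' @export
read_network <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(doc$meta$format, "mgcratio-network")) {
    stopf("not an mgcratio network file")
  }
  sp <- doc$meta$spec
  spec <- network_spec(
    regime = sp$regime, seed = sp$seed,
    n_pn_per_glomerulus = sp$n_pn_per_glomerulus,
    n_glomeruli = sp$n_glomeruli, n_ln = sp$n_ln,
    p_pn_pn = sp$p_pn_pn, w_pn_pn = sp$w_pn_pn,
    p_ln_pn = sp$p_ln_pn, w_ln_pn = sp$w_ln_pn,
    p_pn_ln = sp$p_pn_ln, w_pn_ln = sp$w_pn_ln,
    p_ln_ln = sp$p_ln_ln, w_ln_ln = sp$w_ln_ln,
    w_orn = sp$w_orn, tau_pn = sp$tau_pn, tau_ln = sp$tau_ln
  )
  net <- lapply(doc$arrays, as.matrix)
  net$glomerulus <- doc$glomerulus
  net$regime <- spec$regime
  net$spec <- spec
  class(net) <- "mgc_network"
  validate_network(net)
  net
}

#' Write a stimulus program to JSON
#'
#' @param stim an `mgc_stimulus`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_stimulus <- function(stim, file) {
  jsonlite::write_json(
    list(
      format = "mgcratio-stimulus", ratio = stim$ratio,
      amplitude = stim$amplitude,
      pulses = as.data.frame(stim$pulses)
    ),
    file,
    digits = NA, auto_unbox = TRUE
  )
  invisible(file)
}

#' Read a stimulus program from JSON
#'
#' @param file path written by [write_stimulus()].
#' @return an `mgc_stimulus`.
#' @export
read_stimulus <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(doc$format, "mgcratio-stimulus")) {
    stopf("not an mgcratio stimulus file")
  }
  pulses <- as.matrix(doc$pulses)
  if (length(pulses) == 0) pulses <- matrix(numeric(0), 0, 2)
  stimulus_program(doc$ratio, pulses, doc$amplitude)
}

#' Export an activity trace as CSV
#'
#' One row per time sample; columns: time, the two input channels, then one
#' column per PN and per LN.
#'
#' @param trace an `mgc_trace`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trace_csv <- function(trace, file) {
  n_pn <- nrow(trace$pn)
  n_ln <- nrow(trace$ln)
  df <- data.frame(
    time_ms = trace$times,
    input1 = trace$input[1, ], input2 = trace$input[2, ],
    t(trace$pn), t(trace$ln)
  )
  names(df)[3 + seq_len(n_pn)] <- sprintf("pn%02d", seq_len(n_pn))
  names(df)[3 + n_pn + seq_len(n_ln)] <- sprintf("ln%02d", seq_len(n_ln))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Export a correlation or classification map as CSV with a JSON sidecar
#'
#' The CSV carries the map with reference-bin times as row names and
#' test-bin times as column headers; the sidecar (`<file>.json`) records
#' bin size, onset and any extra parameters supplied.
#'
#' @param map a matrix from [cross_correlation_map()] or
#'   [cross_classification_map()].
#' @param file output CSV path.
#' @param params named list of extra parameters for the sidecar.
#' @return `file`, invisibly.
#' @export
write_map_csv <- function(map, file, params = list()) {
  utils::write.csv(as.data.frame(map), file, row.names = TRUE)
  side <- c(
    list(
      delta_t = attr(map, "delta_t"),
      onset = attr(map, "onset"),
      nrow = nrow(map), ncol = ncol(map)
    ),
    params
  )
  jsonlite::write_json(side, paste0(file, ".json"),
    digits = NA,
    auto_unbox = TRUE
  )
  invisible(file)
}
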