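# Shared fixtures and a lazy cache for the expensive ensemble experiments,
# so the acceptance blocks that share simulated data compute it once.

.mgc_cache <- new.env(parent = emptyenv())

# run every expectation even when several study-level checks are red
if (requireNamespace("testthat", quietly = TRUE)) {
  try(testthat::set_max_fails(Inf), silent = TRUE)
}

cache_get <- function(key, builder) {
  if (!exists(key, envir = .mgc_cache)) {
    assign(key, builder(), envir = .mgc_cache)
  }
  get(key, envir = .mgc_cache)
}

# Full-scale decoding experiment per regime (the standard protocol: 20
# networks, 100 training / 400 test stimuli, 500 ms pulses); the LCA run
# also carries the bin-wise cross-classification map.
decoding_full <- function(regime) {
  cache_get(paste0("decode_", regime), function() {
    ratio_decoding_experiment(
      regime,
      code_lengths = c(20, 100, 200, 300, 400, 500),
      n_networks = 20, n_train = 100, n_test = 400,
      binwise_map = (regime == "LCA"),
      seed = if (regime == "FPA") 4001 else 4002
    )
  })
}

# Construct a synthetic activity trace object for detector/binning tests
# without running the simulator.
synthetic_trace <- function(pn, ln = NULL, dt = 1, onset = NA_real_) {
  ln <- ln %||% matrix(0, 30, ncol(pn))
  times <- (seq_len(ncol(pn)) - 1) * dt
  structure(
    list(
      times = times, pn = pn, ln = ln,
      input = matrix(0, 2, ncol(pn)), onset = onset,
      stim = stimulus_program(0.5, matrix(numeric(0), 0, 2)),
      config = sim_config(
        duration = max(times), dt = dt, pre_stimulus = 0,
        noise_enabled = FALSE
      ),
      regime = "FPA", network_seed = 0L
    ),
    class = "mgc_trace"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
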