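#' Rectified sigmoid squashing function
#'
#' The static nonlinearity of every model neuron: 0 for non-positive drive,
#' `tanh(gain * x)` for positive drive.  It bounds activity to `[0, 1)`,
#' gives a zero resting state, and is linear-like over the mid-range of
#' drives between non-activation and saturation.
#'
#' The default gain of 2 places typical stimulus-driven synaptic drives
#' (around 1) in the saturated region, the operating regime in which the
#' fixed-point attractor's spatial code loses fine ratio information at the
#' attractor while the limit-cycle attractor's spatiotemporal code retains
#' it — the characteristic contrast between the two wiring schemes.
#'
#' @param x numeric vector of synaptic drives.
#' @param gain slope at the origin from the right.
#' @return activations in `[0, 1)`.
#' @export
#' @examples
#' squash(c(-1, 0, 0.5, 50))
squash <- function(x, gain = mgc_default_gain) {
  tanh(gain * pmax(x, 0))
}

#' Simulation configuration
#'
#' Integration and noise settings for [simulate_network()].  Defaults follow
#' the model's standard conditions: 1 ms fixed-step 4th-order Runge-Kutta,
#' additive Gaussian state noise of sd `5e-4` applied after every step,
#' Gaussian initial activations (mean 0.01, sd 0.0025), and a 100 ms
#' pre-stimulus settling period before stimulus onset.
#'
#' @param duration total simulated time, ms.
#' @param dt integration step, ms (default 1).
#' @param pre_stimulus nominal settling time before stimulus onset, ms; used
#'   as the default alignment for response binning.
#' @param noise_sd,noise_mean Gaussian state-noise parameters per step.
#' @param noise_enabled logical; disable for bit-reproducible traces.
#' @param init_mean,init_sd Gaussian initial-condition parameters.
#' @param gain sigmoid gain passed to [squash()].
#' @param seed integer seed for initial conditions and noise.
#' @param init_seed,noise_seed optional separate seeds for the
#'   initial-condition and noise streams; when `NULL` both are drawn
#'   sequentially from the stream seeded by `seed`.
#' @return an object of class `mgc_sim_config`.
#' @export
sim_config <- function(duration = 700, dt = 1, pre_stimulus = 100,
                       noise_sd = 5e-4, noise_mean = 0, noise_enabled = TRUE,
                       init_mean = 0.01, init_sd = 0.0025,
                       gain = mgc_default_gain, seed = 1L,
                       init_seed = NULL, noise_seed = NULL) {
  if (dt <= 0) stopf("`dt` must be positive")
  if (duration < pre_stimulus) stopf("`duration` must cover `pre_stimulus`")
  if (noise_sd < 0 || init_sd < 0) stopf("standard deviations must be >= 0")
  structure(
    list(
      duration = duration, dt = dt, pre_stimulus = pre_stimulus,
      noise_sd = noise_sd, noise_mean = noise_mean,
      noise_enabled = isTRUE(noise_enabled),
      init_mean = init_mean, init_sd = init_sd, gain = gain,
      seed = as.integer(seed), init_seed = init_seed, noise_seed = noise_seed
    ),
    class = "mgc_sim_config"
  )
}

#' Integrate the firing-rate dynamics of an MGC network
#'
#' Solves `tau_i da_i/dt = -a_i + f(sum_j w_ij a_j + I_i(t))` for all 60
#' neurons with classical 4th-order Runge-Kutta at a fixed step, where `f` is
#' [squash()] and `I_i(t)` is the dot product of the two-channel stimulus
#' with the neuron's afferent weights.  After each step, Gaussian noise is
#' added to every activation (when enabled) and the state is clipped to
#' `[0, 1]`.
#'
#' @param net an `mgc_network` from [build_network()].
#' @param stim an `mgc_stimulus`.
#' @param cfg an [sim_config()].
#' @return an object of class `mgc_trace` with fields `times` (ms grid),
#'   `pn` (`n_pn x length(times)` activations), `ln` (same for LNs),
#'   `input` (`2 x length(times)` stimulus echo), `onset` (first pulse onset
#'   or `NA`), plus the stimulus and config.
#' @export
#' @examples
#' net <- build_network(network_spec("FPA", seed = 1))
#' stim <- make_pulse_train(0.5, onset = 100, pulse_ms = 200)
#' tr <- simulate_network(net, stim, sim_config(duration = 400, seed = 1))
simulate_network <- function(net, stim, cfg = sim_config()) {
  if (!inherits(net, "mgc_network")) stopf("`net` must be an mgc_network")
  if (!inherits(stim, "mgc_stimulus")) stopf("`stim` must be an mgc_stimulus")
  if (!inherits(cfg, "mgc_sim_config")) stopf("`cfg` must be a sim_config()")
  if (ncol(net$A_orn_pn) != 2) {
    stopf("simulation requires a 2-channel network")
  }

  n_pn <- nrow(net$W_pn_pn)
  n_ln <- nrow(net$W_ln_ln)
  n <- n_pn + n_ln
  W <- rbind(
    cbind(net$W_pn_pn, net$W_ln_pn),
    cbind(net$W_pn_ln, net$W_ln_ln)
  )
  A <- rbind(net$A_orn_pn, net$A_orn_ln)
  if (!all(is.finite(W)) || !all(is.finite(A))) {
    stopf("network weights must be finite")
  }
  tau <- c(rep(net$spec$tau_pn, n_pn), rep(net$spec$tau_ln, n_ln))

  nsteps <- round(cfg$duration / cfg$dt)

  draw_init <- function() pmin(pmax(rnorm(n, cfg$init_mean, cfg$init_sd), 0), 1)
  draw_noise <- function() {
    matrix(rnorm(n * nsteps, cfg$noise_mean, cfg$noise_sd), n, nsteps)
  }
  if (is.null(cfg$init_seed) && is.null(cfg$noise_seed)) {
    # one stream: initial conditions first, then the noise field
    dat <- with_seed(cfg$seed, {
      a0 <- draw_init()
      eps <- if (cfg$noise_enabled) draw_noise() else matrix(0, n, 0)
      list(a0 = a0, eps = eps)
    })
  } else {
    dat <- list(
      a0 = with_seed(cfg$init_seed %||% cfg$seed, draw_init()),
      eps = if (cfg$noise_enabled) {
        with_seed(cfg$noise_seed %||% cfg$seed, draw_noise())
      } else {
        matrix(0, n, 0)
      }
    )
  }

  act <- .sim_rk4_core(
    W, A, tau,
    as.numeric(stim$pulses[, 1]), as.numeric(stim$pulses[, 2]),
    stim$ratio * stim$amplitude, (1 - stim$ratio) * stim$amplitude,
    cfg$duration, cfg$dt, dat$a0, dat$eps, cfg$gain
  )

  times <- seq(0, cfg$duration, by = cfg$dt)
  structure(
    list(
      times = times,
      pn = act[seq_len(n_pn), , drop = FALSE],
      ln = act[n_pn + seq_len(n_ln), , drop = FALSE],
      input = stimulus_values(stim, times),
      onset = if (nrow(stim$pulses) > 0) stim$pulses[1, 1] else NA_real_,
      stim = stim, config = cfg,
      regime = net$regime, network_seed = net$spec$seed
    ),
    class = "mgc_trace"
  )
}

#' Simulate an ensemble of traces with provenance
#'
#' Runs every combination of network, stimulus and noise repeat, deriving an
#' independent noise seed for each `(network, stimulus, repeat)` triple from
#' the master seed, so the whole collection is reproducible and networks are
#' reused across noise realizations.
#'
#' @param networks a single `mgc_network` or a list of them.
#' @param stims a single `mgc_stimulus` or a list of them.
#' @param cfg an [sim_config()]; its seed fields are ignored in favour of
#'   seeds derived from `master_seed`.
#' @param n_repeats noise repeats per (network, stimulus) pair; 0 gives an
#'   empty collection.
#' @param master_seed integer master seed.
#' @return a list of `mgc_trace` objects, each carrying attributes
#'   `network_id`, `stim_id`, `repeat_id` and `noise_seed`.
#' @export
run_ensemble <- function(networks, stims, cfg = sim_config(),
                         n_repeats = 1, master_seed = 1L) {
  if (inherits(networks, "mgc_network")) networks <- list(networks)
  if (inherits(stims, "mgc_stimulus")) stims <- list(stims)
  if (n_repeats < 0 || n_repeats != round(n_repeats)) {
    stopf("`n_repeats` must be a non-negative integer")
  }
  out <- list()
  idx <- 0L
  for (i in seq_along(networks)) {
    for (j in seq_along(stims)) {
      for (k in seq_len(n_repeats)) {
        idx <- idx + 1L
        seed_ijk <- derive_seed(master_seed, idx)
        cfg_ijk <- cfg
        cfg_ijk$seed <- seed_ijk
        cfg_ijk$init_seed <- NULL
        cfg_ijk$noise_seed <- NULL
        tr <- simulate_network(networks[[i]], stims[[j]], cfg_ijk)
        attr(tr, "network_id") <- i
        attr(tr, "stim_id") <- j
        attr(tr, "repeat_id") <- k
        attr(tr, "noise_seed") <- seed_ijk
        out[[idx]] <- tr
      }
    }
  }
  out
}

#' @export
print.mgc_trace <- function(x, ...) {
  cat(sprintf(
    "MGC activity trace: %s network, %d PNs + %d LNs, %g ms at dt = %g ms\n",
    x$regime, nrow(x$pn), nrow(x$ln), max(x$times), x$config$dt
  ))
  cat(sprintf(
    "  stimulus: ratio %.3f, %d pulse(s); peak PN activity %.3f\n",
    x$stim$ratio, nrow(x$stim$pulses), max(x$pn)
  ))
  invisible(x)
}
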