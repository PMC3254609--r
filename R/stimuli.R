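#' Construct a blend-ratio stimulus program
#'
#' A stimulus program is a square-pulse schedule applied to both ORN input
#' channels simultaneously.  During a pulse the channels carry
#' `(ratio * amplitude, (1 - ratio) * amplitude)`; outside pulses both are
#' zero.  `ratio` is the proportion of the blend carried by channel 1, so
#' the channels always sum to `amplitude` during a pulse and the ratio alone
#' parameterizes the blend.
#'
#' @param ratio blend ratio in `[0, 1]` (proportion of channel 1).
#' @param pulses two-column matrix or data.frame of `(onset, offset)` times
#'   in ms; pulses must be time-ordered and non-overlapping.
#' @param amplitude total blend concentration (default 1).
#' @return an object of class `mgc_stimulus`.
#' @export
#' @examples
#' stim <- stimulus_program(0.5, cbind(100, 600))
stimulus_program <- function(ratio, pulses, amplitude = 1) {
  if (!is_prob(ratio)) stopf("`ratio` must lie in [0, 1]")
  if (length(amplitude) != 1 || amplitude < 0) stopf("`amplitude` must be >= 0")
  pulses <- as.matrix(pulses)
  if (length(pulses) == 0) {
    pulses <- matrix(numeric(0), 0, 2)
  }
  if (ncol(pulses) != 2) stopf("`pulses` must have columns (onset, offset)")
  colnames(pulses) <- c("onset", "offset")
  if (nrow(pulses) > 0) {
    if (any(pulses[, 2] <= pulses[, 1])) {
      stopf("every pulse must have offset > onset")
    }
    if (is.unsorted(pulses[, 1], strictly = TRUE) && nrow(pulses) > 1) {
      stopf("pulses must be in increasing time order")
    }
    if (nrow(pulses) > 1 &&
        any(pulses[-1, 1] < pulses[-nrow(pulses), 2])) {
      stopf("pulses must not overlap")
    }
  }
  structure(
    list(ratio = ratio, pulses = pulses, amplitude = amplitude),
    class = "mgc_stimulus"
  )
}

#' Periodic pulse-train stimulus
#'
#' `n_pulses` square pulses of `pulse_ms` each, separated by silent gaps of
#' `gap_ms`, starting at `onset` (default 100 ms, the standard pre-stimulus
#' settling period).
#'
#' @param ratio blend ratio in `[0, 1]`.
#' @param onset time of the first pulse onset, ms.
#' @param n_pulses number of pulses.
#' @param pulse_ms pulse duration, ms.
#' @param gap_ms inter-stimulus interval, ms.
#' @param amplitude total blend concentration.
#' @return an `mgc_stimulus`.
#' @export
#' @examples
#' # the plume-conflict schedules: five 50 ms pulses, 10/50/100 ms gaps
#' make_pulse_train(0.5, n_pulses = 5, pulse_ms = 50, gap_ms = 50)
make_pulse_train <- function(ratio, onset = 100, n_pulses = 1,
                             pulse_ms = 500, gap_ms = 0, amplitude = 1) {
  if (!is_count(n_pulses)) stopf("`n_pulses` must be a positive integer")
  if (pulse_ms <= 0 || gap_ms < 0 || onset < 0) {
    stopf("durations must be non-negative and pulses non-empty")
  }
  if (n_pulses > 1 && gap_ms == 0) {
    stopf("adjacent pulses with zero gap overlap; use a single longer pulse")
  }
  starts <- onset + (seq_len(n_pulses) - 1) * (pulse_ms + gap_ms)
  stimulus_program(ratio, cbind(starts, starts + pulse_ms), amplitude)
}

#' Random plume-like pulse train
#'
#' Generates a telegraph-style schedule mimicking the intermittent structure
#' of an odour plume: pulse onsets follow a renewal process with
#' exponentially distributed gaps (mean `1 / mean_rate` ms) and pulse
#' durations of `min_pulse_ms` plus an exponential excess with the same mean
#' as the minimum.  All pulses are at least `min_pulse_ms` long, the shortest
#' filament width considered realistic for natural plumes (about 40 ms).
#'
#' @param ratio blend ratio in `[0, 1]`.
#' @param span total schedule length in ms; pulses are truncated at `span`.
#' @param seed integer seed; the schedule is deterministic per seed.
#' @param min_pulse_ms minimum pulse duration, ms (default 40).
#' @param mean_rate pulse initiation rate in events/ms during silence
#'   (default 0.005, i.e. mean 200 ms between pulse trains); `mean_rate = 0`
#'   yields an empty schedule.
#' @param onset earliest allowed pulse onset, ms (default 100).
#' @param amplitude total blend concentration.
#' @return an `mgc_stimulus`.
#' @export
make_random_plume <- function(ratio, span, seed, min_pulse_ms = 40,
                              mean_rate = 0.005, onset = 100, amplitude = 1) {
  if (span <= 0) stopf("`span` must be positive")
  if (mean_rate < 0) stopf("`mean_rate` must be >= 0")
  pulses <- if (mean_rate == 0) {
    matrix(numeric(0), 0, 2)
  } else {
    with_seed(seed, {
      t <- onset
      out <- list()
      repeat {
        start <- t + rexp(1, rate = mean_rate)
        if (start >= span) break
        dur <- min_pulse_ms + rexp(1, rate = 1 / min_pulse_ms)
        end <- min(start + dur, span)
        if (end - start >= min_pulse_ms) out[[length(out) + 1]] <- c(start, end)
        t <- end
      }
      if (length(out)) do.call(rbind, out) else matrix(numeric(0), 0, 2)
    })
  }
  stimulus_program(ratio, pulses, amplitude)
}

#' Draw blend ratios uniformly from the unit interval
#'
#' @param n number of ratios.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
sample_ratios <- function(n, seed) {
  if (n < 0 || n != round(n)) stopf("`n` must be a non-negative integer")
  if (n == 0) return(numeric(0))
  with_seed(seed, runif(n))
}

#' Evaluate the two-channel input time series of a stimulus
#'
#' @param stim an `mgc_stimulus`.
#' @param times numeric vector of times in ms.
#' @return a `2 x length(times)` matrix: row 1 = channel 1, row 2 = channel 2.
#' @export
stimulus_values <- function(stim, times) {
  if (!inherits(stim, "mgc_stimulus")) stopf("`stim` must be an mgc_stimulus")
  on <- rep(FALSE, length(times))
  if (nrow(stim$pulses) > 0) {
    for (p in seq_len(nrow(stim$pulses))) {
      on <- on | (times >= stim$pulses[p, 1] & times < stim$pulses[p, 2])
    }
  }
  rbind(
    ifelse(on, stim$ratio * stim$amplitude, 0),
    ifelse(on, (1 - stim$ratio) * stim$amplitude, 0)
  )
}

#' Total stimulated time of a program
#' @param stim an `mgc_stimulus`.
#' @return total pulse duration in ms.
#' @export
stimulus_on_time <- function(stim) {
  if (nrow(stim$pulses) == 0) return(0)
  sum(stim$pulses[, 2] - stim$pulses[, 1])
}

#' @export
print.mgc_stimulus <- function(x, ...) {
  cat(sprintf(
    "Blend stimulus: ratio %.3f : %.3f, amplitude %g, %d pulse(s), %g ms on-time\n",
    x$ratio, 1 - x$ratio, x$amplitude, nrow(x$pulses), stimulus_on_time(x)
  ))
  if (nrow(x$pulses) > 0 && nrow(x$pulses) <= 10) {
    cat(paste(sprintf(
      "  [%g, %g) ms", x$pulses[, 1], x$pulses[, 2]
    ), collapse = "\n"), "\n")
  }
  invisible(x)
}
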