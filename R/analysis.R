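#' Build an ensemble of network realizations
#'
#' @param n number of realizations.
#' @param regime `"FPA"` or `"LCA"`.
#' @param seed master seed; each network gets a derived seed.
#' @param ... further arguments to [network_spec()].
#' @return list of `mgc_network` objects.
#' @export
mgc_networks <- function(n, regime, seed = 1L, ...) {
  lapply(seq_len(n), function(i) {
    build_network(network_spec(regime, seed = derive_seed(seed, i), ...))
  })
}

# ---------------------------------------------------------------------------
# Trajectory divergence timing (3-PC space, 5 ms bins)
# ---------------------------------------------------------------------------

#' Time of maximal divergence between ratio-specific PN trajectories
#'
#' For one network: simulates all `ratios` with `n_repeats` independent noise
#' realizations each, bins PN activity at `bin_ms`, projects all binned
#' patterns of the network into a common 3-dimensional principal-component
#' space, averages the trajectory of each ratio over repeats, and finds the
#' time (relative to stimulus onset) at which the mean pairwise Euclidean
#' distance between the ratio trajectories is maximal.
#'
#' @param net an `mgc_network`.
#' @param ratios blend ratios to compare (default the five class centres).
#' @param n_repeats noise repeats per ratio (default 20).
#' @param pulse_ms stimulus duration (default 500).
#' @param onset stimulus onset (default 100).
#' @param post_ms simulated time after stimulus offset (default 100).
#' @param bin_ms trajectory bin size (default 5).
#' @param seed master seed for the noise repeats.
#' @param n_pc number of principal components (default 3).
#' @param gain sigmoid gain forwarded to [sim_config()].
#' @return a list: `time_ms` (argmax time after onset, at the bin midpoint),
#'   `distance` (mean pairwise distance per bin), `bin_time` (bin midpoints
#'   relative to onset).
#' @export
trajectory_distance_timing <- function(net, ratios = c(0, 0.25, 0.5, 0.75, 1),
                                       n_repeats = 20, pulse_ms = 500,
                                       onset = 100, post_ms = 100,
                                       bin_ms = 5, seed = 1L, n_pc = 3, gain = mgc_default_gain) {
  if (length(ratios) < 2) stopf("at least two ratios are required")
  stims <- lapply(ratios, function(r) {
    make_pulse_train(r, onset = onset, pulse_ms = pulse_ms)
  })
  cfg <- sim_config(duration = onset + pulse_ms + post_ms, gain = gain)
  traces <- run_ensemble(net, stims, cfg,
    n_repeats = n_repeats,
    master_seed = seed
  )
  resp <- lapply(traces, bin_responses, delta_t = bin_ms)
  n_bins <- ncol(resp[[1]]$R)
  n_pn <- nrow(resp[[1]]$R)

  # common PC space for the network: pool every binned pattern
  pooled <- do.call(rbind, lapply(resp, function(r) t(r$R)))
  pca <- stats::prcomp(pooled, center = TRUE, scale. = FALSE, rank. = n_pc)

  # mean trajectory per ratio (repeat-averaged), then pairwise distances
  traj <- array(0, c(length(ratios), n_bins, n_pc))
  for (i in seq_along(resp)) {
    sid <- attr(traces[[i]], "stim_id")
    sc <- sweep(t(resp[[i]]$R), 2, pca$center) %*% pca$rotation
    traj[sid, , ] <- traj[sid, , ] + sc / n_repeats
  }
  pairs <- utils::combn(length(ratios), 2)
  dist_t <- vapply(seq_len(n_bins), function(b) {
    d <- apply(pairs, 2, function(p) {
      sqrt(sum((traj[p[1], b, ] - traj[p[2], b, ])^2))
    })
    mean(d)
  }, numeric(1))

  bin_mid <- resp[[1]]$bin_start + bin_ms / 2 - onset
  search <- bin_mid > 0
  if (max(dist_t[search]) < 1e-12) {
    stopf("ratio trajectories coincide; divergence time undefined")
  }
  best <- which(search)[which.max(dist_t[search])]
  list(
    time_ms = bin_mid[best],
    distance = dist_t,
    bin_time = bin_mid
  )
}

#' Trajectory divergence timing over an ensemble of networks
#'
#' @param regime `"FPA"` or `"LCA"`.
#' @param n_networks number of network realizations (default 20).
#' @param seed master seed (networks and noise derive from it).
#' @param ... forwarded to [trajectory_distance_timing()].
#' @return a list: `times_ms` per network, `mean_ms`, `sd_ms`.
#' @export
trajectory_timing_ensemble <- function(regime, n_networks = 20, seed = 1L,
                                       ...) {
  nets <- mgc_networks(n_networks, regime, seed = derive_seed(seed, 1))
  times <- vapply(seq_along(nets), function(i) {
    trajectory_distance_timing(nets[[i]],
      seed = derive_seed(seed, 1000 + i), ...
    )$time_ms
  }, numeric(1))
  list(times_ms = times, mean_ms = mean(times), sd_ms = stats::sd(times))
}

#' Welch t-test comparing divergence timing between regimes
#'
#' @param times_fpa,times_lca per-network timing vectors from
#'   [trajectory_timing_ensemble()].
#' @return the `htest` object from [stats::t.test()].
#' @export
compare_regime_timing <- function(times_fpa, times_lca) {
  stats::t.test(times_fpa, times_lca)
}

# ---------------------------------------------------------------------------
# Decoding experiments (Fig. 5 / Fig. 6c style)
# ---------------------------------------------------------------------------

# Simulate and bin one decoding dataset for a network: n_train + n_test
# stimuli with uniform random ratios, single pulse of pulse_ms.
decode_dataset <- function(net, n_train = 100, n_test = 400, pulse_ms = 500,
                           onset = 100, post_ms = 100, delta_t = 10,
                           seed = 1L, gain = mgc_default_gain) {
  cfg0 <- sim_config(duration = onset + pulse_ms + post_ms, gain = gain)
  ratios_train <- sample_ratios(n_train, derive_seed(seed, 1))
  ratios_test <- sample_ratios(n_test, derive_seed(seed, 2))
  sim_bin <- function(rho, noise_seed) {
    cfg <- cfg0
    cfg$seed <- noise_seed
    tr <- simulate_network(
      net, make_pulse_train(rho, onset = onset, pulse_ms = pulse_ms), cfg
    )
    bin_responses(tr, delta_t = delta_t)
  }
  train <- lapply(seq_len(n_train), function(i) {
    sim_bin(ratios_train[i], derive_seed(seed, 100000 + i))
  })
  test <- lapply(seq_len(n_test), function(i) {
    sim_bin(ratios_test[i], derive_seed(seed, 200000 + i))
  })
  list(
    train = stack_responses(train),
    test = if (n_test > 0) stack_responses(test) else NULL,
    train_ratios = ratios_train, test_ratios = ratios_test,
    train_labels = ratio_class(ratios_train),
    test_labels = ratio_class(ratios_test),
    onset = onset, delta_t = delta_t, pulse_ms = pulse_ms
  )
}

# Flatten a stacked response array to spatiotemporal vectors of a given
# code length (ms from onset): [n_stim, n_pn * n_kept_bins], PN-major.
flatten_stack <- function(arr, onset, code_length) {
  rel <- attr(arr, "bin_start") - onset
  keep <- which(rel >= 0 & rel < code_length)
  if (!length(keep)) stopf("code length shorter than one bin")
  sub <- arr[, , keep, drop = FALSE]
  dim(sub) <- c(dim(arr)[1], dim(arr)[2] * length(keep))
  sub
}

#' Decoding accuracy as a function of code length
#'
#' The reliability analysis: for each network, flattened spatiotemporal PN
#' vectors truncated to each code length are used to train the PCA (90%
#' variance) + linear-discriminant decoder on the training stimuli and score
#' it on the test stimuli.
#'
#' @param regime `"FPA"` or `"LCA"`, or a list of `mgc_network` objects.
#' @param code_lengths code lengths in ms (default 10–500).
#' @param n_networks networks when `regime` is a string (default 20).
#' @param n_train,n_test training/test stimuli per network (100 / 400).
#' @param pulse_ms,onset,post_ms,delta_t stimulus and binning geometry.
#' @param var_retained PCA variance fraction (default 0.9).
#' @param seed master seed.
#' @param gain sigmoid gain forwarded to [sim_config()].
#' @return a list: `accuracy` matrix `[network x code length]`, `mean`, `se`
#'   (across networks), and `code_lengths`.
#' @export
accuracy_vs_code_length <- function(regime, code_lengths = c(
                                      10, 20, 50, 100, 200, 300, 400, 500
                                    ),
                                    n_networks = 20, n_train = 100,
                                    n_test = 400, pulse_ms = 500, onset = 100,
                                    post_ms = 100, delta_t = 10,
                                    var_retained = 0.9, seed = 1L,
                                    gain = mgc_default_gain) {
  nets <- if (is.list(regime)) {
    regime
  } else {
    mgc_networks(n_networks, regime, seed = derive_seed(seed, 1))
  }
  acc <- matrix(NA_real_, length(nets), length(code_lengths))
  for (i in seq_along(nets)) {
    ds <- decode_dataset(nets[[i]],
      n_train = n_train, n_test = n_test,
      pulse_ms = pulse_ms, onset = onset, post_ms = post_ms,
      delta_t = delta_t, seed = derive_seed(seed, 5000 + i), gain = gain
    )
    for (l in seq_along(code_lengths)) {
      Xtr <- flatten_stack(ds$train, onset, code_lengths[l])
      Xte <- flatten_stack(ds$test, onset, code_lengths[l])
      fit <- fit_pca_lda(Xtr, ds$train_labels,
        var_retained = var_retained,
        seed = derive_seed(seed, 7000 + i)
      )
      acc[i, l] <- mean(predict(fit, Xte) == ds$test_labels)
    }
  }
  ms <- mean_se(acc)
  list(
    accuracy = acc, mean = ms$mean, se = ms$se,
    code_lengths = code_lengths
  )
}

#' Full ratio-decoding experiment for one regime
#'
#' Simulates the standard decoding protocol (100 training and 400 test
#' stimuli with uniform random ratios, 500 ms pulses) for an ensemble of
#' networks and computes, per network, (a) test accuracy of the flattened
#' spatiotemporal decoder at each code length and (b) optionally the
#' bin-wise cross-classification map.  Datasets are simulated once per
#' network and shared between the two analyses.
#'
#' @inheritParams accuracy_vs_code_length
#' @param binwise_map if `TRUE`, also compute the mean cross-classification
#'   map over networks.
#' @return a list: `accuracy`, `mean`, `se`, `code_lengths` as in
#'   [accuracy_vs_code_length()]; when `binwise_map` is `TRUE` also `map`
#'   (mean accuracy map over networks) and `diag_accuracy` (per network mean
#'   matched-bin accuracy during the stimulus, excluding the first 50 ms
#'   transient).
#' @export
ratio_decoding_experiment <- function(regime, code_lengths = c(
                                        10, 20, 50, 100, 200, 300, 400, 500
                                      ),
                                      n_networks = 20, n_train = 100,
                                      n_test = 400, pulse_ms = 500,
                                      onset = 100, post_ms = 100,
                                      delta_t = 10, var_retained = 0.9,
                                      binwise_map = FALSE, seed = 1L,
                                      gain = mgc_default_gain) {
  nets <- if (is.list(regime)) {
    regime
  } else {
    mgc_networks(n_networks, regime, seed = derive_seed(seed, 1))
  }
  acc <- matrix(NA_real_, length(nets), length(code_lengths))
  maps <- NULL
  diag_acc <- rep(NA_real_, length(nets))
  for (i in seq_along(nets)) {
    ds <- decode_dataset(nets[[i]],
      n_train = n_train, n_test = n_test,
      pulse_ms = pulse_ms, onset = onset, post_ms = post_ms,
      delta_t = delta_t, seed = derive_seed(seed, 5000 + i), gain = gain
    )
    for (l in seq_along(code_lengths)) {
      Xtr <- flatten_stack(ds$train, onset, code_lengths[l])
      Xte <- flatten_stack(ds$test, onset, code_lengths[l])
      fit <- fit_pca_lda(Xtr, ds$train_labels,
        var_retained = var_retained,
        seed = derive_seed(seed, 7000 + i)
      )
      acc[i, l] <- mean(predict(fit, Xte) == ds$test_labels)
    }
    if (binwise_map) {
      clf <- train_binwise(ds$train, ds$train_labels,
        var_retained = var_retained, seed = derive_seed(seed, 9000 + i)
      )
      map_i <- cross_classification_map(clf, ds$test, ds$test_labels)
      maps <- if (is.null(maps)) map_i else maps + map_i
      diag_acc[i] <- diagonal_accuracy(map_i,
        onset = onset,
        window = c(50, pulse_ms)
      )
    }
  }
  ms <- mean_se(acc)
  out <- list(
    accuracy = acc, mean = ms$mean, se = ms$se, code_lengths = code_lengths
  )
  if (binwise_map) {
    out$map <- maps / length(nets)
    out$diag_accuracy <- diag_acc
  }
  out
}

#' Mean matched-bin (diagonal) accuracy of a cross-classification map
#'
#' @param map a square accuracy map from [cross_classification_map()] with
#'   identical training and test binning.
#' @param onset stimulus onset in map time (default the map's `onset`
#'   attribute).
#' @param window `c(from, to)` in ms relative to onset over which diagonal
#'   bins are averaged (default 50–500 ms, excluding the onset transient).
#' @return mean accuracy over the selected diagonal bins.
#' @export
diagonal_accuracy <- function(map, onset = NULL, window = c(50, 500)) {
  onset <- onset %||% attr(map, "onset") %||% 0
  tt <- as.numeric(rownames(map)) - onset
  keep <- which(tt >= window[1] & tt < window[2])
  mean(map[cbind(keep, keep)])
}

#' Width of the high-correlation band around the map diagonal
#'
#' For each reference bin inside `window`, measures the temporal width of the
#' contiguous region around the diagonal where the correlation (or accuracy)
#' exceeds `threshold`.  Narrow bands indicate fast-switching spatiotemporal
#' codes; wide blocks indicate a stationary spatial code.
#'
#' @param map a square map with bin times as dimnames.
#' @param threshold band threshold (default 0.5).
#' @param onset stimulus onset (default the map attribute).
#' @param window `c(from, to)` ms relative to onset for the reference bins.
#' @return a list: `width_ms` per reference bin and `mean_width_ms`.
#' @export
diagonal_band_width <- function(map, threshold = 0.5, onset = NULL,
                                window = c(50, 500)) {
  onset <- onset %||% attr(map, "onset") %||% 0
  delta_t <- attr(map, "delta_t") %||%
    diff(as.numeric(rownames(map)))[1]
  tt <- as.numeric(rownames(map)) - onset
  keep <- which(tt >= window[1] & tt < window[2])
  widths <- vapply(keep, function(i) {
    above <- map[i, ] > threshold
    if (!above[i]) return(0)
    lo <- i
    while (lo > 1 && above[lo - 1]) lo <- lo - 1
    hi <- i
    while (hi < ncol(map) && above[hi + 1]) hi <- hi + 1
    (hi - lo + 1) * delta_t
  }, numeric(1))
  list(width_ms = widths, mean_width_ms = mean(widths))
}

# ---------------------------------------------------------------------------
# Ratio specificity: bell-curve width (second moment about the peak)
# ---------------------------------------------------------------------------

#' Bell-curve width of a ratio-correlation curve
#'
#' Correlating the spatiotemporal response for ratio `rho` against responses
#' to neighbouring ratios yields an approximately bell-shaped curve peaking
#' at 1 for `rho` itself.  Its width is summarized by the second moment of
#' the curve about the peak, taken over a window of half-width `half_width`
#' around `rho`; near the boundaries of `[0, 1]` the window is one-sided
#' (`rho < 0.25`: only ratios above `rho`; `rho > 0.75`: only below) so the
#' window never leaves the valid ratio range.  Negative correlations are
#' clipped to zero so they cannot act as negative weights.
#'
#' @param rho the reference ratio.
#' @param grid ratios at which the correlation curve is sampled.
#' @param corr correlation of the response at each `grid` ratio with the
#'   response at `rho`.
#' @param half_width window half-width (default 0.25).
#' @return the width `W >= 0` (units: squared ratio).
#' @export
#' @examples
#' g <- seq(0, 1, by = 0.025)
#' bell_curve_width(0.5, g, as.numeric(g == 0.5)) # all mass at the peak -> 0
bell_curve_width <- function(rho, grid, corr, half_width = 0.25) {
  if (length(grid) != length(corr)) stopf("`grid` and `corr` must match")
  lo <- if (rho < 0.25) rho else rho - half_width
  hi <- if (rho > 0.75) rho else rho + half_width
  keep <- grid >= lo - 1e-9 & grid <= hi + 1e-9
  if (sum(keep) < 2) stopf("ratio grid does not cover the window")
  w <- pmax(corr[keep], 0)
  if (sum(w) == 0) return(0)
  sum(w * (grid[keep] - rho)^2) / sum(w)
}

#' Ratio-specificity curve: mean bell-curve width vs code length
#'
#' For each network, simulates one noisy response per ratio on a dense grid,
#' flattens the spatiotemporal PN code to each requested code length,
#' correlates the response at every grid ratio with every other, and
#' computes the mean [bell_curve_width()] over grid ratios.  Small widths
#' mean high ratio specificity.
#'
#' @param regime `"FPA"` or `"LCA"`, or a list of networks.
#' @param code_lengths code lengths in ms.
#' @param n_networks networks when `regime` is a string.
#' @param ratio_grid grid of ratios (default step 0.025).
#' @param pulse_ms,onset,post_ms,delta_t stimulus and binning geometry.
#' @param seed master seed.
#' @param gain sigmoid gain forwarded to [sim_config()].
#' @return a list: `width` matrix `[network x code length]`, `mean`, `se`,
#'   `code_lengths`.
#' @export
specificity_curve <- function(regime, code_lengths = c(
                                10, 20, 50, 100, 200, 300, 400, 500
                              ),
                              n_networks = 20,
                              ratio_grid = seq(0, 1, by = 0.025),
                              pulse_ms = 500, onset = 100, post_ms = 100,
                              delta_t = 10, seed = 1L, gain = mgc_default_gain) {
  nets <- if (is.list(regime)) {
    regime
  } else {
    mgc_networks(n_networks, regime, seed = derive_seed(seed, 1))
  }
  W <- matrix(NA_real_, length(nets), length(code_lengths))
  cfg0 <- sim_config(duration = onset + pulse_ms + post_ms, gain = gain)
  for (i in seq_along(nets)) {
    resp <- lapply(seq_along(ratio_grid), function(g) {
      cfg <- cfg0
      cfg$seed <- derive_seed(seed, 3000 + i * length(ratio_grid) + g)
      tr <- simulate_network(
        nets[[i]],
        make_pulse_train(ratio_grid[g], onset = onset, pulse_ms = pulse_ms),
        cfg
      )
      bin_responses(tr, delta_t = delta_t)
    })
    arr <- stack_responses(resp)
    for (l in seq_along(code_lengths)) {
      X <- flatten_stack(arr, onset, code_lengths[l])
      C <- suppressWarnings(stats::cor(t(X)))
      C[!is.finite(C)] <- 0
      W[i, l] <- mean(vapply(seq_along(ratio_grid), function(g) {
        bell_curve_width(ratio_grid[g], ratio_grid, C[g, ])
      }, numeric(1)))
    }
  }
  ms <- mean_se(W)
  list(width = W, mean = ms$mean, se = ms$se, code_lengths = code_lengths)
}

#' Averaged cross-trial correlation map experiment
#'
#' The population-pattern similarity analysis: for each network and each of
#' `n_stimuli` random ratios, a reference response (single 500 ms pulse) and
#' a test response (either another independent 500 ms pulse trial or a train
#' of five 50 ms pulses with the given gap) are simulated with independent
#' noise, their binned PN patterns are cross-correlated over all bin pairs,
#' and the maps are averaged over stimuli and networks.
#'
#' @param regime `"FPA"` or `"LCA"`, or a list of networks.
#' @param gap_ms `NULL` for a single 500 ms test pulse (the autocorrelation
#'   layout), or an inter-stimulus interval in ms for a five-pulse 50 ms
#'   train.
#' @param n_networks networks when `regime` is a string.
#' @param n_stimuli random ratios per network.
#' @param pulse_ms reference pulse duration (default 500).
#' @param onset,post_ms,delta_t geometry as elsewhere.
#' @param seed master seed.
#' @param gain sigmoid gain forwarded to [sim_config()].
#' @return the averaged correlation map (reference bins x test bins) with
#'   attributes `delta_t` and `onset`.
#' @export
correlation_map_experiment <- function(regime, gap_ms = NULL, n_networks = 4,
                                       n_stimuli = 25, pulse_ms = 500,
                                       onset = 100, post_ms = 100,
                                       delta_t = 10, seed = 1L, gain = mgc_default_gain) {
  nets <- if (is.list(regime)) {
    regime
  } else {
    mgc_networks(n_networks, regime, seed = derive_seed(seed, 1))
  }
  ref_cfg <- sim_config(duration = onset + pulse_ms + post_ms, gain = gain)
  test_span <- if (is.null(gap_ms)) {
    pulse_ms
  } else {
    5 * 50 + 4 * gap_ms
  }
  test_cfg <- sim_config(duration = onset + test_span + post_ms, gain = gain)
  acc <- NULL
  k <- 0
  for (i in seq_along(nets)) {
    ratios <- sample_ratios(n_stimuli, derive_seed(seed, 400 + i))
    for (s in seq_len(n_stimuli)) {
      k <- k + 1
      rc <- ref_cfg
      rc$seed <- derive_seed(seed, 10000 + 2 * k)
      tc <- test_cfg
      tc$seed <- derive_seed(seed, 10000 + 2 * k + 1)
      ref_tr <- simulate_network(
        nets[[i]], make_pulse_train(ratios[s], onset = onset,
          pulse_ms = pulse_ms
        ), rc
      )
      test_stim <- if (is.null(gap_ms)) {
        make_pulse_train(ratios[s], onset = onset, pulse_ms = pulse_ms)
      } else {
        make_pulse_train(ratios[s],
          onset = onset, n_pulses = 5,
          pulse_ms = 50, gap_ms = gap_ms
        )
      }
      test_tr <- simulate_network(nets[[i]], test_stim, tc)
      m <- cross_correlation_map(
        bin_responses(ref_tr, delta_t = delta_t),
        bin_responses(test_tr, delta_t = delta_t)
      )
      acc <- if (is.null(acc)) m else acc + m
    }
  }
  avg <- acc / k
  attr(avg, "delta_t") <- delta_t
  attr(avg, "onset") <- onset
  avg
}

# ---------------------------------------------------------------------------
# Pulse-train interference (Fig. 4/5 b-d style)
# ---------------------------------------------------------------------------

#' Pulse-train interference experiment
#'
#' Trains the bin-wise decoder on single 500 ms pulse responses and tests it
#' on trains of five 50 ms pulses separated by `gap_ms` intervals.  Each test
#' pulse is scored against the training bins at the matching latency from
#' pulse onset (the first 50 ms of the long-pulse response), giving a
#' per-pulse accuracy: if a pulse restarts the network's response afresh,
#' accuracy matches the single-pulse case; if the tail of the previous
#' response interferes, accuracy drops.
#'
#' @param regime `"FPA"` or `"LCA"`, or a list of networks.
#' @param gap_ms inter-stimulus intervals to test (default 10, 50, 100).
#' @param n_networks networks when `regime` is a string.
#' @param n_train,n_test training / test stimuli per network.
#' @param pulse_ms duration of the five test pulses (default 50).
#' @param n_pulses number of pulses in the train (default 5).
#' @param train_pulse_ms duration of the single training pulse (default 500).
#' @param onset,delta_t geometry as elsewhere.
#' @param seed master seed.
#' @param gain sigmoid gain forwarded to [sim_config()].
#' @return a list: `accuracy` array `[network, gap, pulse]`, `mean` and `se`
#'   matrices `[gap x pulse]`, and the gap/pulse labels.
#' @export
interval_interference_experiment <- function(regime, gap_ms = c(10, 50, 100),
                                             n_networks = 4, n_train = 100,
                                             n_test = 100, pulse_ms = 50,
                                             n_pulses = 5,
                                             train_pulse_ms = 500,
                                             onset = 100, delta_t = 10,
                                             seed = 1L, gain = mgc_default_gain) {
  nets <- if (is.list(regime)) {
    regime
  } else {
    mgc_networks(n_networks, regime, seed = derive_seed(seed, 1))
  }
  acc <- array(
    NA_real_, c(length(nets), length(gap_ms), n_pulses),
    dimnames = list(NULL, sprintf("gap%g", gap_ms), NULL)
  )
  lag_bins <- seq(0, pulse_ms - delta_t, by = delta_t)
  for (i in seq_along(nets)) {
    ds <- decode_dataset(nets[[i]],
      n_train = n_train, n_test = 0,
      pulse_ms = train_pulse_ms, onset = onset, delta_t = delta_t,
      seed = derive_seed(seed, 5000 + i), gain = gain
    )
    clf <- train_binwise(ds$train, ds$train_labels,
      seed = derive_seed(seed, 9000 + i)
    )
    test_ratios <- sample_ratios(n_test, derive_seed(seed, 6000 + i))
    test_labels <- ratio_class(test_ratios)
    for (g in seq_along(gap_ms)) {
      span <- n_pulses * pulse_ms + (n_pulses - 1) * gap_ms[g]
      cfg0 <- sim_config(duration = onset + span + 100, gain = gain)
      resp <- lapply(seq_len(n_test), function(s) {
        cfg <- cfg0
        cfg$seed <- derive_seed(seed, 50000 + i * 1000 + g * 200 + s)
        tr <- simulate_network(
          nets[[i]],
          make_pulse_train(test_ratios[s],
            onset = onset, n_pulses = n_pulses,
            pulse_ms = pulse_ms, gap_ms = gap_ms[g]
          ),
          cfg
        )
        bin_responses(tr, delta_t = delta_t)
      })
      arr <- stack_responses(resp)
      map <- cross_classification_map(clf, arr, test_labels)
      train_t <- as.numeric(rownames(map))
      test_t <- as.numeric(colnames(map))
      for (p in seq_len(n_pulses)) {
        p_on <- onset + (p - 1) * (pulse_ms + gap_ms[g])
        cells <- vapply(lag_bins, function(lag) {
          map[
            match(onset + lag, train_t),
            match(p_on + lag, test_t)
          ]
        }, numeric(1))
        acc[i, g, p] <- mean(cells)
      }
    }
  }
  mean_gp <- apply(acc, c(2, 3), mean)
  se_gp <- apply(acc, c(2, 3), stats::sd) / sqrt(dim(acc)[1])
  list(
    accuracy = acc, mean = mean_gp, se = se_gp,
    gap_ms = gap_ms, pulses = seq_len(n_pulses)
  )
}

# ---------------------------------------------------------------------------
# Long-run attractor detection (stationarity / periodicity)
# ---------------------------------------------------------------------------

#' Detect the late attractor of a long simulation
#'
#' Classifies the late dynamics of a trace as a fixed point (every neuron's
#' activity stays within `tol` over the final `ref_window` ms), a periodic
#' orbit (the final window matches itself under some time shift up to
#' `max_period` ms), or neither.  Also estimates the settling time — the
#' last time, relative to stimulus onset, at which the trajectory is farther
#' than `tol` (root-mean-square across neurons) from the set of late states —
#' and counts the LNs still active at the end.
#'
#' The tolerance defaults to 0.05 activation units: comfortably above the
#' per-step noise floor (sd 5e-4), far below the order-one swings of
#' switching dynamics.
#'
#' @param trace an `mgc_trace`, typically several seconds long.
#' @param ref_window length of the final reference window, ms (default 1000).
#' @param tol tolerance in activation units (default 0.05).
#' @param max_period maximum period searched, ms (default 500).
#' @param sub_ms temporal subsampling for the settling-time search (default 5).
#' @param active_threshold LN mean activity over the final 200 ms counted as
#'   active (default 0.1).
#' @return a list: `type` (`"fixed_point"`, `"periodic"` or `"none"`),
#'   `period_ms` (`NA` unless periodic), `settle_ms` (relative to onset),
#'   `n_active_ln`.
#' @export
detect_attractor <- function(trace, ref_window = 1000, tol = 0.05,
                             max_period = 500, sub_ms = 5,
                             active_threshold = 0.1) {
  act <- rbind(trace$pn, trace$ln)
  times <- trace$times
  tmax <- max(times)
  ref_idx <- which(times > tmax - ref_window)
  ref <- act[, ref_idx, drop = FALSE]

  type <- "none"
  period <- NA_real_
  if (max(apply(ref, 1, function(x) diff(range(x)))) < tol) {
    type <- "fixed_point"
  } else {
    dt <- trace$config$dt
    lags <- seq(2 * sub_ms, max_period, by = sub_ms) / dt
    for (p in lags) {
      n <- ncol(ref) - p
      if (n < 100) break
      mismatch <- max(abs(ref[, seq_len(n) + p] - ref[, seq_len(n)]))
      if (mismatch < tol) {
        type <- "periodic"
        period <- p * dt
        break
      }
    }
  }

  # settling time: last excursion beyond tol (RMS across neurons) from the
  # late state set, measured on a sub_ms grid
  onset <- if (is.na(trace$onset)) 0 else trace$onset
  sub <- which(times %% sub_ms == 0)
  S <- act[, sub, drop = FALSE]
  Rf <- act[, ref_idx[ref_idx %in% sub], drop = FALSE]
  n_neuron <- nrow(act)
  # squared Euclidean distances via the crossprod expansion
  s2 <- colSums(S^2)
  r2 <- colSums(Rf^2)
  d2 <- outer(s2, r2, "+") - 2 * crossprod(S, Rf)
  dmin <- sqrt(pmax(apply(d2, 1, min), 0) / n_neuron)
  beyond <- which(dmin > tol & times[sub] >= onset)
  settle <- if (length(beyond)) times[sub][max(beyond)] + sub_ms - onset else 0

  late <- act[, times > tmax - 200, drop = FALSE]
  late_ln <- rowMeans(late[nrow(trace$pn) + seq_len(nrow(trace$ln)), ,
    drop = FALSE
  ])
  list(
    type = type, period_ms = period, settle_ms = settle,
    n_active_ln = sum(late_ln > active_threshold)
  )
}

#' Per-bin label-shuffled (chance) accuracy
#'
#' Utility for calibrating the decoder: shuffles the training labels
#' uniformly and reports test accuracy, which must sit at the chance rate
#' (20% for balanced five-class data).
#'
#' @param X_train,y_train training patterns and labels.
#' @param X_test,y_test test patterns and labels.
#' @param seed seed for the shuffle.
#' @return test accuracy under shuffled training labels.
#' @export
shuffled_accuracy <- function(X_train, y_train, X_test, y_test, seed = 1L) {
  y_shuf <- with_seed(seed, sample(y_train))
  fit <- fit_pca_lda(X_train, y_shuf, seed = derive_seed(seed, 1))
  mean(predict(fit, X_test) == y_test)
}
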