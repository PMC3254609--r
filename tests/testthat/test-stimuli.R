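test_that("pulse trains have exact square schedules", {
  # single 500 ms pulse at the standard onset
  stim <- make_pulse_train(0.5, onset = 100, pulse_ms = 500)
  g <- stimulus_values(stim, c(99, 100, 350, 599, 600))
  expect_equal(g[, 1], c(0, 0))
  expect_equal(g[, 2], c(0.5, 0.5))
  expect_equal(g[, 4], c(0.5, 0.5))
  expect_equal(g[, 5], c(0, 0))

  # five 50 ms pulses with 50 ms gaps: on-time and last offset by arithmetic
  tr5 <- make_pulse_train(0.3, onset = 100, n_pulses = 5, pulse_ms = 50,
                          gap_ms = 50)
  expect_equal(stimulus_on_time(tr5), 250)
  expect_equal(unname(tr5$pulses[5, 2]), 100 + 4 * 100 + 50)
  expect_equal(nrow(tr5$pulses), 5)
})

test_that("channel values decompose the amplitude by the blend ratio", {
  for (rho in c(0, 0.21, 0.5, 0.87, 1)) {
    stim <- make_pulse_train(rho, onset = 10, pulse_ms = 100, amplitude = 1)
    g <- stimulus_values(stim, 10:109)
    expect_true(all(abs(colSums(g) - 1) < 1e-12))
    expect_true(all(abs(g[1, ] - rho) < 1e-12))
  }
  # pure channel-1 stimulus leaves channel 2 silent everywhere
  stim <- make_pulse_train(1.0, onset = 0, n_pulses = 3, pulse_ms = 20,
                           gap_ms = 30)
  expect_true(all(stimulus_values(stim, 0:200)[2, ] == 0))
})

test_that("invalid schedules are rejected", {
  expect_error(stimulus_program(1.2, cbind(0, 10)), "\\[0, 1\\]")
  expect_error(stimulus_program(0.5, cbind(10, 5)), "offset > onset")
  expect_error(stimulus_program(0.5, rbind(c(0, 20), c(10, 30))), "overlap")
  expect_error(make_pulse_train(0.5, n_pulses = 2, gap_ms = 0), "overlap")
})

test_that("random plumes respect the minimum pulse width and the seed", {
  p1 <- make_random_plume(0.4, span = 5000, seed = 11, min_pulse_ms = 40)
  expect_gt(nrow(p1$pulses), 0)
  expect_true(all(p1$pulses[, 2] - p1$pulses[, 1] >= 40))
  p2 <- make_random_plume(0.4, span = 5000, seed = 11, min_pulse_ms = 40)
  expect_identical(p1$pulses, p2$pulses)
  p3 <- make_random_plume(0.4, span = 5000, seed = 12, min_pulse_ms = 40)
  expect_false(identical(p1$pulses, p3$pulses))
  # zero initiation rate: no pulses at all
  p0 <- make_random_plume(0.4, span = 5000, seed = 11, mean_rate = 0)
  expect_equal(nrow(p0$pulses), 0)
})

test_that("sampled ratios are uniform on [0, 1]", {
  r <- sample_ratios(400, seed = 21)
  expect_length(r, 400)
  expect_true(all(r >= 0 & r <= 1))
  expect_lt(abs(mean(r) - 0.5), 0.05) # 3 x sd of the mean of 400 uniforms
  expect_identical(r, sample_ratios(400, seed = 21))
  expect_length(sample_ratios(0, seed = 1), 0)

  # Kolmogorov-Smirnov distance below the 1% critical value at n = 10000
  big <- sort(sample_ratios(10000, seed = 22))
  ecdf_up <- seq_along(big) / 10000
  ecdf_lo <- (seq_along(big) - 1) / 10000
  d <- max(abs(ecdf_up - big), abs(big - ecdf_lo))
  expect_lt(d, 1.628 / sqrt(10000))
})

test_that("mean PN activity follows the pulse schedule in both regimes", {
  # activity during pulses must exceed activity during long gaps
  stim <- make_pulse_train(0.5, onset = 100, n_pulses = 3, pulse_ms = 100,
                           gap_ms = 100)
  for (regime in c("FPA", "LCA")) {
    net <- build_network(network_spec(regime, seed = 31))
    cfg <- sim_config(duration = 700)
    cfg$seed <- 99
    tr <- simulate_network(net, stim, cfg)
    on <- colSums(tr$input) > 0
    # skip the first 50 ms of each gap so return transients have faded
    gap <- !on & tr$times >= 150 &
      !(tr$times %in% unlist(lapply(tr$stim$pulses[, 2], function(o) o + 0:49)))
    expect_gt(mean(tr$pn[, on]), mean(tr$pn[, gap]))
  }
})
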