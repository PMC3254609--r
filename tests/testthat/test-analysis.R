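test_that("bell-curve width is the second moment about the peak", {
  g <- seq(0, 1, by = 0.025)
  # all mass at the peak: width 0
  expect_equal(bell_curve_width(0.5, g, as.numeric(g == 0.5)), 0)
  # flat curve: width equals the plain second moment of the window,
  # computed here independently as an explicit sum
  keep <- g >= 0.25 - 1e-9 & g <= 0.75 + 1e-9
  expect_equal(
    bell_curve_width(0.5, g, rep(1, length(g))),
    sum((g[keep] - 0.5)^2) / sum(keep)
  )
  # one-sided windows at the boundaries never leave [0, 1]
  w0 <- bell_curve_width(0.1, g, rep(1, length(g)))
  keep0 <- g >= 0.1 - 1e-9 & g <= 0.35 + 1e-9
  expect_equal(w0, sum((g[keep0] - 0.1)^2) / sum(keep0))
  w1 <- bell_curve_width(0.9, g, rep(1, length(g)))
  keep1 <- g >= 0.65 - 1e-9 & g <= 0.9 + 1e-9
  expect_equal(w1, sum((g[keep1] - 0.9)^2) / sum(keep1))
  # negative correlations cannot act as negative mass
  expect_gte(bell_curve_width(0.5, g, ifelse(g == 0.5, 1, -3)), 0)
  expect_error(bell_curve_width(0.5, g, rep(1, 3)), "match")
})

test_that("specificity curves are non-negative and seed-reproducible", {
  net <- build_network(network_spec("LCA", seed = 8))
  s1 <- specificity_curve(list(net),
    code_lengths = c(50, 200),
    ratio_grid = seq(0, 1, by = 0.1), seed = 5
  )
  s2 <- specificity_curve(list(net),
    code_lengths = c(50, 200),
    ratio_grid = seq(0, 1, by = 0.1), seed = 5
  )
  expect_true(all(s1$width >= 0))
  expect_identical(s1$width, s2$width)
})

test_that("diagonal statistics read maps correctly", {
  map <- matrix(0.1, 8, 8)
  diag(map) <- 0.95
  map[3, 4] <- map[4, 3] <- 0.9 # widen the band around bins 3-4
  rownames(map) <- colnames(map) <- sprintf("%d", seq(0, 70, by = 10))
  attr(map, "delta_t") <- 10
  expect_equal(
    diagonal_accuracy(map, onset = 0, window = c(0, 80)), 0.95
  )
  bw <- diagonal_band_width(map, 0.5, onset = 0, window = c(0, 80))
  expect_equal(bw$width_ms[1], 10)
  expect_equal(bw$width_ms[3], 20)
  expect_equal(bw$width_ms[4], 20)
})

test_that("the attractor detector recognizes fixed points and orbits", {
  # constant late state: fixed point, settled at the step change
  pn <- cbind(matrix(0.8, 30, 1000), matrix(0.3, 30, 2001))
  tr <- synthetic_trace(pn, onset = 0)
  det <- detect_attractor(tr, ref_window = 1000, tol = 0.05)
  expect_equal(det$type, "fixed_point")
  expect_lte(det$settle_ms, 1010)
  expect_gte(det$settle_ms, 990)

  # clean oscillation: periodic with the right period
  tt <- 0:3000
  pn <- 0.5 + 0.4 * outer(sin(seq(0, 3, length.out = 30)), sin(2 * pi * tt / 180))
  ln <- 0.5 + 0.4 * outer(cos(seq(0, 3, length.out = 30)), cos(2 * pi * tt / 180))
  tr <- synthetic_trace(pmax(pn, 0), ln = pmax(ln, 0), onset = 0)
  det <- detect_attractor(tr, ref_window = 1000, tol = 0.05, max_period = 400)
  expect_equal(det$type, "periodic")
  expect_equal(det$period_ms, 180)
})

test_that("trajectory timing requires at least two distinct ratios", {
  net <- build_network(network_spec("FPA", seed = 2))
  expect_error(
    trajectory_distance_timing(net, ratios = 0.5, n_repeats = 2),
    "two ratios"
  )
})

test_that("trajectory timing is reproducible and lies inside the trace", {
  net <- build_network(network_spec("LCA", seed = 5))
  r1 <- trajectory_distance_timing(net,
    ratios = c(0, 0.5, 1), n_repeats = 3,
    seed = 7
  )
  r2 <- trajectory_distance_timing(net,
    ratios = c(0, 0.5, 1), n_repeats = 3,
    seed = 7
  )
  expect_equal(r1$time_ms, r2$time_ms)
  expect_gt(r1$time_ms, 0)
  expect_lte(r1$time_ms, 600)
  expect_length(r1$distance, length(r1$bin_time))
  expect_true(all(r1$distance >= 0))
})

test_that("regime timing comparison returns a Welch t-test", {
  out <- compare_regime_timing(c(300, 350, 400), c(200, 220, 260))
  expect_s3_class(out, "htest")
  expect_true(is.finite(out$p.value))
})
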