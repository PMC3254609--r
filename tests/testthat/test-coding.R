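test_that("binning averages activity per bin and conserves the mean", {
  # constant trace: every entry equals the constant
  pn <- matrix(0.37, 30, 501)
  tr <- synthetic_trace(pn, onset = 100)
  resp <- bin_responses(tr, delta_t = 10, window = c(100, 500))
  expect_equal(dim(resp$R), c(30, 40))
  expect_true(all(abs(resp$R - 0.37) < 1e-15))

  # 500 ms window with 10 ms bins gives 50 columns
  resp2 <- bin_responses(tr, delta_t = 10, window = c(0, 500))
  expect_equal(ncol(resp2$R), 50)

  # binning conserves the mean over the window
  set.seed(4)
  pn <- matrix(runif(30 * 501), 30, 501)
  tr <- synthetic_trace(pn)
  resp3 <- bin_responses(tr, delta_t = 10, window = c(0, 500))
  expect_lt(abs(mean(resp3$R) - mean(pn[, 1:500])), 1e-12)
})

test_that("a linear ramp bins to its midpoint up to one sample edge", {
  ramp <- matrix(seq(0, 0.9, by = 0.1), 30, 10, byrow = TRUE)
  tr <- synthetic_trace(cbind(ramp, 0))
  resp <- bin_responses(tr, delta_t = 10, window = c(0, 10))
  # samples 0, 0.1, ..., 0.9 -> mean 0.45; midpoint 0.5; edge correction 0.05
  expect_equal(unname(resp$R[1, 1]), 0.45)
  expect_lt(abs(resp$R[1, 1] - 0.5), 0.1 / 2 + 1e-12)
})

test_that("binning rejects bad windows", {
  tr <- synthetic_trace(matrix(0, 30, 101))
  expect_error(bin_responses(tr, delta_t = 10, window = c(0, 200)), "within")
  expect_error(bin_responses(tr, delta_t = 7, window = c(0, 100)), "divide")
})

test_that("pattern correlation matches the textbook Pearson formula", {
  # independent oracle: explicit sum formula
  pearson <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt(sum(x^2) - n * mean(x)^2) * sqrt(sum(y^2) - n * mean(y)^2)
    num / den
  }
  set.seed(12)
  for (i in 1:1000) {
    x <- rnorm(30)
    y <- rnorm(30)
    expect_lt(abs(correlate_patterns(x, y) - pearson(x, y)), 1e-12)
  }
  x <- runif(30)
  expect_equal(as.numeric(correlate_patterns(x, x)), 1)
  expect_equal(as.numeric(correlate_patterns(x, -2 * x + 0.3)), -1)
})

test_that("zero-variance patterns yield a flagged zero, not an error", {
  z <- rep(0.2, 30)
  x <- runif(30)
  out <- correlate_patterns(z, x)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "degenerate"))
  expect_error(correlate_patterns(x, x[-1]), "equal length")
})

test_that("self cross-correlation maps are symmetric with unit diagonal", {
  set.seed(5)
  pn <- matrix(runif(30 * 301), 30, 301)
  tr <- synthetic_trace(pn, onset = 0)
  resp <- bin_responses(tr, delta_t = 10, window = c(0, 300))
  map <- cross_correlation_map(resp, resp)
  expect_equal(dim(map), c(30, 30))
  expect_true(all(abs(map - t(map)) < 1e-12))
  expect_true(all(abs(diag(map) - 1) < 1e-12))
})

test_that("silent bins contribute zero rows and columns to maps", {
  pn <- cbind(matrix(0, 30, 100), matrix(runif(30 * 101), 30, 101))
  tr <- synthetic_trace(pn, onset = 100)
  resp <- bin_responses(tr, delta_t = 10, window = c(0, 200))
  map <- cross_correlation_map(resp, resp)
  expect_true(all(map[1:10, ] == 0))
  expect_true(all(map[, 1:10] == 0))
})

test_that("flattening is PN-major and invertible", {
  set.seed(6)
  pn <- matrix(runif(30 * 201), 30, 201)
  tr <- synthetic_trace(pn, onset = 100)
  resp <- bin_responses(tr, delta_t = 10, window = c(0, 200))
  v <- flatten_response(resp, code_length = 50)
  expect_length(v, 30 * 5)
  # PN index varies fastest: the first 30 entries are the first kept bin
  onset_bin <- which(resp$bin_start == 100)
  expect_equal(v[1:30], unname(resp$R[, onset_bin]))
  back <- unflatten_response(v)
  expect_equal(back, unname(resp$R[, onset_bin + 0:4]))
  expect_error(unflatten_response(1:7, n_pn = 3), "divisible")
})

test_that("map averaging is the arithmetic mean", {
  m1 <- matrix(1, 2, 2)
  m2 <- matrix(3, 2, 2)
  expect_equal(average_maps(list(m1, m2)), matrix(2, 2, 2))
  expect_error(average_maps(list()), "non-empty")
})
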