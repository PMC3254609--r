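test_that("ratio classes partition [0, 1] with round-half-up boundaries", {
  expect_equal(as.character(ratio_class(0.30)), "0.25")
  expect_equal(as.character(ratio_class(0)), "0")
  expect_equal(as.character(ratio_class(1)), "1")
  expect_equal(as.character(ratio_class(0.125)), "0.25") # boundary, half-up
  expect_equal(as.character(ratio_class(0.375)), "0.5")
  expect_equal(as.character(ratio_class(0.1249)), "0")
  expect_error(ratio_class(1.01), "\\[0, 1\\]")
  expect_error(ratio_class(-0.1), "\\[0, 1\\]")
  # every ratio lands within half-width of its class centre
  r <- seq(0, 1, by = 0.001)
  centres <- ratio_classes()$centers[as.integer(ratio_class(r))]
  expect_true(all(abs(r - centres) <= 0.125 + 1e-12))
})

test_that("well-separated clusters are decoded perfectly", {
  # inter-mean distance 10x the within-class sd
  set.seed(31)
  centres <- matrix(rnorm(5 * 8), 5, 8) * 10
  y <- factor(rep(ratio_classes()$levels, each = 20),
    levels = ratio_classes()$levels
  )
  X <- centres[rep(1:5, each = 20), ] + matrix(rnorm(100 * 8), 100, 8)
  fit <- fit_pca_lda(X, y)
  expect_false(fit$uninformative)
  expect_gte(fit$explained_variance, 0.9)
  expect_equal(mean(predict(fit, X) == y), 1)
})

test_that("all-silent training bins give a chance-level classifier", {
  y <- factor(rep(ratio_classes()$levels, each = 20),
    levels = ratio_classes()$levels
  )
  fit <- fit_pca_lda(matrix(0, 100, 30), y, seed = 5)
  expect_true(fit$uninformative)
  pred <- predict(fit, matrix(0, 2000, 30))
  expect_identical(pred, predict(fit, matrix(1, 2000, 30))) # reproducible
  acc <- mean(pred == sample(rep(levels(y), each = 400)))
  expect_lt(abs(acc - 0.2), 3 * sqrt(0.2 * 0.8 / 2000))
})

test_that("degenerate training sets are rejected", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(fit_pca_lda(X, rep("a", 20)), "2 classes")
  expect_error(fit_pca_lda(X, c("a", rep("b", 19))), "2 samples")
})

test_that("the PCA+LDA pipeline matches the closed-form two-class rule", {
  # equal-covariance Gaussians: the Bayes/Fisher boundary is linear with
  # w = Sigma^-1 (mu1 - mu0); compare decisions on a grid of test points
  set.seed(77)
  mu0 <- c(-1, 0.5)
  mu1 <- c(1.2, -0.4)
  n <- 400
  X <- rbind(
    matrix(rnorm(2 * n, sd = 0.8), ncol = 2, byrow = TRUE) +
      matrix(mu0, n, 2, byrow = TRUE),
    matrix(rnorm(2 * n, sd = 0.8), ncol = 2, byrow = TRUE) +
      matrix(mu1, n, 2, byrow = TRUE)
  )
  y <- factor(rep(c("A", "B"), each = n))

  # oracle uses sample moments, pooled covariance, equal priors
  m0 <- colMeans(X[1:n, ])
  m1 <- colMeans(X[n + 1:n, ])
  S <- (stats::cov(X[1:n, ]) * (n - 1) +
    stats::cov(X[n + 1:n, ]) * (n - 1)) / (2 * n - 2)
  w <- solve(S, m1 - m0)
  b <- -0.5 * sum((m1 + m0) * w)
  grid <- as.matrix(expand.grid(
    seq(-3, 3, length.out = 40),
    seq(-3, 3, length.out = 40)
  ))
  oracle <- ifelse(grid %*% w + b > 0, "B", "A")

  fit <- fit_pca_lda(X, y, var_retained = 0.9999)
  pred <- as.character(predict(fit, grid))
  margin <- abs(grid %*% w + b)
  # decisions must agree except within a hair of the boundary
  expect_gt(mean(pred == oracle), 0.995)
  expect_true(all(pred[margin > 0.05] == oracle[margin > 0.05]))
})

test_that("bin-wise training yields one model per bin and maps score it", {
  set.seed(9)
  n_stim <- 60
  ratios <- sample_ratios(n_stim, seed = 14)
  y <- ratio_class(ratios)
  # synthetic responses: bins 1-2 silent, bins 3-6 encode the ratio linearly
  arr <- array(0, c(n_stim, 10, 6))
  for (s in seq_len(n_stim)) {
    for (b in 3:6) arr[s, , b] <- ratios[s] * seq(0.5, 1.4, length.out = 10) +
        rnorm(10, sd = 0.01)
  }
  attr(arr, "bin_start") <- seq(0, 50, by = 10)
  attr(arr, "delta_t") <- 10
  attr(arr, "onset") <- 0
  clf <- train_binwise(arr, y, seed = 2)
  expect_length(clf$fits, 6)
  expect_true(clf$fits[[1]]$uninformative)
  expect_false(clf$fits[[4]]$uninformative)
  map <- cross_classification_map(clf, arr, y)
  expect_equal(dim(map), c(6, 6))
  # informative (training bin, test bin) pairs decode far above chance
  expect_gt(mean(map[3:6, 3:6]), 0.8)
  # silent training bins stay near chance everywhere
  expect_lt(mean(map[1:2, ]), 0.35)
})

test_that("label shuffling drives the decoder to chance", {
  set.seed(41)
  n <- 200
  ratios <- rep(ratio_classes()$centers, each = n / 5)
  y <- ratio_class(ratios)
  X <- matrix(rnorm(n * 12), n, 12) +
    outer(ratios, seq_len(12)) # informative features
  acc <- shuffled_accuracy(X, y, X, y, seed = 3)
  expect_lt(abs(acc - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})
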