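#' The five blend-ratio classes
#'
#' Ratio stimuli are categorized into five groups centred at
#' 0, 0.25, 0.5, 0.75 and 1, each extending 0.125 either side, which
#' partitions `[0, 1]`.  Boundary values (0.125, 0.375, ...) are assigned to
#' the larger centre (round-half-up), a measure-zero convention fixed for
#' reproducibility.
#'
#' @return a list with `centers`, `half_width` and factor `levels`.
#' @export
ratio_classes <- function() {
  centers <- c(0, 0.25, 0.5, 0.75, 1)
  list(
    centers = centers, half_width = 0.125,
    levels = sprintf("%g", centers)
  )
}

#' Assign a blend ratio to its class
#'
#' @param rho numeric vector of ratios in `[0, 1]`.
#' @return a factor with levels `"0", "0.25", "0.5", "0.75", "1"`.
#' @export
#' @examples
#' ratio_class(c(0.3, 0, 0.125))
ratio_class <- function(rho) {
  if (any(rho < 0 | rho > 1 | !is.finite(rho))) {
    stopf("ratios must lie in [0, 1]")
  }
  cls <- ratio_classes()
  # round-half-up: boundaries go to the larger centre
  idx <- floor(rho / 0.25 + 0.5) + 1
  factor(cls$levels[idx], levels = cls$levels)
}

# ---- regularized linear discriminant fallback ------------------------------
# Plain LDA with a ridge term on the pooled within-class covariance, used
# when MASS::lda cannot invert the within-class scatter.
rlda_fit <- function(X, y, lambda = 1e-6) {
  X <- as.matrix(X)
  y <- droplevels(factor(y))
  lev <- levels(y)
  means <- t(vapply(lev, function(l) colMeans(X[y == l, , drop = FALSE]),
    numeric(ncol(X))
  ))
  S <- matrix(0, ncol(X), ncol(X))
  for (l in lev) {
    Xl <- X[y == l, , drop = FALSE]
    if (nrow(Xl) > 1) S <- S + crossprod(scale(Xl, center = TRUE, scale = FALSE))
  }
  S <- S / max(nrow(X) - length(lev), 1)
  S <- S + diag(lambda * max(mean(diag(S)), 1e-12), ncol(X))
  Sinv <- solve(S)
  prior <- as.numeric(table(y)) / length(y)
  list(means = means, Sinv = Sinv, prior = prior, levels = lev)
}

rlda_predict <- function(fit, X) {
  X <- as.matrix(X)
  # linear discriminant score: x' Sinv mu_k - mu_k' Sinv mu_k / 2 + log pi_k
  G <- X %*% fit$Sinv %*% t(fit$means)
  const <- -0.5 * rowSums((fit$means %*% fit$Sinv) * fit$means) +
    log(fit$prior)
  scores <- sweep(G, 2, const, "+")
  factor(fit$levels[max.col(scores)], levels = fit$levels)
}

#' Fit the PCA + linear-discriminant decoding pipeline
#'
#' The standard decoder applied throughout the analyses: principal component
#' analysis retaining the leading components that explain at least
#' `var_retained` of the variance (to remove redundant, linearly dependent
#' dimensions that would make the within-class covariance singular),
#' followed by linear discriminant analysis over the ratio classes.  PCA is
#' fit on the training set only; test patterns are projected with the
#' training loadings.
#'
#' If the within-class covariance is still singular after reduction the fit
#' degrades, with a warning, to a ridge-regularized discriminant.  Training
#' sets with (near-)zero total variance — e.g. all-silent pre-stimulus bins —
#' give an *uninformative* classifier whose predictions are uniform random
#' draws over the classes (seeded, hence reproducible), i.e. chance.
#'
#' @param X `n_samples x n_features` training matrix.
#' @param y class labels (factor or coercible).
#' @param var_retained minimum fraction of variance the kept components must
#'   explain (default 0.9).
#' @param seed seed used only by uninformative classifiers to draw chance
#'   predictions.
#' @return an object of class `mgc_pcalda` with elements `uninformative`,
#'   `n_components`, `explained_variance`.
#' @export
fit_pca_lda <- function(X, y, var_retained = 0.9, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  present <- droplevels(y)
  if (nrow(X) != length(y)) stopf("`X` rows must match `y`")

  total_var <- sum(apply(X, 2, stats::var))
  if (!is.finite(total_var) || total_var < 1e-20) {
    return(structure(
      list(
        uninformative = TRUE, levels = levels(y), seed = as.integer(seed),
        n_components = 0L, explained_variance = 0
      ),
      class = "mgc_pcalda"
    ))
  }
  if (nlevels(present) < 2) stopf("training requires at least 2 classes")
  if (any(table(present) < 2)) {
    stopf("training requires at least 2 samples per present class")
  }

  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vfrac <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- which(vfrac >= var_retained)[1]
  # guard against components of numerically zero variance
  k <- min(k, sum(pca$sdev^2 > 1e-12 * sum(pca$sdev^2)))
  k <- max(k, 1L)
  scores <- pca$x[, seq_len(k), drop = FALSE]

  model <- tryCatch(
    list(kind = "lda", fit = MASS::lda(scores, grouping = present)),
    error = function(e) {
      warning(
        "within-class covariance singular after reduction; ",
        "falling back to a regularized discriminant",
        call. = FALSE
      )
      list(kind = "rlda", fit = rlda_fit(scores, present))
    }
  )

  structure(
    list(
      uninformative = FALSE,
      center = pca$center,
      rotation = pca$rotation[, seq_len(k), drop = FALSE],
      n_components = k,
      explained_variance = vfrac[k],
      model = model,
      levels = levels(y),
      present_levels = levels(present),
      seed = as.integer(seed)
    ),
    class = "mgc_pcalda"
  )
}

#' @describeIn fit_pca_lda predict class labels for new patterns.
#' @param object an `mgc_pcalda` fit.
#' @param newdata `n_samples x n_features` matrix.
#' @param ... unused.
#' @export
predict.mgc_pcalda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$uninformative) {
    return(with_seed(
      object$seed,
      factor(sample(object$levels, nrow(newdata), replace = TRUE),
        levels = object$levels
      )
    ))
  }
  scores <- sweep(newdata, 2, object$center) %*% object$rotation
  pred <- if (object$model$kind == "lda") {
    stats::predict(object$model$fit, scores)$class
  } else {
    rlda_predict(object$model$fit, scores)
  }
  factor(as.character(pred), levels = object$levels)
}

# Stack a list of mgc_response objects into [n_stim, n_pn, n_bins]
stack_responses <- function(responses) {
  R1 <- responses[[1]]$R
  arr <- array(NA_real_, c(length(responses), nrow(R1), ncol(R1)))
  for (i in seq_along(responses)) arr[i, , ] <- responses[[i]]$R
  attr(arr, "bin_start") <- responses[[1]]$bin_start
  attr(arr, "delta_t") <- responses[[1]]$delta_t
  attr(arr, "onset") <- responses[[1]]$onset
  arr
}

#' Train one discriminant per time bin
#'
#' For every training time bin, fits the [fit_pca_lda()] decoder on the
#' instantaneous PN spatial patterns of all training stimuli at that bin.
#' The resulting bin-indexed family of classifiers is what the
#' cross-classification maps are built from: it lets a pattern observed at
#' any test time be decoded by the model trained at any training time.
#'
#' @param responses list of `mgc_response` objects (one per training
#'   stimulus) with identical binning, or a 3-D array
#'   `[n_stim, n_pn, n_bins]` from `stack_responses()`.
#' @param labels class labels, one per stimulus (factor or ratios via
#'   [ratio_class()]).
#' @param var_retained PCA variance fraction per bin (default 0.9).
#' @param seed seed forwarded to uninformative bins.
#' @return an object of class `mgc_binwise_classifier`.
#' @export
train_binwise <- function(responses, labels, var_retained = 0.9, seed = 1L) {
  arr <- if (is.array(responses) && length(dim(responses)) == 3) {
    responses
  } else {
    stack_responses(responses)
  }
  y <- if (is.numeric(labels)) ratio_class(labels) else factor(labels)
  if (dim(arr)[1] != length(y)) stopf("one label per training stimulus needed")
  n_bins <- dim(arr)[3]
  fits <- lapply(seq_len(n_bins), function(j) {
    fit_pca_lda(arr[, , j], y,
      var_retained = var_retained,
      seed = derive_seed(seed, j)
    )
  })
  structure(
    list(
      fits = fits,
      bin_start = attr(arr, "bin_start"),
      delta_t = attr(arr, "delta_t"),
      onset = attr(arr, "onset"),
      levels = levels(y),
      n_train = dim(arr)[1]
    ),
    class = "mgc_binwise_classifier"
  )
}

#' Cross-classification map: accuracy over (training bin, test bin)
#'
#' Applies every bin-trained discriminant to the test patterns of every test
#' bin.  `map[i, j]` is the fraction of test stimuli whose bin-`j` spatial
#' pattern is assigned its true ratio class by the model trained at bin `i`.
#' With five balanced classes the chance success rate is 20%.
#'
#' @param clf an `mgc_binwise_classifier`.
#' @param responses test responses (list of `mgc_response` or 3-D array).
#' @param labels true class labels (or numeric ratios).
#' @return accuracy matrix `[training bin x test bin]` with bin start times
#'   as dimnames, carrying attributes `delta_t` and `onset`.
#' @export
cross_classification_map <- function(clf, responses, labels) {
  if (!inherits(clf, "mgc_binwise_classifier")) {
    stopf("`clf` must come from train_binwise()")
  }
  arr <- if (is.array(responses) && length(dim(responses)) == 3) {
    responses
  } else {
    stack_responses(responses)
  }
  y <- if (is.numeric(labels)) ratio_class(labels) else factor(labels)
  n_stim <- dim(arr)[1]
  n_test_bins <- dim(arr)[3]
  # stack all test bins into one matrix so each bin-model predicts once
  X_all <- matrix(aperm(arr, c(1, 3, 2)), nrow = n_stim * n_test_bins)
  y_all <- rep(y, times = n_test_bins)
  map <- matrix(NA_real_, length(clf$fits), n_test_bins)
  for (i in seq_along(clf$fits)) {
    hit <- predict(clf$fits[[i]], X_all) == y_all
    map[i, ] <- colMeans(matrix(hit, nrow = n_stim))
  }
  dimnames(map) <- list(
    sprintf("%g", clf$bin_start),
    sprintf("%g", attr(arr, "bin_start"))
  )
  attr(map, "delta_t") <- clf$delta_t
  attr(map, "onset") <- clf$onset
  map
}

#' @export
print.mgc_binwise_classifier <- function(x, ...) {
  n_unin <- sum(vapply(x$fits, `[[`, logical(1), "uninformative"))
  cat(sprintf(
    "Bin-wise PCA+LDA classifier: %d bins of %g ms, %d training stimuli, %d classes\n",
    length(x$fits), x$delta_t, x$n_train, length(x$levels)
  ))
  cat(sprintf("  uninformative (silent) bins: %d\n", n_unin))
  invisible(x)
}
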