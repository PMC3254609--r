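#' Derive a reproducible child seed from a master seed
#'
#' Deterministically maps a (master seed, index) pair to an integer seed in
#' `[1, 2^31 - 2]` via a Lehmer-style multiplicative step.  Used throughout
#' the package so that ensembles of networks, stimuli and noise repeats each
#' get an independent, reproducible random stream from one master seed.
#'
#' @param master integer master seed.
#' @param index non-negative integer index of the child stream.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1, 1:3)
derive_seed <- function(master, index) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(master) %% m) + 1
  as.integer(((s * 48271 + as.numeric(index) * 16807) %% (m - 1)) + 1)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x > 0
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

# mean and standard error across the first dimension (rows = replicates)
mean_se <- function(x) {
  x <- as.matrix(x)
  list(
    mean = colMeans(x),
    se = apply(x, 2, stats::sd) / sqrt(nrow(x))
  )
}

# Default sigmoid gain of the model: calibrated once so that typical synaptic
# drives (~1) operate in the saturated region of the squashing function,
# which is the regime in which the two wiring schemes show their
# characteristic contrast in ratio-decoding performance.
mgc_default_gain <- 2
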