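#' Specify an MGC network configuration
#'
#' Collects all structural parameters of the macroglomerular-complex model:
#' neuron counts, connection probabilities, synaptic weight distributions
#' (given as `c(mean, sd)` of a normal distribution whose draws are
#' sign-rectified), membrane time constants and the LN-wiring regime.
#'
#' The two regimes share every parameter except the LN-to-LN wiring:
#' `"FPA"` (fixed-point attractor) uses all-to-all symmetric inhibition
#' between LNs (connection probability 1), `"LCA"` (limit-cycle attractor)
#' connects ordered LN pairs independently with probability 0.25, which makes
#' the inhibition asymmetric and prevents a long-term winner.
#'
#' @param regime `"FPA"` or `"LCA"`.
#' @param seed integer seed; a spec is a complete, reproducible recipe —
#'   [build_network()] is a pure function of the spec.
#' @param n_pn_per_glomerulus PNs per glomerulus (default 15).
#' @param n_glomeruli number of glomeruli / input channels (fixed at 2 for
#'   all analyses; the type tolerates other values).
#' @param n_ln number of local neurons (default 30).
#' @param p_pn_pn probability of a PN synapsing onto another PN of the same
#'   glomerulus (0.8).
#' @param w_pn_pn `c(mean, sd)` of PN-to-PN weights (0.0125, 0.1), negative
#'   draws rectified to 0.
#' @param p_ln_pn probability of an LN inhibiting any given PN (0.2).
#' @param w_ln_pn `c(mean, sd)` of LN-to-PN weights (-2.5, 0.1), positive
#'   draws rectified to 0.
#' @param p_pn_ln probability of a PN exciting any given LN (0.5).
#' @param w_pn_ln `c(mean, sd)` of PN-to-LN weights (0.033, 0.1).
#' @param p_ln_ln probability for ordered LN pairs; defaults to 1 for FPA and
#'   0.25 for LCA.
#' @param w_ln_ln `c(mean, sd)` of LN-to-LN weights (-15, 0.1).
#' @param w_orn `c(mean, sd)` of afferent ORN weights (1, 1), negative draws
#'   rectified to 0.
#' @param tau_pn,tau_ln membrane time constants in ms (10 and 20).
#' @return an object of class `mgc_network_spec`.
#' @seealso [build_network()]
#' @export
#' @examples
#' spec <- network_spec("FPA", seed = 1)
#' net <- build_network(spec)
network_spec <- function(regime = c("FPA", "LCA"), seed = 1L,
                         n_pn_per_glomerulus = 15L, n_glomeruli = 2L,
                         n_ln = 30L,
                         p_pn_pn = 0.8, w_pn_pn = c(0.0125, 0.1),
                         p_ln_pn = 0.2, w_ln_pn = c(-2.5, 0.1),
                         p_pn_ln = 0.5, w_pn_ln = c(0.033, 0.1),
                         p_ln_ln = NULL, w_ln_ln = c(-15, 0.1),
                         w_orn = c(1, 1),
                         tau_pn = 10, tau_ln = 20) {
  regime <- match.arg(regime)
  p_ln_ln <- p_ln_ln %||% if (regime == "FPA") 1.0 else 0.25

  for (nm in c("n_pn_per_glomerulus", "n_glomeruli", "n_ln")) {
    if (!is_count(get(nm))) stopf("`%s` must be a positive integer", nm)
  }
  for (nm in c("p_pn_pn", "p_ln_pn", "p_pn_ln", "p_ln_ln")) {
    if (!is_prob(get(nm))) stopf("`%s` must be a probability in [0, 1]", nm)
  }
  for (nm in c("w_pn_pn", "w_ln_pn", "w_pn_ln", "w_ln_ln", "w_orn")) {
    w <- get(nm)
    if (length(w) != 2 || !all(is.finite(w)) || w[2] < 0) {
      stopf("`%s` must be c(mean, sd) with sd >= 0", nm)
    }
  }
  if (!(length(tau_pn) == 1 && tau_pn > 0) ||
      !(length(tau_ln) == 1 && tau_ln > 0)) {
    stopf("time constants must be positive")
  }
  if (length(seed) != 1 || !is.finite(seed)) stopf("`seed` must be an integer")

  structure(
    list(
      regime = regime, seed = as.integer(seed),
      n_pn_per_glomerulus = as.integer(n_pn_per_glomerulus),
      n_glomeruli = as.integer(n_glomeruli), n_ln = as.integer(n_ln),
      p_pn_pn = p_pn_pn, w_pn_pn = w_pn_pn,
      p_ln_pn = p_ln_pn, w_ln_pn = w_ln_pn,
      p_pn_ln = p_pn_ln, w_pn_ln = w_pn_ln,
      p_ln_ln = p_ln_ln, w_ln_ln = w_ln_ln,
      w_orn = w_orn, tau_pn = tau_pn, tau_ln = tau_ln
    ),
    class = "mgc_network_spec"
  )
}

# One random weight block, drawn in a fixed order (row-major) so that
# identical seeds give identical blocks regardless of regime.  `sign` gives
# the rectification: "exc" clips negative draws to 0, "inh" clips positive
# draws to 0.
draw_block <- function(nrow, ncol, p, w, sign = c("exc", "inh")) {
  sign <- match.arg(sign)
  mask <- matrix(runif(nrow * ncol) < p, nrow, ncol, byrow = TRUE)
  wts <- matrix(rnorm(nrow * ncol, w[1], w[2]), nrow, ncol, byrow = TRUE)
  if (sign == "exc") wts[wts < 0] <- 0 else wts[wts > 0] <- 0
  wts * mask
}

#' Build a random MGC network realization
#'
#' Draws all synaptic weight blocks of the model from the distributions in
#' the spec.  Weight convention: `W[i, j]` is the influence of presynaptic
#' neuron `j` on postsynaptic neuron `i`.  Weights originating from PNs or
#' ORN channels are excitatory (negative draws rectified to 0); weights
#' originating from LNs are inhibitory (positive draws rectified to 0).
#'
#' Blocks are drawn in a fixed documented order — PN-to-PN, LN-to-PN,
#' PN-to-LN, ORN-to-PN, ORN-to-LN, and LN-to-LN last, each filled row-major —
#' so that FPA and LCA networks built from the same seed share every block
#' except the LN-to-LN wiring.  PN-to-PN connections exist only within a
#' glomerulus; PNs 1..15 belong to glomerulus/channel 1 and PNs 16..30 to
#' channel 2.  Each PN receives afferent input from exactly its own channel;
#' each LN from both channels.  No neuron synapses onto itself.
#'
#' @param spec an [network_spec()] object.
#' @return an object of class `mgc_network`: weight matrices `W_pn_pn`,
#'   `W_ln_pn`, `W_pn_ln`, `W_ln_ln`, afferent matrices `A_orn_pn`,
#'   `A_orn_ln`, the `glomerulus` assignment of each PN, `regime`, and the
#'   originating `spec`.
#' @export
#' @examples
#' net <- build_network(network_spec("LCA", seed = 7))
#' summarize_connectivity(net)
build_network <- function(spec) {
  if (!inherits(spec, "mgc_network_spec")) {
    stopf("`spec` must be created by network_spec()")
  }
  n_pn <- spec$n_pn_per_glomerulus * spec$n_glomeruli
  n_ln <- spec$n_ln
  glom <- rep(seq_len(spec$n_glomeruli), each = spec$n_pn_per_glomerulus)

  net <- with_seed(spec$seed, {
    W_pn_pn <- draw_block(n_pn, n_pn, spec$p_pn_pn, spec$w_pn_pn, "exc")
    # uniglomerular: remove cross-glomerulus entries and autapses
    same_glom <- outer(glom, glom, "==")
    W_pn_pn[!same_glom] <- 0
    diag(W_pn_pn) <- 0

    W_ln_pn <- draw_block(n_pn, n_ln, spec$p_ln_pn, spec$w_ln_pn, "inh")
    W_pn_ln <- draw_block(n_ln, n_pn, spec$p_pn_ln, spec$w_pn_ln, "exc")

    # each PN listens to exactly one ORN channel
    A_orn_pn <- matrix(0, n_pn, spec$n_glomeruli)
    a <- pmax(rnorm(n_pn, spec$w_orn[1], spec$w_orn[2]), 0)
    A_orn_pn[cbind(seq_len(n_pn), glom)] <- a
    # LNs listen to both channels
    A_orn_ln <- draw_block(n_ln, spec$n_glomeruli, 1.0, spec$w_orn, "exc")

    # LN-to-LN wiring drawn last: the only block that differs between regimes
    W_ln_ln <- draw_block(n_ln, n_ln, spec$p_ln_ln, spec$w_ln_ln, "inh")
    diag(W_ln_ln) <- 0

    list(
      W_pn_pn = W_pn_pn, W_ln_pn = W_ln_pn, W_pn_ln = W_pn_ln,
      W_ln_ln = W_ln_ln, A_orn_pn = A_orn_pn, A_orn_ln = A_orn_ln
    )
  })

  net$glomerulus <- glom
  net$regime <- spec$regime
  net$spec <- spec
  class(net) <- "mgc_network"
  validate_network(net)
  net
}

# internal invariant checks, run at build time
validate_network <- function(net) {
  spec <- net$spec
  if (any(net$W_pn_pn < 0) || any(net$W_pn_ln < 0) ||
      any(net$A_orn_pn < 0) || any(net$A_orn_ln < 0)) {
    stopf("excitatory blocks must be non-negative")
  }
  if (any(net$W_ln_pn > 0) || any(net$W_ln_ln > 0)) {
    stopf("inhibitory blocks must be non-positive")
  }
  if (any(diag(net$W_pn_pn) != 0) || any(diag(net$W_ln_ln) != 0)) {
    stopf("autapses are not allowed")
  }
  same_glom <- outer(net$glomerulus, net$glomerulus, "==")
  if (any(net$W_pn_pn[!same_glom] != 0)) {
    stopf("PN-to-PN connections must be uniglomerular")
  }
  if (any(rowSums(net$A_orn_pn != 0) > 1)) {
    stopf("each PN may receive at most one ORN channel")
  }
  if (spec$regime == "FPA") {
    off <- net$W_ln_ln[row(net$W_ln_ln) != col(net$W_ln_ln)]
    if (any(off == 0)) stopf("FPA LN wiring must be all-to-all")
  }
  invisible(net)
}

#' Summarize the connectivity of a network
#'
#' Per-block connection counts, densities, mean nonzero weights and sign
#' checks; used by tests and the command-line `inspect` entry point.
#'
#' @param net an `mgc_network`.
#' @return a `data.frame` with one row per weight block.
#' @export
summarize_connectivity <- function(net) {
  if (!inherits(net, "mgc_network")) stopf("`net` must be an mgc_network")
  block_row <- function(name, W, sign, off_diagonal = FALSE) {
    if (off_diagonal) {
      keep <- row(W) != col(W)
      vals <- W[keep]
    } else {
      vals <- as.vector(W)
    }
    nz <- vals != 0
    data.frame(
      block = name,
      n_possible = length(vals),
      n_nonzero = sum(nz),
      density = mean(nz),
      mean_nonzero = if (any(nz)) mean(vals[nz]) else NA_real_,
      sign_ok = if (sign == "exc") all(vals >= 0) else all(vals <= 0),
      stringsAsFactors = FALSE
    )
  }
  same_glom <- outer(net$glomerulus, net$glomerulus, "==")
  W_pp <- net$W_pn_pn
  W_pp_within <- W_pp[same_glom & row(W_pp) != col(W_pp)]
  out <- rbind(
    data.frame(
      block = "pn_pn", n_possible = length(W_pp_within),
      n_nonzero = sum(W_pp_within != 0), density = mean(W_pp_within != 0),
      mean_nonzero = if (any(W_pp_within != 0)) {
        mean(W_pp_within[W_pp_within != 0])
      } else NA_real_,
      sign_ok = all(net$W_pn_pn >= 0), stringsAsFactors = FALSE
    ),
    block_row("ln_pn", net$W_ln_pn, "inh"),
    block_row("pn_ln", net$W_pn_ln, "exc"),
    block_row("ln_ln", net$W_ln_ln, "inh", off_diagonal = TRUE),
    block_row("orn_pn", net$A_orn_pn, "exc"),
    block_row("orn_ln", net$A_orn_ln, "exc")
  )
  attr(out, "regime") <- net$regime
  out
}

#' @export
print.mgc_network_spec <- function(x, ...) {
  cat(sprintf(
    "MGC network spec: %s regime, seed %d\n  %d PNs (%d glomeruli x %d), %d LNs; tau_pn %g ms, tau_ln %g ms\n",
    x$regime, x$seed, x$n_pn_per_glomerulus * x$n_glomeruli, x$n_glomeruli,
    x$n_pn_per_glomerulus, x$n_ln, x$tau_pn, x$tau_ln
  ))
  cat(sprintf("  p(LN->LN) = %g\n", x$p_ln_ln))
  invisible(x)
}

#' @export
print.mgc_network <- function(x, ...) {
  cat(sprintf(
    "MGC network (%s, seed %d): %d PNs, %d LNs\n",
    x$regime, x$spec$seed, nrow(x$W_pn_pn), nrow(x$W_ln_ln)
  ))
  print(summarize_connectivity(x))
  invisible(x)
}
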