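#' Latency temporal coding of a potential column
#'
#' Converts a column of N neuron potentials into a latency code: each
#' neuron whose potential strictly exceeds the threshold `theta` receives
#' the code `T_window - m`, where `m` is the smallest suprathreshold
#' potential in the column; all other neurons receive 0. All firing
#' neurons within a column therefore share a common latency factor set by
#' the weakest suprathreshold input, and raising `theta` can only silence
#' entries, never create new ones. If no potential exceeds `theta` the
#' column is all zeros, and a potential exactly equal to `theta` does not
#' fire (strict inequality).
#'
#' The code is stored as the real-valued latency; downstream consumers
#' (weight updates, firing decisions) use its binarised view `code > 0`.
#'
#' @param p Numeric vector of N potentials (one column), all finite.
#' @param theta Spike-detection threshold, in the units of `p`.
#' @param T_window Coding time window, seconds (> 0).
#' @return Numeric vector of N nonnegative latency codes.
#' @examples
#' encode_latency(c(0.6, 0.4, 0.9), theta = 0.5, T_window = 10)  # 9.4 0 9.4
#' @export
encode_latency <- function(p, theta, T_window) {
  if (!is.numeric(p) || length(p) < 1L) stopf("`p` must be a numeric vector")
  if (!all(is.finite(p))) stopf("`p` contains non-finite potentials")
  check_scalar(theta, "theta")
  check_scalar(T_window, "T_window", positive = TRUE)
  fired <- p > theta
  if (!any(fired)) return(numeric(length(p)))
  m <- min(p[fired])
  ifelse(fired, T_window - m, 0)
}

#' Encode a potential matrix column by column
#'
#' Applies [encode_latency()] to every column of an N x n potential
#' matrix, yielding the N x n temporal-code matrix. Columns are treated
#' generically — a column may represent a time point or a sample; the
#' caller chooses the mapping.
#'
#' @param p_matrix Numeric N x n matrix of potentials.
#' @inheritParams encode_latency
#' @return N x n matrix of latency codes.
#' @export
encode_matrix <- function(p_matrix, theta, T_window) {
  p_matrix <- as.matrix(p_matrix)
  out <- vapply(seq_len(ncol(p_matrix)),
                function(j) encode_latency(p_matrix[, j], theta, T_window),
                numeric(nrow(p_matrix)))
  matrix(out, nrow(p_matrix), ncol(p_matrix),
         dimnames = dimnames(p_matrix))
}

#' Random initial weight matrix
#'
#' Synaptic weights are drawn independently and uniformly on \[-1, 1\],
#' the admissible range maintained by every subsequent update.
#'
#' @param N Neuron count (>= 1).
#' @param seed Integer seed; the draw is reproducible.
#' @return N x N numeric matrix with entries in \[-1, 1\].
#' @examples
#' W <- init_weights(10, seed = 42)
#' range(W)
#' @export
init_weights <- function(N, seed = 1L) {
  check_scalar(N, "N", positive = TRUE)
  if (N != round(N)) stopf("`N` must be an integer")
  N <- as.integer(N)
  with_seed(seed, matrix(stats::runif(N * N, -1, 1), N, N))
}

#' Hebbian co-activation weight update
#'
#' Unsupervised update capturing co-activation: for the binarised code
#' `b = (code > 0)`, the outer product `b %o% b` is added to the weights
#' scaled by the learning rate, the diagonal is held at its current value
#' (no self-reinforcement), and every entry is clipped back into
#' \[-1, 1\]. Neurons that fire together are thus pulled towards a
#' saturated +1 coupling; pairs that never co-fire keep their
#' initialisation.
#'
#' @param W N x N weight matrix with entries in \[-1, 1\].
#' @param code Length-N code column (real latencies or already binary).
#' @param learning_rate Nonnegative step size (default 0.1).
#' @return Updated N x N weight matrix, entries in \[-1, 1\], diagonal
#'   unchanged.
#' @examples
#' W <- matrix(0, 3, 3)
#' coactivation_update(W, c(1, 1, 0), learning_rate = 0.5)
#' @export
coactivation_update <- function(W, code, learning_rate = 0.1) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stopf("`W` must be square")
  if (length(code) != nrow(W)) {
    stopf("`code` length (%d) must match weight dimension (%d)",
          length(code), nrow(W))
  }
  check_scalar(learning_rate, "learning_rate", nonnegative = TRUE)
  b <- as.numeric(code > 0)
  d <- diag(W)
  W_new <- W + learning_rate * tcrossprod(b)
  diag(W_new) <- d
  W_new[W_new > 1] <- 1
  W_new[W_new < -1] <- -1
  W_new
}

#' Train weights over a sequence of code columns
#'
#' Applies [coactivation_update()] once per column of a code matrix, in
#' column order.
#'
#' @param W Initial N x N weight matrix.
#' @param codes N x n code matrix (columns are presentation steps).
#' @inheritParams coactivation_update
#' @return Final weight matrix after all updates.
#' @export
train_weights <- function(W, codes, learning_rate = 0.1) {
  codes <- as.matrix(codes)
  for (j in seq_len(ncol(codes))) {
    W <- coactivation_update(W, codes[, j], learning_rate)
  }
  W
}

#' Postsynaptic and post-postsynaptic connectivity indices
#'
#' Quantifies the excitatory drive a network delivers onto each neuron,
#' weighted by how active its presynaptic partners are. For activity
#' levels `a` in \[0, 1\]:
#' \deqn{PSI_j = \sum_i \max(W_{ij}, 0)\, a_i \ / \ \max(\sum_i a_i, \epsilon)}
#' is the first-order (direct) index; the second-order index PPI applies
#' the same formula to the two-step propagation matrix
#' `max(W,0) %*% max(W,0) / N`, i.e. excitatory influence arriving
#' through one intermediate neuron. Negative weights are rectified away —
#' both indices measure excitatory potency only — and both lie in
#' \[0, 1\]. With all-zero activity both indices are defined as 0.
#'
#' These index formulas are this package's concrete definition of the
#' verbal notions of first- and second-order connection potency; no
#' canonical formula exists for them.
#'
#' @param W N x N weight matrix, entries in \[-1, 1\].
#' @param mean_activity Length-N vector of per-neuron mean activity in
#'   \[0, 1\] (e.g. firing fraction over the coded columns).
#' @param eps Floor on the activity normaliser (default 1e-12).
#' @return List with numeric length-N vectors `psi` and `ppi`.
#' @examples
#' W <- matrix(0, 2, 2); W[1, 2] <- 1
#' psi_ppi(W, c(1, 0))$psi   # neuron 2 receives full drive
#' @export
psi_ppi <- function(W, mean_activity, eps = 1e-12) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stopf("`W` must be square")
  a <- as.numeric(mean_activity)
  if (length(a) != nrow(W)) stopf("`mean_activity` length must equal nrow(W)")
  if (any(a < 0 | a > 1)) stopf("`mean_activity` must lie in [0, 1]")
  if (all(a == 0)) {
    z <- numeric(nrow(W))
    return(list(psi = z, ppi = z))
  }
  P <- pmax(W, 0)
  denom <- max(sum(a), eps)
  psi <- as.numeric(crossprod(P, a)) / denom
  P2 <- (P %*% P) / nrow(W)
  ppi <- as.numeric(crossprod(P2, a)) / denom
  list(psi = psi, ppi = ppi)
}
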