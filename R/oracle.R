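#' Discrete cluster-level reference model
#'
#' The spiking model reduces, at the cluster level, to a simple assignment
#' chain: each of the C uniform-sampler clusters points at one of the 8
#' sensory bins, holding 1/C of the probability mass. At every observation of
#' a sample x, the momentarily active uniform cluster (a fresh uniform draw,
#' since the inter-sample interval is much longer than the switching period)
#' is reassigned to bin x. Spontaneous sampling maps i.i.d. uniform cluster
#' choices through the assignment. This abstraction is used as an independent
#' brute-force reference for learning, sampling, forgetting and decision
#' statistics.
#'
#' @param C Number of uniform clusters.
#' @param target Optional [bin_distribution()]; the initial assignment then
#'   encodes it by largest-remainder apportionment. Defaults to bin 1 for all
#'   clusters if missing.
#' @return An object of class `oracle_state`: integer vector of length C with
#'   the assigned bin per uniform cluster, attribute `n_bins`.
#' @export
oracle_state <- function(C, target = NULL, n_bins = 8) {
  stopifnot(C >= 1)
  if (is.null(target)) {
    assignment <- rep(1L, C)
  } else {
    target <- bin_distribution(target)
    n_bins <- length(target)
    counts <- largest_remainder(as.numeric(target) * C)
    assignment <- rep(seq_len(n_bins), times = counts)
  }
  structure(as.integer(assignment), n_bins = as.integer(n_bins),
            class = "oracle_state")
}

#' @rdname oracle_state
#' @param state An `oracle_state`.
#' @param x Observed bin index.
#' @export
oracle_observe <- function(state, x) {
  n_bins <- attr(state, "n_bins")
  stopifnot(x >= 1, x <= n_bins)
  active <- sample.int(length(state), 1)
  state[active] <- as.integer(x)
  state
}

#' @rdname oracle_state
#' @param xs Integer vector: a stream of observed samples.
#' @export
oracle_train <- function(state, xs) {
  active <- sample.int(length(state), length(xs), replace = TRUE)
  for (k in seq_along(xs)) state[active[k]] <- as.integer(xs[k])
  state
}

#' Distribution currently encoded by an oracle assignment
#'
#' @param state An [oracle_state()].
#' @return A [bin_distribution()] with the assignment fractions `n_k / C`.
#' @export
oracle_distribution <- function(state) {
  bin_distribution(tabulate(state, nbins = attr(state, "n_bins")) /
                     length(state))
}

#' Sample stream generated by an oracle assignment
#'
#' I.i.d. uniform cluster choices mapped through the assignment — the
#' cluster-level picture of spontaneous sampling, and the "rng" baseline used
#' to benchmark the KL-divergence of the spiking model.
#'
#' @param state An [oracle_state()].
#' @param n Number of samples.
#' @return Integer vector of bin labels.
#' @export
oracle_sample_stream <- function(state, n) {
  as.integer(state[sample.int(length(state), n, replace = TRUE)])
}

#' Monte-Carlo forgetting times of the assignment chain
#'
#' Number of observations until every uniform cluster has been reassigned at
#' least once (all memory of the previous distribution erased) — a coupon
#' collector problem with mean `C * H_C`.
#'
#' @param C Number of uniform clusters.
#' @param reps Monte-Carlo repetitions.
#' @return Integer vector of forgetting times (length `reps`).
#' @export
oracle_forgetting_time <- function(C, reps = 1000) {
  stopifnot(C >= 1)
  vapply(seq_len(reps), function(r) {
    seen <- logical(C)
    n <- 0L
    while (!all(seen)) {
      seen[sample.int(C, 1)] <- TRUE
      n <- n + 1L
    }
    n
  }, integer(1))
}

#' Closed-form psychometric curve of an ideal sampler
#'
#' For i.i.d. samples from p, the long-run decision output at half-integer
#' input i is `E[f(i, X)] = P(X < i) - P(X > i) = 2 F(i) - 1`.
#'
#' @param p A [bin_distribution()].
#' @param inputs Half-integer inputs.
#' @return Tibble with columns `input` and `r_expected`.
#' @export
oracle_psychometric <- function(p, inputs = seq(0.5, 8.5, by = 1)) {
  check_half_integer(inputs)
  tibble::tibble(input = inputs, r_expected = 2 * bin_cdf(p, inputs) - 1)
}
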