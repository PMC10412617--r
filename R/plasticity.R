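#' Eligibility trace for the Hebbian rule
#'
#' A neuron is eligible (`y = 1`) if it fired within the last `window` ms,
#' including a spike at exactly `t`.
#'
#' @param last_spike_times Last spike time per neuron (ms; `-Inf` if never).
#' @param t Current time (ms).
#' @param window Eligibility window (ms).
#' @return Numeric 0/1 vector.
#' @export
eligibility <- function(last_spike_times, t, window = 15) {
  stopifnot("last spike times cannot lie in the future" =
              all(last_spike_times <= t + 1e-9))
  as.numeric((t - last_spike_times) <= window + 1e-9)
}

#' One Euler step of the Hebbian + soft-normalization rule
#'
#' The plastic weight from presynaptic neuron j (uniform sampler) to
#' postsynaptic neuron i (sensory network) changes as
#'
#' `dW_ij/dt = A_p * y_i * y_j + (K - S_j) / tau_n`
#'
#' where `S_j` is neuron j's total outgoing plastic weight: the same scalar
#' deficit drives every outgoing weight of neuron j, so while a new
#' postsynaptic block is being potentiated, the previously potentiated block
#' is depressed by the surplus — the weight mass is re-attributed, not grown.
#' Weights are clipped to `[W_min, W_max]` after the step (entries at the
#' lower bound are unaffected by surplus-driven depression). A no-op when
#' `params$enabled` is `FALSE`.
#'
#' @param W Plastic weight matrix, `n_post x n_pre`.
#' @param y_post,y_pre Eligibility (0/1) vectors for the postsynaptic rows and
#'   presynaptic columns.
#' @param params [plasticity_params()]; `K_norm` must be resolved (non-NULL).
#' @param dt Time step (ms).
#' @return The updated weight matrix.
#' @export
hebb_norm_step <- function(W, y_post, y_pre, params, dt = 0.1) {
  if (!params$enabled) return(W)
  stopifnot(length(y_post) == nrow(W), length(y_pre) == ncol(W),
            !is.null(params$K_norm))
  dev <- params$K_norm - colSums(W)
  share <- dt * dev / params$tau_n
  # never move the column sum past K within one step (matters only for
  # coarse effective steps; a no-op at dt = 0.1 ms)
  n_eff <- ifelse(dev >= 0,
                  pmax(colSums(W < params$W_max - 1e-12), 1),
                  pmax(colSums(W > params$W_min + 1e-12), 1))
  share <- sign(share) * pmin(abs(share), abs(dev) / n_eff)
  W <- W + dt * params$A_p * tcrossprod(y_post, y_pre) +
    matrix(share, nrow(W), ncol(W), byrow = TRUE)
  W[W < params$W_min] <- params$W_min
  W[W > params$W_max] <- params$W_max
  W
}

#' One step of short-term plasticity on the read-out weights
#'
#' Each weight first relaxes toward baseline
#' (`w += dt * (baseline - w) / recovery_tau`), then every presynaptic spike
#' changes it multiplicatively: depression multiplies by
#' `1 - step_fraction` (floored at 0), facilitation by `1 + step_fraction`
#' (capped at `w_cap`).
#'
#' @param w_eff Effective read-out weight per presynaptic neuron (pF).
#' @param pre_spikes Logical/0-1 vector marking presynaptic spikes this step.
#' @param params [stp_params()].
#' @param dt Time step (ms).
#' @return Updated weight vector.
#' @export
stp_step <- function(w_eff, pre_spikes, params, dt = 0.1) {
  stopifnot(all(w_eff >= 0), length(pre_spikes) == length(w_eff))
  if (!params$enabled) return(w_eff)
  w <- w_eff + dt * (params$baseline - w_eff) / params$recovery_tau
  s <- as.logical(pre_spikes)
  if (params$mode == "depression") {
    w[s] <- pmax(0, w[s] * (1 - params$step_fraction))
  } else {
    w[s] <- pmin(params$w_cap, w[s] * (1 + params$step_fraction))
  }
  w
}

#' Decode the stored distribution from the plastic weights
#'
#' Sums all weights into each sensory cluster and divides by the total plastic
#' weight, giving the empirical distribution the network will sample from.
#' Accepts either the full `n_post x n_pre` matrix (rows grouped by sensory
#' cluster) or a cluster-block-sum matrix (`C x n_bins`, as stored in training
#' snapshots).
#'
#' @param W Plastic weight matrix or block-sum matrix.
#' @param n_bins Number of sensory clusters.
#' @return A [bin_distribution()] over the sensory bins.
#' @export
decode_weights <- function(W, n_bins = 8) {
  stopifnot(all(W >= 0))
  tot <- sum(W)
  if (tot <= 0) stop("cannot decode an all-zero weight matrix")
  if (ncol(W) == n_bins) {
    q <- colSums(W) / tot  # cluster-block-sum form (C x n_bins)
  } else if (nrow(W) %% n_bins == 0) {
    cl <- rep(seq_len(n_bins), each = nrow(W) / n_bins)
    q <- as.numeric(rowsum(rowSums(W), cl)) / tot
  } else {
    stop("weight matrix shape is not compatible with ", n_bins, " bins")
  }
  bin_distribution(q)
}
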