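# Small fixtures shared across the suite. Everything is generated in code;
# sizes are kept tiny so single tests run in seconds.

# A miniature two-network model (C uniform clusters of `npc` neurons).
tiny_model <- function(C = 4, npc = 10, seed = 1, target = NULL, ...) {
  if (is.null(target)) target <- bin_distribution(rep(1 / 8, 8))
  build_model(target, C = C, neurons_per_cluster = npc, seed = seed, ...)
}

# Decoded trace built directly from a label vector (dt in ms).
make_trace <- function(labels, dt = 0.1, n_clusters = max(labels)) {
  structure(tibble::tibble(t_ms = dt * seq_along(labels), label = labels),
            class = c("decoded_trace", "tbl_df", "tbl", "data.frame"),
            n_clusters = n_clusters, dt = dt)
}

# Cluster-block sums of a plastic matrix (n_bins x C).
block_sums <- function(W, n_bins, C) {
  npc_post <- nrow(W) / n_bins
  npc_pre <- ncol(W) / C
  rowsum(t(rowsum(W, rep(seq_len(n_bins), each = npc_post))),
         rep(seq_len(C), each = npc_pre))  # C x n_bins
}

# Deterministic external-drive override: every neuron receives `lam` expected
# counts per step (fractional counts are fine for the conductance path).
constant_drive <- function(model, n_steps, lam_E, lam_I = lam_E) {
  lapply(model$populations, function(pop) {
    n <- pop$n_E + pop$n_I
    matrix(rep(c(rep(lam_E, pop$n_E), rep(lam_I, pop$n_I)), n_steps),
           n, n_steps)
  })
}
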