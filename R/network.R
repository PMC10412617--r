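#' Build the clustered sub-networks
#'
#' The model consists of up to three sub-networks of AdEx excitatory and LIF
#' inhibitory neurons:
#'
#' * **uniform sampler** — `C` disjoint clusters of excitatory neurons plus a
#'   single inhibitory pool of `25 * C * (neurons_per_cluster / 100)` neurons.
#'   Lateral inhibition makes exactly one cluster transiently active at a
#'   time and strong spike-triggered adaptation (`beta = 100` pA) paces random
#'   switching, so cluster activations realize draws from a discrete uniform
#'   distribution with mass `1/C` each.
#' * **sensory** — 8 clusters encoding the discretized external variable,
#'   weak adaptation (`beta = 0.805` pA); switches are controlled by the
#'   plastic input from the uniform sampler.
#' * **read-out** — one unclustered balanced E/I network receiving dense
#'   input from all sensory excitatory neurons through short-term plastic
#'   weights.
#'
#' Connectivity is Bernoulli with probability `p_connect` and no
#' self-connections. Baseline synaptic strengths (pF) are scaled by
#' `f = sqrt(8 / C)` in the uniform sampler and `f = 1` elsewhere; existing
#' excitatory-to-excitatory connections within the same cluster are multiplied
#' by `10 * sqrt(C / 6)` in the uniform sampler and by 10 in the sensory
#' network.
#'
#' Networks built at reduced cluster size apply the same square-root scaling
#' rule used for network size elsewhere in the model: all recurrent weights
#' are multiplied by `w_scale = sqrt(100 / neurons_per_cluster)`, which keeps
#' the metastable switching regime intact at desk scale (`w_scale = 1` at the
#' full size of 100).
#'
#' @param C Number of clusters in the uniform sampler (>= 2).
#' @param neurons_per_cluster Excitatory neurons per cluster (100 at full
#'   scale; reduced sizes scale the inhibitory pools proportionally).
#' @param p_connect Connection probability.
#' @param w_EE,w_IE,w_EI,w_II Baseline synaptic strengths before scaling (pF):
#'   E to E, E to I, I to E, I to I.
#' @param drive External Poisson drive, see [external_drive()].
#' @param beta Spike-triggered adaptation increment (pA) for the excitatory
#'   neurons of this sub-network.
#' @param seed Integer seed for the connectivity draw.
#' @param w_scale Desk-scale weight compensation factor (see Details).
#' @return A `population` object: a list with the weight matrix `W`
#'   (post x pre, excitatory neurons first), cluster membership, sizes, and
#'   drive parameters.
#' @export
build_uniform_sampler <- function(C = 24, neurons_per_cluster = 100,
                                  p_connect = 0.2,
                                  w_EE = 5, w_IE = 5, w_EI = 175, w_II = 35,
                                  drive = external_drive(r_ext_E = 4.35),
                                  beta = 100, seed = 1L,
                                  w_scale = sqrt(100 / neurons_per_cluster)) {
  stopifnot("need at least two clusters" = C >= 2)
  f <- sqrt(8 / C) * w_scale
  build_population(
    name = "uniform", n_clusters = C, neurons_per_cluster = neurons_per_cluster,
    n_I = round(25 * C * neurons_per_cluster / 100),
    p_connect = p_connect,
    w = c(EE = w_EE, IE = w_IE, EI = w_EI, II = w_II) * f,
    within_factor = 10 * sqrt(C / 6),
    drive = drive, beta = beta, seed = seed
  )
}

#' @rdname build_uniform_sampler
#' @export
build_sensory <- function(neurons_per_cluster = 100, p_connect = 0.2,
                          w_EE = 5, w_IE = 5, w_EI = 175, w_II = 35,
                          drive = external_drive(r_ext_E = 4),
                          beta = 0.805, seed = 1L,
                          w_scale = sqrt(100 / neurons_per_cluster)) {
  build_population(
    name = "sensory", n_clusters = 8, neurons_per_cluster = neurons_per_cluster,
    n_I = round(200 * neurons_per_cluster / 100),
    p_connect = p_connect,
    w = c(EE = w_EE, IE = w_IE, EI = w_EI, II = w_II) * w_scale,
    within_factor = 10,
    drive = drive, beta = beta, seed = seed
  )
}

#' @rdname build_uniform_sampler
#' @export
build_readout <- function(neurons_per_cluster = 100, p_connect = 0.2,
                          w_EE = 5, w_IE = 5, w_EI = 175, w_II = 35,
                          drive = external_drive(r_ext_E = 4),
                          beta = 0.805, seed = 1L,
                          w_scale = sqrt(100 / neurons_per_cluster)) {
  build_population(
    name = "readout", n_clusters = 1,
    neurons_per_cluster = 8 * neurons_per_cluster,
    n_I = round(200 * neurons_per_cluster / 100),
    p_connect = p_connect,
    w = c(EE = w_EE, IE = w_IE, EI = w_EI, II = w_II) * w_scale,
    within_factor = 1,
    drive = drive, beta = beta, seed = seed
  )
}

# Shared population constructor: Bernoulli connectivity, zero diagonal,
# within-cluster multiplier on E->E only.
build_population <- function(name, n_clusters, neurons_per_cluster, n_I,
                             p_connect, w, within_factor, drive, beta, seed) {
  stopifnot(p_connect > 0, p_connect <= 1, all(w >= 0))
  n_E <- n_clusters * neurons_per_cluster
  n <- n_E + n_I
  cluster_id <- rep(seq_len(n_clusters), each = neurons_per_cluster)

  W <- local_seed(seed, {
    mask <- matrix(stats::rbinom(n * n, 1L, p_connect), n, n)
    diag(mask) <- 0L
    M <- matrix(0, n, n)
    eidx <- seq_len(n_E)
    iidx <- if (n_I > 0) n_E + seq_len(n_I) else integer(0)
    M[eidx, eidx] <- w[["EE"]]
    M[iidx, eidx] <- w[["IE"]]
    M[eidx, iidx] <- w[["EI"]]
    M[iidx, iidx] <- w[["II"]]
    same <- outer(cluster_id, cluster_id, "==")
    M[eidx, eidx][same] <- w[["EE"]] * within_factor
    M * mask
  })

  structure(list(name = name, n_E = n_E, n_I = n_I,
                 n_clusters = n_clusters,
                 neurons_per_cluster = neurons_per_cluster,
                 cluster_id = cluster_id,
                 W = W, beta = beta, drive = drive,
                 p_connect = p_connect, seed = seed),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population '%s'> %d E (%d clusters) + %d I neurons\n",
              x$name, x$n_E, x$n_clusters, x$n_I))
  invisible(x)
}

#' Encode a target distribution in the plastic weight matrix
#'
#' Assigns each uniform-sampler cluster to exactly one sensory cluster so that
#' the per-bin cluster counts are `round(C * p_k)` with largest-remainder
#' correction (ties broken toward the lowest bin index). Weights from a
#' presynaptic neuron to its assigned sensory cluster are set to `W_max` and
#' all other weights to `W_min`; the plastic matrix is all-to-all, so each
#' presynaptic neuron's outgoing sum equals `W_max` times the sensory cluster
#' size — the normalization constant K.
#'
#' @param target A [bin_distribution()] over the 8 sensory bins.
#' @param C Number of uniform-sampler clusters.
#' @param n_pre_per_cluster,n_post_per_cluster Neurons per cluster in the
#'   uniform sampler / sensory network.
#' @param W_max,W_min Weight bounds (pF).
#' @return A `n_post x n_pre` plastic weight matrix with attribute
#'   `"assignment"` (the bin assigned to each uniform cluster).
#' @export
init_plastic_weights <- function(target, C = 24,
                                 n_pre_per_cluster = 100,
                                 n_post_per_cluster = 100,
                                 W_max = 5, W_min = 0) {
  target <- bin_distribution(target)
  n_bins <- length(target)
  counts <- largest_remainder(as.numeric(target) * C)
  assignment <- rep(seq_len(n_bins), times = counts)
  n_pre <- C * n_pre_per_cluster
  n_post <- n_bins * n_post_per_cluster
  W <- matrix(W_min, n_post, n_pre)
  post_cluster <- rep(seq_len(n_bins), each = n_post_per_cluster)
  pre_cluster <- rep(seq_len(C), each = n_pre_per_cluster)
  for (c_u in seq_len(C)) {
    W[post_cluster == assignment[c_u], pre_cluster == c_u] <- W_max
  }
  attr(W, "assignment") <- assignment
  W
}

# Integer apportionment with the largest-remainder method; ties go to the
# lowest index. Input: non-negative reals summing to an integer total.
largest_remainder <- function(x) {
  n_total <- round(sum(x))
  base <- floor(x)
  rem <- x - base
  short <- n_total - sum(base)
  if (short > 0) {
    ord <- order(-rem, seq_along(x))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Assemble the full two- or three-network model
#'
#' Builds the uniform sampler, the sensory network, optionally the read-out
#' network, and the plastic inter-network weight matrix initialized to encode
#' `target`. Sub-seeds for each connectivity draw are derived from `seed`.
#'
#' @param target Initial [bin_distribution()] encoded in the plastic weights.
#' @param C Number of uniform-sampler clusters.
#' @param neurons_per_cluster Excitatory neurons per cluster (both networks).
#' @param readout Attach the read-out network?
#' @param sensory Include the sensory network? (`FALSE` builds a bare uniform
#'   sampler, e.g. for measuring its switching statistics.)
#' @param neuron,synapse,plasticity,stp Parameter records; `NULL` plasticity
#'   `K_norm` is resolved to `W_max * neurons_per_cluster`.
#' @param uniform_drive,sensory_drive,readout_drive External drives per
#'   sub-network.
#' @param seed Integer seed.
#' @return An object of class `network_model`.
#' @export
#' @examples
#' m <- build_model(target_distribution("uniform"), C = 4,
#'                  neurons_per_cluster = 10, seed = 1)
#' decode_weights(m$W_plastic, n_bins = 8)
build_model <- function(target = target_distribution("uniform"),
                        C = 24, neurons_per_cluster = 100,
                        readout = FALSE, sensory = TRUE,
                        neuron = neuron_params(),
                        synapse = synapse_params(),
                        plasticity = plasticity_params(),
                        stp = stp_params(),
                        uniform_drive = external_drive(r_ext_E = 4.35),
                        sensory_drive = external_drive(r_ext_E = 4),
                        readout_drive = external_drive(r_ext_E = 4),
                        seed = 1L) {
  target <- bin_distribution(target)
  seeds <- derive_seeds(seed, 4)
  uniform <- build_uniform_sampler(C = C, neurons_per_cluster = neurons_per_cluster,
                                   drive = uniform_drive, seed = seeds[1])
  pops <- list(uniform = uniform)
  if (sensory) {
    pops$sensory <- build_sensory(neurons_per_cluster = neurons_per_cluster,
                                  drive = sensory_drive, seed = seeds[2])
    if (readout) {
      pops$readout <- build_readout(neurons_per_cluster = neurons_per_cluster,
                                    drive = readout_drive, seed = seeds[3])
    }
  }
  # desk-scale compensation: the same square-root rule applied to the
  # recurrent weights also rescales the plastic and read-out weight scales so
  # the inter-network drive keeps its proportion at reduced cluster sizes
  size_factor <- sqrt(100 / neurons_per_cluster)
  if (size_factor != 1) {
    plasticity$W_max <- plasticity$W_max * size_factor
    plasticity$W_min <- plasticity$W_min * size_factor
    plasticity$A_p <- plasticity$A_p * size_factor
    stp$baseline <- stp$baseline * size_factor
    stp$w_cap <- stp$w_cap * size_factor
  }
  if (is.null(plasticity$K_norm)) {
    plasticity$K_norm <- plasticity$W_max * neurons_per_cluster
  }
  W_plastic <- if (sensory) {
    init_plastic_weights(
      target, C = C,
      n_pre_per_cluster = neurons_per_cluster,
      n_post_per_cluster = neurons_per_cluster,
      W_max = plasticity$W_max, W_min = plasticity$W_min
    )
  } else NULL
  structure(list(populations = pops, W_plastic = W_plastic,
                 target = target, C = C,
                 neurons_per_cluster = neurons_per_cluster,
                 neuron = neuron, synapse = synapse,
                 plasticity = plasticity, stp = stp,
                 w_stp = if (sensory) rep(stp$baseline, pops$sensory$n_E) else NULL,
                 state = NULL, seed = seed),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> C = %d uniform clusters, %d neurons/cluster%s\n",
              x$C, x$neurons_per_cluster,
              if (!is.null(x$populations$readout)) ", with read-out" else ""))
  if (!is.null(x$W_plastic)) {
    cat("stored distribution (decoded from plastic weights):\n")
    print(round(decode_weights(x$W_plastic), 4))
  }
  invisible(x)
}

# Derive k reproducible sub-seeds (< 2^31) from one integer seed.
derive_seeds <- function(seed, k) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
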