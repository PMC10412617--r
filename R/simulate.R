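#' Low-level simulation driver
#'
#' Advances the model by `duration` ms of forward-Euler integration, carrying
#' all dynamic state (membrane potentials, adaptation variables, synaptic
#' traces, plastic and read-out weights) on the returned model so consecutive
#' calls form one continuous simulation. Most users call the protocol
#' functions ([simulate_spontaneous()], [train_model()], the experiment
#' drivers) instead.
#'
#' @param model A [build_model()] object.
#' @param duration Simulated time (ms).
#' @param seed Integer seed for this segment's noise (external Poisson drive
#'   and, on the first segment, initial membrane potentials).
#' @param dt Time step (ms).
#' @param schedule Optional stimulus schedule: a matrix with columns
#'   `time, pop, cluster, rate` (ms, population index, cluster index, kHz;
#'   rate `-1` restores the baseline drive).
#' @param snapshot_times Absolute times (ms) at which cluster-block sums of
#'   the plastic matrix are recorded.
#' @param plasticity_enabled Override the model's plasticity flag for this
#'   segment (`NULL` = use `model$plasticity$enabled`).
#' @param record_spikes Record the spike table?
#' @param ext_override Testing hook: list of per-population external count
#'   matrices (`n_neurons x n_steps`) replacing the Poisson drive.
#' @param plast_every Plasticity update period in steps. The plasticity time
#'   constants (100 ms normalization, 15 ms eligibility) are slow relative to
#'   `dt`, so the weight update is subsampled with an effective Euler step of
#'   `plast_every * dt`; 1 updates every step.
#' @return A list with elements `model` (updated), `spikes` (tibble with
#'   columns `population`, `neuron`, `t_ms`), and `snapshots` (list of
#'   `list(t, blocks)`).
#' @export
run_simulation <- function(model, duration, seed, dt = 0.1,
                           schedule = NULL, snapshot_times = numeric(0),
                           plasticity_enabled = NULL,
                           record_spikes = TRUE, ext_override = NULL,
                           plast_every = 10L) {
  stopifnot(inherits(model, "network_model"), duration >= 0, dt > 0)
  pops <- unname(model$populations)
  pop_names <- names(model$populations)
  has_readout <- "readout" %in% pop_names
  plast <- model$plasticity
  if (!is.null(plasticity_enabled)) plast$enabled <- isTRUE(plasticity_enabled)
  if (is.null(plast$K_norm)) {
    plast$K_norm <- plast$W_max * model$neurons_per_cluster
  }
  if (is.null(schedule)) schedule <- matrix(0, 0, 4)
  schedule <- as.matrix(schedule)
  t0 <- if (is.null(model$t0)) 0 else model$t0
  init_state <- if (is.null(model$state)) list() else model$state
  if (is.null(ext_override)) ext_override <- vector("list", length(pops))

  has_sensory <- "sensory" %in% pop_names
  res <- .sim_run_cpp(
    pops, model$neuron, model$synapse,
    if (has_sensory) model$W_plastic else NULL, plast,
    1L, 2L,
    if (has_readout) model$w_stp else NULL, model$stp,
    2L, if (has_readout) which(pop_names == "readout") else 3L,
    schedule, t0, duration, dt,
    as.numeric(snapshot_times),
    as.integer(seed), record_spikes, init_state, ext_override,
    as.integer(plast_every)
  )

  if (has_sensory) {
    assignment <- attr(model$W_plastic, "assignment")
    model$W_plastic <- res$W_plastic
    attr(model$W_plastic, "assignment") <- assignment
  }
  if (has_readout) model$w_stp <- res$w_stp
  model$state <- res$state
  model$t0 <- res$t_end

  spikes <- tibble::tibble(
    population = factor(pop_names[res$spike_pop], levels = pop_names),
    neuron = res$spike_neuron,
    t_ms = res$spike_time
  )
  list(model = model, spikes = spikes, snapshots = res$snapshots)
}

#' Simulate spontaneous dynamics
#'
#' Runs the model under baseline external drive only: the uniform sampler
#' switches randomly between clusters and steers the sensory network through
#' the plastic weights, so sensory cluster activations sample from the stored
#' distribution. Plasticity remains active unless the model (or the
#' `plasticity` argument) freezes it.
#'
#' @inheritParams run_simulation
#' @param plasticity `NULL` to use the model's flag, otherwise `TRUE`/`FALSE`.
#' @return An object of class `sim_result`: list with `spikes`, `model`,
#'   `t_start`, `t_end`, `dt`.
#' @export
#' @examples
#' \donttest{
#' m <- build_model(target_distribution("uniform"), C = 6,
#'                  neurons_per_cluster = 20, seed = 1)
#' out <- simulate_spontaneous(m, duration = 500, seed = 2)
#' head(out$spikes)
#' }
simulate_spontaneous <- function(model, duration, seed, dt = 0.1,
                                 plasticity = NULL, record_spikes = TRUE) {
  t_start <- if (is.null(model$t0)) 0 else model$t0
  res <- run_simulation(model, duration, seed = seed, dt = dt,
                        plasticity_enabled = plasticity,
                        record_spikes = record_spikes)
  structure(list(spikes = res$spikes, model = res$model,
                 t_start = t_start, t_end = res$model$t0, dt = dt),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %.1f ms (%d spikes recorded)\n",
              x$t_end - x$t_start, nrow(x$spikes)))
  invisible(x)
}

#' Train the model on a stream of samples
#'
#' Presents the samples sequentially: every `inter_sample_interval` ms, the
#' sensory cluster encoding the current sample receives high-rate
#' (`stim_rate`) external input for `stim_duration` ms, then baseline drive
#' for the remainder of the interval. The uniform sampler runs freely
#' throughout and Hebbian plasticity (unless frozen) repoints the momentarily
#' active uniform cluster to the stimulated sensory cluster. Cluster-block
#' sums of the plastic matrix are snapshotted every `snapshot_every`
#' presentations.
#'
#' @inheritParams run_simulation
#' @param samples Integer vector of bin indices in `1..8` (use
#'   [draw_samples()] to draw them from a target distribution).
#' @param inter_sample_interval Time between sample onsets (ms).
#' @param stim_rate Stimulus rate (kHz).
#' @param stim_duration Stimulus duration (ms).
#' @param snapshot_every Snapshot period in presentations (0 = none).
#' @return A list with `model`, `spikes`, and `snapshots` (tibble-compatible
#'   list of `t`, `blocks`, plus `sample` index attribute).
#' @export
train_model <- function(model, samples, seed, dt = 0.1,
                        inter_sample_interval = 200,
                        stim_rate = 30, stim_duration = 50,
                        snapshot_every = 5, record_spikes = FALSE,
                        plasticity_enabled = NULL) {
  n_bins <- model$populations$sensory$n_clusters
  if (length(samples) && (any(samples < 1) || any(samples > n_bins))) {
    stop("sample indices must lie in 1..", n_bins)
  }
  stopifnot(stim_duration < inter_sample_interval)
  t0 <- if (is.null(model$t0)) 0 else model$t0
  n <- length(samples)
  if (n == 0) {
    return(list(model = model, spikes = empty_spikes(model), snapshots = list()))
  }
  onsets <- t0 + (seq_len(n) - 1) * inter_sample_interval
  schedule <- rbind(
    cbind(onsets, 2, samples, stim_rate),
    cbind(onsets + stim_duration, 2, samples, -1)
  )
  schedule <- schedule[order(schedule[, 1]), , drop = FALSE]
  snap_idx <- if (snapshot_every > 0) {
    seq_len(n %/% snapshot_every) * snapshot_every
  } else integer(0)
  snap_times <- t0 + snap_idx * inter_sample_interval
  res <- run_simulation(model, duration = n * inter_sample_interval,
                        seed = seed, dt = dt, schedule = schedule,
                        snapshot_times = snap_times,
                        plasticity_enabled = plasticity_enabled,
                        record_spikes = record_spikes)
  snapshots <- res$snapshots
  for (k in seq_along(snapshots)) snapshots[[k]]$sample <- snap_idx[k]
  list(model = res$model, spikes = res$spikes, snapshots = snapshots)
}

empty_spikes <- function(model) {
  tibble::tibble(population = factor(character(0),
                                     levels = names(model$populations)),
                 neuron = integer(0), t_ms = numeric(0))
}
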