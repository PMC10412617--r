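#' Run one decision probe on freshly generated spontaneous dynamics
#'
#' Simulates `duration` ms of spontaneous activity (continuing the model's
#' state), decodes the active sensory cluster per time step, and integrates
#' the comparison function for each requested input. The decision itself is
#' computed mathematically from the decoded samples; it does not feed back
#' into the network.
#'
#' @param model A [build_model()] object.
#' @param inputs Half-integer comparison inputs.
#' @param duration Decision time (ms).
#' @param seed Integer seed.
#' @param dt Time step (ms).
#' @param cfg [integrator_config()].
#' @param plasticity Plasticity override for the probe segment (`NULL` =
#'   model default).
#' @return List with the updated `model`, `r` (named vector of final outputs
#'   per input) and the decoded `trace`.
#' @export
decision_probe <- function(model, inputs, duration = 2000, seed = 1, dt = 0.1,
                           cfg = integrator_config(), plasticity = NULL) {
  check_half_integer(inputs)
  sim <- simulate_spontaneous(model, duration, seed = seed, dt = dt,
                              plasticity = plasticity)
  trace <- active_cluster_trace(sim$spikes, "sensory",
                                n_clusters = model$populations$sensory$n_clusters,
                                neurons_per_cluster = model$neurons_per_cluster,
                                t_start = sim$t_start, t_end = sim$t_end,
                                dt = dt)
  r <- vapply(inputs, function(i) {
    out <- run_decision(trace, i, cfg)
    out$r[nrow(out)]
  }, numeric(1))
  list(model = sim$model, r = stats::setNames(r, inputs), trace = trace)
}

#' Psychometric curves from spontaneous sampling
#'
#' For each comparison input i, simulates `repeats` fresh decision probes and
#' reports the mean and standard deviation of the final output r. Each probe
#' uses a freshly generated spontaneous trace (continuing the model state);
#' with `share_traces = TRUE` all inputs of a repeat are evaluated on the same
#' trace, which is faster but correlates the outputs across inputs.
#'
#' @inheritParams decision_probe
#' @param repeats Number of probes per input.
#' @param share_traces Evaluate all inputs on one trace per repeat?
#' @return A tibble of class `psychometric_curve` with columns `input`,
#'   `r_mean`, `r_sd`, `n`; the per-probe outputs are in attribute `"probes"`.
#' @export
psychometric_experiment <- function(model, inputs = seq(0.5, 8.5, by = 1),
                                    duration = 2000, repeats = 20, seed = 1,
                                    dt = 0.1, cfg = integrator_config(),
                                    plasticity = NULL, share_traces = FALSE) {
  check_half_integer(inputs)
  probes <- list()
  if (share_traces) {
    seeds <- derive_seeds(seed, repeats)
    for (rep_k in seq_len(repeats)) {
      pr <- decision_probe(model, inputs, duration, seed = seeds[rep_k],
                           dt = dt, cfg = cfg, plasticity = plasticity)
      model <- pr$model
      probes[[length(probes) + 1]] <-
        tibble::tibble(input = inputs, r = unname(pr$r), repeat_ = rep_k)
    }
  } else {
    seeds <- derive_seeds(seed, repeats * length(inputs))
    k <- 0
    for (rep_k in seq_len(repeats)) {
      for (i in inputs) {
        k <- k + 1
        pr <- decision_probe(model, i, duration, seed = seeds[k], dt = dt,
                             cfg = cfg, plasticity = plasticity)
        model <- pr$model
        probes[[length(probes) + 1]] <-
          tibble::tibble(input = i, r = unname(pr$r), repeat_ = rep_k)
      }
    }
  }
  probes <- dplyr::bind_rows(probes)
  out <- probes |>
    dplyr::group_by(input) |>
    dplyr::summarise(r_mean = mean(r), r_sd = stats::sd(r), n = dplyr::n(),
                     .groups = "drop")
  structure(out, class = c("psychometric_curve", class(out)),
            probes = probes, model = model)
}

#' Distribution-switch experiment (long-term forgetting)
#'
#' Encodes `p_old` in the plastic weights, optionally streams burn-in samples
#' from it, then streams `n_samples` from `p_new`. After every
#' `probe_every`-th sample the stream pauses and a decision probe measures the
#' psychometric slope (outputs at inputs 5.5 and 3.5, halved; normalized by
#' the output at 8.5 when `normalize = TRUE`).
#'
#' @inheritParams decision_probe
#' @param p_old,p_new Old and new target distributions.
#' @param n_samples Number of samples streamed from `p_new`.
#' @param burn_in Samples streamed from `p_old` before the switch.
#' @param probe_every Probe period in samples.
#' @param probe_duration Decision time per probe (ms).
#' @param probe_delay Gap (ms) between the last sample of a block and the
#'   start of the decision, letting stimulus-evoked activity dissipate so the
#'   probe reads the stored weights rather than the lingering attractor.
#' @param normalize Normalize the slope by the output at input 8.5?
#' @param inter_sample_interval,stim_rate,stim_duration Training protocol.
#' @return A tibble of class `switch_series`: one row per probe with columns
#'   `sample` (index relative to the switch; burn-in probes are negative),
#'   `slope`, plus the updated model in attribute `"model"`.
#' @export
switch_experiment <- function(model, p_old, p_new, n_samples = 300,
                              burn_in = 25, probe_every = 5,
                              probe_duration = 2000, probe_delay = 300,
                              normalize = FALSE,
                              seed = 1, dt = 0.1, cfg = integrator_config(),
                              inter_sample_interval = 200, stim_rate = 30,
                              stim_duration = 50) {
  p_old <- bin_distribution(p_old); p_new <- bin_distribution(p_new)
  model$W_plastic <- init_plastic_weights(
    p_old, C = model$C,
    n_pre_per_cluster = model$neurons_per_cluster,
    n_post_per_cluster = model$neurons_per_cluster,
    W_max = model$plasticity$W_max, W_min = model$plasticity$W_min)
  seeds <- derive_seeds(seed, 3)
  stream <- local_seed(seeds[1], {
    c(draw_samples(p_old, burn_in), draw_samples(p_new, n_samples))
  })
  phase_new <- seq_along(stream) > burn_in
  res <- probed_stream(model, stream, probe_every = probe_every,
                       probe_inputs = c(3.5, 5.5, 8.5),
                       probe_duration = probe_duration, seed = seeds[2],
                       dt = dt, cfg = cfg,
                       inter_sample_interval = inter_sample_interval,
                       stim_rate = stim_rate, stim_duration = stim_duration,
                       probe_delay = probe_delay)
  slopes <- vapply(res$probes, function(p) {
    psychometric_slope(stats::setNames(as.list(p$r), names(p$r)),
                       normalize = normalize)
  }, numeric(1))
  out <- tibble::tibble(
    sample = vapply(res$probes, `[[`, numeric(1), "after_sample") - burn_in,
    slope = slopes
  )
  structure(out, class = c("switch_series", class(out)), model = res$model)
}

#' Short-term history experiment
#'
#' Streams `n_samples` from the target distribution at steady state; after
#' every `probe_every`-th sample the stream pauses and a decision at
#' `probe_i` is simulated. Outputs are min-max normalized to `[0, 1]` across
#' all probes of the run and paired with the mean of the last five observed
#' samples. With `frozen = TRUE` the plastic weights are frozen for the whole
#' run (control condition: the history effect should vanish).
#'
#' @inheritParams switch_experiment
#' @param p Target distribution (streamed throughout; also encoded in the
#'   weights at the start unless `encode = FALSE`).
#' @param n_samples Number of samples streamed.
#' @param probe_i Probe input (half-integer).
#' @param frozen Freeze plasticity?
#' @param encode Re-initialize the plastic weights to encode `p` first?
#' @return A tibble of class `history_series` with columns `probe`,
#'   `after_sample`, `last5_mean`, `r_raw`, `r01`; the updated model is in
#'   attribute `"model"`.
#' @export
history_experiment <- function(model, p, n_samples = 300, probe_i = 4.5,
                               frozen = FALSE, encode = TRUE,
                               probe_every = 5, probe_duration = 2000,
                               probe_delay = 300,
                               seed = 1, dt = 0.1, cfg = integrator_config(),
                               inter_sample_interval = 200, stim_rate = 30,
                               stim_duration = 50) {
  check_half_integer(probe_i)
  p <- bin_distribution(p)
  if (encode) {
    model$W_plastic <- init_plastic_weights(
      p, C = model$C,
      n_pre_per_cluster = model$neurons_per_cluster,
      n_post_per_cluster = model$neurons_per_cluster,
      W_max = model$plasticity$W_max, W_min = model$plasticity$W_min)
  }
  seeds <- derive_seeds(seed, 2)
  stream <- local_seed(seeds[1], draw_samples(p, n_samples))
  plast_flag <- if (frozen) FALSE else NULL
  res <- probed_stream(model, stream, probe_every = probe_every,
                       probe_inputs = probe_i,
                       probe_duration = probe_duration, seed = seeds[2],
                       dt = dt, cfg = cfg,
                       inter_sample_interval = inter_sample_interval,
                       stim_rate = stim_rate, stim_duration = stim_duration,
                       plasticity = plast_flag, probe_delay = probe_delay)
  r_raw <- vapply(res$probes, function(pr) unname(pr$r[1]), numeric(1))
  after <- vapply(res$probes, `[[`, numeric(1), "after_sample")
  last5 <- vapply(after, function(k) mean(stream[max(1, k - 4):k]), numeric(1))
  rng <- range(r_raw)
  r01 <- if (diff(rng) > 0) (r_raw - rng[1]) / diff(rng) else rep(NA_real_, length(r_raw))
  out <- tibble::tibble(probe = seq_along(r_raw), after_sample = after,
                        last5_mean = last5, r_raw = r_raw, r01 = r01)
  structure(out, class = c("history_series", class(out)),
            model = res$model, frozen = frozen)
}

# Shared driver: stream samples in blocks of `probe_every`, pausing after each
# block for one decision probe. Plasticity stays in the given mode during both
# training and probes. The whole experiment runs as one continuous simulation
# (the stimulus schedule encodes the pauses); probe windows are decoded from
# the spike record afterwards.
probed_stream <- function(model, stream, probe_every, probe_inputs,
                          probe_duration, seed, dt, cfg,
                          inter_sample_interval, stim_rate, stim_duration,
                          plasticity = NULL, probe_delay = 300) {
  n <- length(stream)
  blocks <- split(seq_len(n), ceiling(seq_len(n) / probe_every))
  t0 <- if (is.null(model$t0)) 0 else model$t0
  block_len <- probe_every * inter_sample_interval + probe_delay +
    probe_duration
  onsets <- numeric(n)
  probe_start <- numeric(length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    onsets[idx] <- t0 + (b - 1) * block_len +
      (seq_along(idx) - 1) * inter_sample_interval
    probe_start[b] <- t0 + (b - 1) * block_len +
      length(idx) * inter_sample_interval + probe_delay
  }
  schedule <- rbind(
    cbind(onsets, 2, stream, stim_rate),
    cbind(onsets + stim_duration, 2, stream, -1)
  )
  schedule <- schedule[order(schedule[, 1]), , drop = FALSE]
  total <- length(blocks) * block_len
  res <- run_simulation(model, total, seed = seed, dt = dt,
                        schedule = schedule,
                        plasticity_enabled = plasticity,
                        record_spikes = TRUE)
  model <- res$model
  n_bins <- model$populations$sensory$n_clusters
  probes <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    trace <- tryCatch(
      active_cluster_trace(res$spikes, "sensory",
                           n_clusters = n_bins,
                           neurons_per_cluster = model$neurons_per_cluster,
                           t_start = probe_start[b],
                           t_end = probe_start[b] + probe_duration,
                           dt = dt),
      error = function(e) NULL)
    r <- if (is.null(trace)) {
      rep(NA_real_, length(probe_inputs))
    } else {
      vapply(probe_inputs, function(i) {
        out <- run_decision(trace, i, cfg)
        out$r[nrow(out)]
      }, numeric(1))
    }
    probes[[b]] <- list(r = stats::setNames(r, probe_inputs),
                        after_sample = blocks[[b]][length(blocks[[b]])])
  }
  list(model = model, probes = probes)
}

#' Instantaneous probability recall through the STP read-out
#'
#' Runs spontaneous dynamics with the read-out network attached and measures,
#' for every activation episode of each sensory cluster, the population rate
#' of the read-out excitatory neurons. Under short-term depression the
#' read-out weights of frequently active clusters are more depressed, so the
#' read-out rate decreases with stored probability (a novelty code); under
#' facilitation the relationship inverts.
#'
#' @inheritParams decision_probe
#' @param duration Simulated time (ms).
#' @param min_dwell Minimum episode duration (ms) to include.
#' @param discard Initial time (ms) discarded so the STP weights reach their
#'   activity-dependent steady state.
#' @return A tibble of class `recall_result` with one row per sensory
#'   cluster: `cluster`, `probability` (decoded from the plastic weights),
#'   `n_episodes`, `rate_hz` (mean read-out E rate during the cluster's
#'   episodes) and `rate_sd`.
#' @export
recall_experiment <- function(model, duration = 10000, seed = 1, dt = 0.1,
                              min_dwell = 20, discard = 2000) {
  if (is.null(model$populations$readout)) {
    stop("recall_experiment needs a model built with readout = TRUE")
  }
  sim <- simulate_spontaneous(model, duration, seed = seed, dt = dt)
  n_bins <- model$populations$sensory$n_clusters
  trace <- active_cluster_trace(sim$spikes, "sensory", n_clusters = n_bins,
                                neurons_per_cluster = model$neurons_per_cluster,
                                t_start = sim$t_start, t_end = sim$t_end,
                                dt = dt)
  runs <- merged_runs(trace$label, dt = dt, min_dwell = min_dwell)
  ends <- trace$t_ms[cumsum(runs$lengths)]
  starts <- c(trace$t_ms[1] - dt, utils::head(ends, -1))
  keep <- (starts >= sim$t_start + discard) &
    (runs$lengths * dt >= min_dwell)
  ro <- sim$spikes[sim$spikes$population == "readout" &
                     sim$spikes$neuron <= model$populations$readout$n_E, ]
  n_ro_E <- model$populations$readout$n_E
  ep_rate <- function(s, e) {
    nsp <- sum(ro$t_ms > s + 1e-9 & ro$t_ms <= e + 1e-9)
    1000 * nsp / (n_ro_E * (e - s))
  }
  rates <- mapply(ep_rate, starts[keep], ends[keep])
  labels <- runs$values[keep]
  probs <- as.numeric(decode_weights(sim$model$W_plastic, n_bins = n_bins))
  out <- tibble::tibble(cluster = seq_len(n_bins), probability = probs) |>
    dplyr::left_join(
      tibble::tibble(cluster = labels, rate = rates) |>
        dplyr::group_by(cluster) |>
        dplyr::summarise(n_episodes = dplyr::n(), rate_hz = mean(rate),
                         rate_sd = stats::sd(rate), .groups = "drop"),
      by = "cluster")
  structure(out, class = c("recall_result", class(out)), model = sim$model)
}

# Run-length encoding after absorbing runs shorter than min_dwell into the
# preceding label (decoder chatter suppression).
merged_runs <- function(labels, dt, min_dwell) {
  r <- rle(labels)
  if (min_dwell > 0 && length(r$lengths) > 1) {
    min_steps <- round(min_dwell / dt)
    lab <- r$values
    for (k in seq_along(lab)[-1]) {
      if (r$lengths[k] < min_steps) lab[k] <- lab[k - 1]
    }
    r <- rle(rep(lab, r$lengths))
  }
  r
}
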