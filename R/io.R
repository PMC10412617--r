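#' Default run configuration
#'
#' A flat list of every tunable knob with the canonical defaults. Unknown keys
#' in an override file are rejected, so configs stay in sync with the code.
#'
#' @return Named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    experiment = "sample",     # train | sample | decide | switch | history | recall
    seed = 1L,
    out_dir = "spikesampler-run",
    # architecture
    C = 24L,
    neurons_per_cluster = 100L,
    readout = FALSE,
    distribution = "uniform",  # uniform | biased | unimodal | bimodal
    distribution_new = "bimodal",
    # dynamics
    dt = 0.1,
    duration = 5000,
    # training protocol
    n_samples = 100L,
    inter_sample_interval = 200,
    stim_rate = 30,
    stim_duration = 50,
    snapshot_every = 5L,
    # drives
    uniform_rate_E = 4.35,
    sensory_rate_E = 4,
    readout_rate_E = 4,
    rate_I = 2.25,
    # plasticity
    A_p = 0.5,
    tau_n = 100,
    W_min = 0,
    W_max = 5,
    coincidence_window = 15,
    frozen = FALSE,
    # short-term plasticity
    stp_mode = "depression",
    stp_baseline = 4,
    stp_fraction = 0.05,
    stp_tau = 2000,
    stp_cap = 6,
    # decision read-out
    tau_r = 1000,
    probe_every = 5L,
    probe_duration = 2000,
    probe_i = 4.5,
    repeats = 20L,
    burn_in = 25L,
    record_spikes = TRUE
  ), class = "run_config")
}

#' Load a run configuration
#'
#' Reads a YAML file of overrides and merges it onto [default_config()].
#' Unknown keys are an error; an empty file returns the defaults.
#'
#' @param path Path to a YAML file (`NULL` for pure defaults).
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) return(cfg)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(ov)) {
    template <- cfg[[k]]
    value <- ov[[k]]
    if (is.numeric(template) && !is.numeric(value)) {
      stop("configuration key '", k, "' must be numeric")
    }
    cfg[[k]] <- if (is.integer(template)) as.integer(value) else value
  }
  cfg
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Save / load a spike record
#'
#' Lossless CSV round trip of the (population, neuron, t_ms) spike table.
#'
#' @param spikes Spike tibble.
#' @param path CSV file path.
#' @return `load_spikes` returns the spike tibble.
#' @export
save_spikes <- function(spikes, path) {
  df <- as.data.frame(spikes)
  # full round-trip precision for spike times (write.csv would truncate ulps)
  df$t_ms <- sprintf("%.17g", df$t_ms)
  utils::write.csv(df, path, row.names = FALSE, quote = 1)
  invisible(path)
}

#' @rdname save_spikes
#' @export
load_spikes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "neuron", "t_ms")
  if (!all(need %in% names(df))) {
    stop("spike file lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  bad <- which(!is.finite(df$t_ms) | is.na(df$neuron) | is.na(df$population))
  if (length(bad)) {
    stop("malformed spike rows at line(s): ",
         paste(utils::head(bad + 1L, 10), collapse = ", "))
  }
  tibble::tibble(population = factor(df$population,
                                     levels = unique(df$population)),
                 neuron = as.integer(df$neuron), t_ms = as.numeric(df$t_ms))
}

#' Run a configured experiment and write its artifacts
#'
#' Builds the model from a [run_config], dispatches on `config$experiment`,
#' and writes result tables (CSV), the resolved configuration, and a
#' provenance manifest (config hash, seed, package version) to
#' `config$out_dir`.
#'
#' @param config A `run_config` list, see [load_config()].
#' @return The output directory, invisibly; results are also returned in
#'   attribute `"results"`.
#' @export
run_experiment <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- target_distribution(cfg$distribution)
  model <- build_model(
    target = p, C = cfg$C, neurons_per_cluster = cfg$neurons_per_cluster,
    readout = isTRUE(cfg$readout) || cfg$experiment == "recall",
    plasticity = plasticity_params(A_p = cfg$A_p, tau_n = cfg$tau_n,
                                   W_min = cfg$W_min, W_max = cfg$W_max,
                                   coincidence_window = cfg$coincidence_window,
                                   enabled = !isTRUE(cfg$frozen)),
    stp = stp_params(baseline = cfg$stp_baseline,
                     step_fraction = cfg$stp_fraction,
                     recovery_tau = cfg$stp_tau, mode = cfg$stp_mode,
                     w_cap = cfg$stp_cap),
    uniform_drive = external_drive(r_ext_E = cfg$uniform_rate_E,
                                   r_ext_I = cfg$rate_I),
    sensory_drive = external_drive(r_ext_E = cfg$sensory_rate_E,
                                   r_ext_I = cfg$rate_I),
    readout_drive = external_drive(r_ext_E = cfg$readout_rate_E,
                                   r_ext_I = cfg$rate_I),
    seed = cfg$seed
  )
  seeds <- derive_seeds(cfg$seed, 2)
  cfgint <- integrator_config(tau_r = cfg$tau_r, dt = cfg$dt)

  results <- switch(cfg$experiment,
    sample = {
      sim <- simulate_spontaneous(model, cfg$duration, seed = seeds[1],
                                  dt = cfg$dt)
      if (isTRUE(cfg$record_spikes)) {
        save_spikes(sim$spikes, file.path(cfg$out_dir, "spikes.csv"))
      }
      tr <- active_cluster_trace(sim$spikes, "sensory",
                                 neurons_per_cluster = cfg$neurons_per_cluster,
                                 t_start = sim$t_start, t_end = sim$t_end,
                                 dt = cfg$dt)
      tibble::tibble(cluster = seq_along(p),
                     target = as.numeric(p),
                     empirical = as.numeric(empirical_distribution(tr)))
    },
    train = {
      stream <- local_seed(seeds[1], draw_samples(p, cfg$n_samples))
      tr <- train_model(model, stream, seed = seeds[2], dt = cfg$dt,
                        inter_sample_interval = cfg$inter_sample_interval,
                        stim_rate = cfg$stim_rate,
                        stim_duration = cfg$stim_duration,
                        snapshot_every = cfg$snapshot_every,
                        record_spikes = isTRUE(cfg$record_spikes))
      if (isTRUE(cfg$record_spikes)) {
        save_spikes(tr$spikes, file.path(cfg$out_dir, "spikes.csv"))
      }
      learning_curve(tr$snapshots, p)
    },
    decide = {
      as.data.frame(psychometric_experiment(
        model, duration = cfg$probe_duration, repeats = cfg$repeats,
        seed = seeds[1], dt = cfg$dt, cfg = cfgint))
    },
    switch = {
      switch_experiment(model, p, target_distribution(cfg$distribution_new),
                        n_samples = cfg$n_samples, burn_in = cfg$burn_in,
                        probe_every = cfg$probe_every,
                        probe_duration = cfg$probe_duration,
                        seed = seeds[1], dt = cfg$dt, cfg = cfgint,
                        inter_sample_interval = cfg$inter_sample_interval,
                        stim_rate = cfg$stim_rate,
                        stim_duration = cfg$stim_duration)
    },
    history = {
      history_experiment(model, p, n_samples = cfg$n_samples,
                         probe_i = cfg$probe_i, frozen = isTRUE(cfg$frozen),
                         probe_every = cfg$probe_every,
                         probe_duration = cfg$probe_duration,
                         seed = seeds[1], dt = cfg$dt, cfg = cfgint,
                         inter_sample_interval = cfg$inter_sample_interval,
                         stim_rate = cfg$stim_rate,
                         stim_duration = cfg$stim_duration)
    },
    recall = {
      recall_experiment(model, duration = cfg$duration, seed = seeds[1],
                        dt = cfg$dt)
    },
    stop("unknown experiment: ", cfg$experiment)
  )

  utils::write.csv(as.data.frame(results),
                   file.path(cfg$out_dir, "results.csv"), row.names = FALSE)
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  save_config(cfg, cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    experiment = cfg$experiment,
    package_version = as.character(utils::packageVersion("spikesampler")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  out <- cfg$out_dir
  attr(out, "results") <- results
  invisible(out)
}
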