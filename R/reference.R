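# Plain-R reference stepper. Composes the exported single-step operations
# (adex_step, lif_step, update_conductance, stp_step, eligibility,
# hebb_norm_step) into a full simulation with exactly the same update ordering
# as the compiled path. It is intentionally slow and is used as the
# independent trajectory-level oracle in the test suite; the external input
# counts are supplied as matrices so both paths can be fed identical noise.
#
# populations: list of `population` objects.
# ext_counts:  list of n x n_steps count matrices, one per population.
# schedule:    matrix with columns (time, pop, cluster, rate); rate < 0
#              restores the baseline rate.
simulate_reference <- function(populations, duration, dt,
                               ext_counts,
                               neuron = neuron_params(),
                               synapse = synapse_params(),
                               W_plastic = NULL, plasticity = NULL,
                               plastic_pre = 1L, plastic_post = 2L,
                               w_stp = NULL, stp = NULL,
                               stp_pre = 2L, stp_post = 3L,
                               schedule = NULL, t0 = 0,
                               init_V = NULL) {
  P <- length(populations)
  n_steps <- round(duration / dt)
  st <- vector("list", P)
  for (p in seq_len(P)) {
    pop <- populations[[p]]
    V0 <- if (!is.null(init_V)) init_V[[p]] else NULL
    s <- fresh_state(pop$n_E + pop$n_I, pop$n_E, neuron, t0, V = V0)
    s$rate <- c(rep(pop$drive$r_ext_E, pop$n_E), rep(pop$drive$r_ext_I, pop$n_I))
    s$base_rate <- s$rate
    st[[p]] <- s
  }
  sh <- list(d = 0, r = 0, pend = 0)  # shared read-out trace
  has_plastic <- !is.null(W_plastic)
  has_stp <- !is.null(w_stp)
  spikes <- list(pop = integer(0), neuron = integer(0), time = numeric(0))
  ev_idx <- 1L

  for (step in seq_len(n_steps)) {
    tt <- t0 + (step - 1) * dt
    t_new <- tt + dt

    if (!is.null(schedule)) {
      while (ev_idx <= nrow(schedule) && schedule[ev_idx, 1] <= tt + 1e-9) {
        p <- schedule[ev_idx, 2]; cl <- schedule[ev_idx, 3]
        rate <- schedule[ev_idx, 4]
        pop <- populations[[p]]
        sel <- which(pop$cluster_id == cl)
        st[[p]]$rate[sel] <- if (rate < 0) st[[p]]$base_rate[sel] else rate
        ev_idx <- ev_idx + 1L
      }
    }

    # traces: decay, then pending recurrent + external impulses
    g <- vector("list", P)
    for (p in seq_len(P)) {
      pop <- populations[[p]]
      s <- st[[p]]
      n_E <- pop$n_E
      w_ext <- c(rep(pop$drive$W_ext_E, n_E), rep(pop$drive$W_ext_I, pop$n_I))
      impE <- s$pendE + ext_counts[[p]][, step] * w_ext
      upE <- update_conductance(list(d = s$eEd, r = s$eEr), impE, "E", synapse, dt)
      upI <- update_conductance(list(d = s$eId, r = s$eIr), s$pendI, "I", synapse, dt)
      s$eEd <- upE$kernel_state$d; s$eEr <- upE$kernel_state$r
      s$eId <- upI$kernel_state$d; s$eIr <- upI$kernel_state$r
      s$pendE <- s$pendE * 0; s$pendI <- s$pendI * 0
      g[[p]] <- list(E = upE$g, I = upI$g)
      st[[p]] <- s
    }
    if (has_stp) {
      sh$d <- sh$d * exp(-dt / synapse$tau_d_E) + sh$pend
      sh$r <- sh$r * exp(-dt / synapse$tau_r_E) + sh$pend
      sh$pend <- 0
    }
    g_shared <- if (has_stp) (sh$d - sh$r) / (synapse$tau_d_E - synapse$tau_r_E) else 0

    # membrane updates
    spiked <- vector("list", P)
    for (p in seq_len(P)) {
      pop <- populations[[p]]
      s <- st[[p]]
      eidx <- seq_len(pop$n_E)
      iidx <- pop$n_E + seq_len(pop$n_I)
      gE <- g[[p]]$E; gI <- g[[p]]$I
      if (has_stp && p == stp_post) gE[eidx] <- gE[eidx] + g_shared

      upE <- adex_step(list(V = s$V[eidx], V_T_dyn = s$vt, a = s$a,
                            refractory_until = s$ref_until[eidx],
                            last_spike = s$last_spike[eidx], t = tt),
                       gE[eidx], gI[eidx], neuron, dt, beta = pop$beta)
      upI <- lif_step(list(V = s$V[iidx],
                           refractory_until = s$ref_until[iidx],
                           last_spike = s$last_spike[iidx], t = tt),
                      gE[iidx], gI[iidx], neuron, dt)
      s$V[eidx] <- upE$state$V; s$vt <- upE$state$V_T_dyn; s$a <- upE$state$a
      s$ref_until[eidx] <- upE$state$refractory_until
      s$last_spike[eidx] <- upE$state$last_spike
      s$V[iidx] <- upI$state$V
      s$ref_until[iidx] <- upI$state$refractory_until
      s$last_spike[iidx] <- upI$state$last_spike
      spk <- c(which(upE$spikes), pop$n_E + which(upI$spikes))
      spiked[[p]] <- sort(spk)
      if (length(spk)) {
        spikes$pop <- c(spikes$pop, rep(p, length(spk)))
        spikes$neuron <- c(spikes$neuron, sort(spk))
        spikes$time <- c(spikes$time, rep(t_new, length(spk)))
      }
      st[[p]] <- s
    }

    # propagate spikes into next step's pending impulses
    for (p in seq_len(P)) {
      pop <- populations[[p]]
      for (j in spiked[[p]]) {
        if (j <= pop$n_E) {
          st[[p]]$pendE <- st[[p]]$pendE + pop$W[, j]
          if (has_plastic && p == plastic_pre) {
            st[[plastic_post]]$pendE[seq_len(nrow(W_plastic))] <-
              st[[plastic_post]]$pendE[seq_len(nrow(W_plastic))] + W_plastic[, j]
          }
        } else {
          st[[p]]$pendI <- st[[p]]$pendI + pop$W[, j]
        }
      }
    }

    # short-term plasticity on read-out weights
    if (has_stp) {
      pre_E <- seq_along(w_stp)
      spk_pre <- intersect(spiked[[stp_pre]], pre_E)
      if (stp$enabled) {
        w_rec <- w_stp + dt * (stp$baseline - w_stp) / stp$recovery_tau
        sh$pend <- sh$pend + sum(w_rec[spk_pre])
        pre_spk <- rep(FALSE, length(w_stp)); pre_spk[spk_pre] <- TRUE
        w_stp <- stp_step(w_stp, pre_spk, stp, dt)
      } else {
        sh$pend <- sh$pend + sum(w_stp[spk_pre])
      }
    }

    # Hebbian + normalization on the plastic weights
    if (has_plastic && plasticity$enabled) {
      y_pre <- eligibility(st[[plastic_pre]]$last_spike[seq_len(ncol(W_plastic))],
                           t_new, plasticity$coincidence_window)
      y_post <- eligibility(st[[plastic_post]]$last_spike[seq_len(nrow(W_plastic))],
                            t_new, plasticity$coincidence_window)
      W_plastic <- hebb_norm_step(W_plastic, y_post, y_pre, plasticity, dt)
    }
  }

  list(spikes = tibble::tibble(population = spikes$pop, neuron = spikes$neuron,
                               t_ms = spikes$time),
       W_plastic = W_plastic, w_stp = w_stp, state = st,
       t_end = t0 + n_steps * dt)
}
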