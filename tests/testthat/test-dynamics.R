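np <- neuron_params()
sp <- synapse_params()

make_state_E <- function(V, n = length(V), t = 0) {
  list(V = V, V_T_dyn = rep(np$V_T, n), a = rep(0, n),
       refractory_until = rep(-Inf, n), last_spike = rep(-Inf, n), t = t)
}
make_state_I <- function(V, n = length(V), t = 0) {
  list(V = V, refractory_until = rep(-Inf, n), last_spike = rep(-Inf, n), t = t)
}

test_that("rest is a fixed point of the excitatory dynamics up to the exponential tail", {
  st <- make_state_E(np$E_L_E)
  out <- adex_step(st, g_E = 0, g_I = 0, np, dt = 0.1)
  # |dV/dt| < 1e-3 mV/ms: the exponential term is ~ exp(-9)
  expect_lt(abs(out$state$V - np$E_L_E) / 0.1, 1e-3)
  expect_false(out$spikes)
})

test_that("the inhibitory leak fixed point is exact", {
  st <- make_state_I(np$E_L_I)
  out <- lif_step(st, g_E = 0, g_I = 0, np, dt = 0.1)
  expect_equal(out$state$V, np$E_L_I)
})

test_that("constant subthreshold conductance drives the LIF neuron to the analytic fixed point", {
  g_E <- 2; g_I <- 1  # pF/ms
  # 0 = (E_L - V*)/tau + gE (E_E - V*)/C + gI (E_I - V*)/C
  num <- np$E_L_I / np$tau_I + g_E * np$E_rev_E / np$C_mem +
    g_I * np$E_rev_I / np$C_mem
  den <- 1 / np$tau_I + g_E / np$C_mem + g_I / np$C_mem
  V_star <- num / den
  expect_lt(V_star, np$V_T)  # chosen subthreshold
  st <- make_state_I(np$E_L_I)
  for (k in 1:4000) st <- lif_step(st, g_E, g_I, np, dt = 0.1)$state
  expect_equal(st$V, V_star, tolerance = 1e-6)
})

test_that("excitatory spikes reset, increment adaptation, and respect refractoriness", {
  st <- make_state_E(0)  # far past threshold: the exponential fires it this step
  beta <- 100
  out <- adex_step(st, g_E = 0, g_I = 0, np, dt = 0.1, beta = beta)
  expect_true(out$spikes)
  expect_equal(out$state$V, np$V_r)
  expect_equal(out$state$V_T_dyn, np$V_T + np$A_T)
  # one subthreshold-coupling Euler step plus the spike increment
  expect_equal(out$state$a,
               beta + 0.1 * np$alpha * (0 - np$E_L_E) / np$tau_a)
  expect_equal(out$state$refractory_until, out$state$t + np$tau_abs)
  # clamped at V_r while refractory, even under strong drive
  st2 <- out$state
  for (k in 1:49) {  # 4.9 ms < tau_abs
    st2 <- adex_step(st2, g_E = 50, g_I = 0, np, dt = 0.1, beta = beta)$state
    expect_equal(st2$V, np$V_r)
  }
})

test_that("no neuron in a driven network emits two spikes within the refractory period", {
  m <- tiny_model(C = 3, npc = 8, seed = 2)
  out <- simulate_spontaneous(m, 500, seed = 5)
  isi <- out$spikes |>
    dplyr::group_by(population, neuron) |>
    dplyr::summarise(min_isi = min(diff(c(0, sort(t_ms)))), .groups = "drop")
  expect_true(all(isi$min_isi >= np$tau_abs - 1e-9))
})

test_that("the synaptic kernel integrates to one and the discrete trace reproduces it", {
  for (cls in c("E", "I")) {
    td <- if (cls == "E") sp$tau_d_E else sp$tau_d_I
    tr <- if (cls == "E") sp$tau_r_E else sp$tau_r_I
    integral <- stats::integrate(synaptic_kernel, 0, Inf, tau_d = td,
                                 tau_r = tr, rel.tol = 1e-10)$value
    expect_equal(integral, 1, tolerance = 1e-6)

    # isolated unit impulse reproduces the closed-form kernel on the grid
    dt <- 0.1
    ks <- list(d = 0, r = 0)
    g <- numeric(400)
    for (n in 1:400) {
      up <- update_conductance(ks, impulse = if (n == 1) 1 else 0, cls, sp, dt)
      ks <- up$kernel_state
      g[n] <- up$g
    }
    expect_equal(g, synaptic_kernel((0:399) * dt, td, tr), tolerance = 1e-12)
    # peak location matches a dense numeric maximization of the closed form
    tgrid <- seq(0, 20, by = 1e-4)
    t_peak <- tgrid[which.max(synaptic_kernel(tgrid, td, tr))]
    expect_lt(abs((which.max(g) - 1) * dt - t_peak), dt)
  }
  expect_error(synaptic_kernel(1, tau_d = 2, tau_r = 2), "invalid kernel")
  expect_error(update_conductance(list(d = 0, r = 0), 0, "E",
                                  structure(list(tau_d_E = 2, tau_r_E = 2),
                                            class = "synapse_params"), 0.1),
               "invalid kernel")
})

test_that("external Poisson counts have the right mean and respect edge cases", {
  expect_equal(poisson_external(0, 100, 0.1), rep(0L, 100))
  expect_error(poisson_external(-1, 10, 0.1), "non-negative")
  set.seed(42)
  n <- 1e6
  counts <- poisson_external(5, n, 0.1)  # mean 0.5
  se <- sqrt(0.5 / n)
  expect_lt(abs(mean(counts) - 0.5), 3 * se)
})

test_that("single-neuron firing under constant drive is robust to the step size", {
  rate_at <- function(dt) {
    st <- make_state_E(np$E_L_E)
    n_steps <- round(2000 / dt)
    spikes <- 0
    for (k in seq_len(n_steps)) {
      out <- adex_step(st, g_E = 15, g_I = 0, np, dt = dt, beta = 100)
      st <- out$state
      spikes <- spikes + out$spikes
    }
    spikes / 2
  }
  r_coarse <- rate_at(0.1)
  r_fine <- rate_at(0.01)
  expect_gt(r_fine, 5)  # suprathreshold by construction
  expect_lt(abs(r_coarse - r_fine) / r_fine, 0.05)
})

test_that("non-finite membrane values fail loudly with the neuron index", {
  st <- make_state_E(c(-70, NaN))
  expect_error(adex_step(st, g_E = c(0, 0), g_I = c(0, 0), np, dt = 0.1),
               "blow-up.*2")
})
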