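#' Single Euler step of the excitatory (AdEx) neurons
#'
#' Vectorized forward-Euler update of membrane potential, adaptive threshold
#' and adaptation current. Neurons whose membrane exceeds `spike_cutoff` after
#' the update emit a spike: the membrane is reset to `V_r`, the adaptive
#' threshold jumps to `V_T + A_T`, the adaptation current is incremented by
#' `beta`, and the neuron becomes refractory for `tau_abs` ms, during which
#' the membrane stays clamped at `V_r` while threshold and adaptation keep
#' relaxing. The exponential spike-initiation term is capped so the blow-up
#' between detection checks stays finite.
#'
#' @param state List with elements `V`, `V_T_dyn`, `a` (numeric vectors),
#'   `refractory_until`, `last_spike` (times, ms) and `t` (current time, ms).
#' @param g_E,g_I Conductance traces (pF/ms) per neuron.
#' @param params [neuron_params()].
#' @param dt Time step (ms).
#' @param beta Spike-triggered adaptation increment (pA).
#' @return List with the updated `state` (time advanced by `dt`) and `spikes`,
#'   a logical vector.
#' @export
adex_step <- function(state, g_E, g_I, params, dt, beta = 0.805) {
  stopifnot(dt > 0, length(g_E) == length(state$V),
            length(g_I) == length(state$V))
  V <- state$V; vt <- state$V_T_dyn; a <- state$a
  t_new <- state$t + dt
  refractory <- state$t < state$refractory_until - 1e-9

  arg <- pmin((V - vt) / params$Delta_T, 50)
  dV <- (params$E_L_E - V + params$Delta_T * exp(arg)) / params$tau_E +
    g_E * (params$E_rev_E - V) / params$C_mem +
    g_I * (params$E_rev_I - V) / params$C_mem -
    a / params$C_mem
  V_new <- ifelse(refractory, V, pmin(V + dt * dV, params$spike_cutoff + 10))
  vt <- vt + dt * (params$V_T - vt) / params$tau_T
  a <- a + dt * (-a + params$alpha * (V - params$E_L_E)) / params$tau_a

  bad <- which(!is.finite(V_new))
  if (length(bad)) {
    stop("numerical blow-up in excitatory neuron(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " at t = ", t_new)
  }
  spikes <- !refractory & V_new > params$spike_cutoff
  V_new[spikes] <- params$V_r
  vt[spikes] <- params$V_T + params$A_T
  a[spikes] <- a[spikes] + beta
  ref <- state$refractory_until
  ref[spikes] <- t_new + params$tau_abs
  ls <- state$last_spike
  ls[spikes] <- t_new

  list(state = list(V = V_new, V_T_dyn = vt, a = a,
                    refractory_until = ref, last_spike = ls, t = t_new),
       spikes = spikes)
}

#' Single Euler step of the inhibitory (LIF) neurons
#'
#' Leaky integrate-and-fire update with a fixed threshold `V_T`, reset to
#' `V_r` and absolute refractory period `tau_abs`; no adaptation variables.
#'
#' @inheritParams adex_step
#' @return List with updated `state` and logical `spikes`.
#' @export
lif_step <- function(state, g_E, g_I, params, dt) {
  stopifnot(dt > 0, length(g_E) == length(state$V),
            length(g_I) == length(state$V))
  V <- state$V
  t_new <- state$t + dt
  refractory <- state$t < state$refractory_until - 1e-9

  dV <- (params$E_L_I - V) / params$tau_I +
    g_E * (params$E_rev_E - V) / params$C_mem +
    g_I * (params$E_rev_I - V) / params$C_mem
  V_new <- ifelse(refractory, V, V + dt * dV)

  bad <- which(!is.finite(V_new))
  if (length(bad)) {
    stop("numerical blow-up in inhibitory neuron(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " at t = ", t_new)
  }
  spikes <- !refractory & V_new > params$V_T
  V_new[spikes] <- params$V_r
  ref <- state$refractory_until
  ref[spikes] <- t_new + params$tau_abs
  ls <- state$last_spike
  ls[spikes] <- t_new

  list(state = list(V = V_new, refractory_until = ref, last_spike = ls,
                    t = t_new),
       spikes = spikes)
}

#' Difference-of-exponentials synaptic kernel
#'
#' `K(t) = (exp(-t / tau_d) - exp(-t / tau_r)) / (tau_d - tau_r)` for
#' `t >= 0`; its time integral is exactly 1, so a unit spike injects unit
#' conductance-time.
#'
#' @param t Times (ms), may be a vector.
#' @param tau_d,tau_r Decay and rise time constants (ms), `tau_d > tau_r`.
#' @return Kernel values (1/ms).
#' @export
synaptic_kernel <- function(t, tau_d = 6, tau_r = 1) {
  if (tau_d == tau_r) stop("invalid kernel: tau_d must differ from tau_r")
  ifelse(t >= 0, (exp(-t / tau_d) - exp(-t / tau_r)) / (tau_d - tau_r), 0)
}

#' Single step of the two-exponential conductance dynamics
#'
#' The kernel convolution is realized as a linear system of one decay trace
#' and one rise trace per neuron; the conductance is
#' `(decay - rise) / (tau_d - tau_r)`. An isolated unit impulse reproduces
#' [synaptic_kernel()] on the step grid.
#'
#' @param kernel_state List with numeric vectors `d` and `r` (the two traces).
#' @param impulse Summed synaptic weight of spikes arriving this step, per
#'   neuron (pF).
#' @param class `"E"` or `"I"`: which kernel time constants to use.
#' @param params [synapse_params()].
#' @param dt Time step (ms).
#' @return List with updated `kernel_state` and the conductance trace `g`
#'   (pF/ms).
#' @export
update_conductance <- function(kernel_state, impulse, class = c("E", "I"),
                               params = synapse_params(), dt = 0.1) {
  class <- match.arg(class)
  stopifnot(dt > 0)
  tau_d <- if (class == "E") params$tau_d_E else params$tau_d_I
  tau_r <- if (class == "E") params$tau_r_E else params$tau_r_I
  if (tau_d == tau_r) stop("invalid kernel: tau_d must differ from tau_r")
  d <- kernel_state$d * exp(-dt / tau_d) + impulse
  r <- kernel_state$r * exp(-dt / tau_r) + impulse
  list(kernel_state = list(d = d, r = r), g = (d - r) / (tau_d - tau_r))
}

#' Draw one step of external Poisson input
#'
#' Independent Poisson spike counts with mean `rate * dt` per neuron. Rates
#' are in kHz and `dt` in ms. Uses the R random number stream.
#'
#' @param rate Rate (kHz), scalar or per neuron.
#' @param n_neurons Number of neurons.
#' @param dt Time step (ms).
#' @return Integer vector of spike counts.
#' @export
poisson_external <- function(rate, n_neurons, dt = 0.1) {
  if (any(rate < 0)) stop("external rate must be non-negative")
  stats::rpois(n_neurons, rate * dt)
}

# Fresh per-population neuron state at time t0 (V ~ U(V_r, V_T) unless given).
fresh_state <- function(n, n_E, params, t0 = 0, V = NULL) {
  if (is.null(V)) V <- stats::runif(n, params$V_r, params$V_T)
  list(V = V,
       a = rep(0, n_E),
       vt = rep(params$V_T, n_E),
       ref_until = rep(-1e18, n),
       last_spike = rep(-1e18, n),
       eEd = rep(0, n), eEr = rep(0, n), eId = rep(0, n), eIr = rep(0, n),
       pendE = rep(0, n), pendI = rep(0, n))
}
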