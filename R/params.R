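#' Neuron model parameters
#'
#' Parameters of the adaptive exponential integrate-and-fire (AdEx) model used
#' for excitatory neurons and the leaky integrate-and-fire (LIF) model used for
#' inhibitory neurons. Defaults reproduce the standard parameter set of the
#' clustered-network model; the only parameter that differs between
#' sub-networks is the spike-triggered adaptation increment `beta` (large in
#' the uniform sampler, where strong adaptation paces reliable cluster
#' switching; small elsewhere), which lives on the network builders.
#'
#' All times are in ms, potentials in mV, capacitance in pF, `alpha` in nS and
#' `beta` in pA. Conductance traces carry units of pF/ms so that `g * (E - V) /
#' C_mem` is in mV/ms with no conversion factors.
#'
#' @param tau_E,tau_I Membrane time constants of E and I neurons (ms).
#' @param tau_abs Absolute refractory period (ms), both E and I.
#' @param E_rev_E,E_rev_I Excitatory / inhibitory synaptic reversal potentials (mV).
#' @param E_L_E,E_L_I Resting (leak) potentials of E and I neurons (mV).
#' @param V_r Reset potential after a spike (mV), all neurons.
#' @param C_mem Membrane capacitance (pF).
#' @param Delta_T Slope of the AdEx exponential spike-initiation term (mV).
#' @param tau_T Relaxation time constant of the adaptive threshold (ms).
#' @param V_T Baseline membrane potential threshold (mV). Fixed spike
#'   threshold for I neurons; resting value of the adaptive threshold for E.
#' @param A_T Adaptive threshold increase after an E spike (mV).
#' @param tau_a Adaptation current time constant (ms).
#' @param alpha Subthreshold adaptation coupling (nS).
#' @param spike_cutoff Membrane potential at which an E spike is detected (mV).
#'
#' @return An object of class `neuron_params` (a named list).
#' @export
#' @examples
#' neuron_params()
neuron_params <- function(tau_E = 20, tau_I = 20, tau_abs = 5,
                          E_rev_E = 0, E_rev_I = -75,
                          E_L_E = -70, E_L_I = -62,
                          V_r = -60, C_mem = 300,
                          Delta_T = 2, tau_T = 30, V_T = -52, A_T = 10,
                          tau_a = 100, alpha = 4, spike_cutoff = 20) {
  p <- list(tau_E = tau_E, tau_I = tau_I, tau_abs = tau_abs,
            E_rev_E = E_rev_E, E_rev_I = E_rev_I,
            E_L_E = E_L_E, E_L_I = E_L_I,
            V_r = V_r, C_mem = C_mem,
            Delta_T = Delta_T, tau_T = tau_T, V_T = V_T, A_T = A_T,
            tau_a = tau_a, alpha = alpha, spike_cutoff = spike_cutoff)
  stopifnot(
    "time constants must be positive" =
      all(unlist(p[c("tau_E", "tau_I", "tau_abs", "tau_T", "tau_a")]) > 0),
    "need V_r < V_T < spike_cutoff" = V_r < V_T && V_T < spike_cutoff,
    "capacitance must be positive" = C_mem > 0,
    "Delta_T must be positive" = Delta_T > 0
  )
  structure(p, class = "neuron_params")
}

#' Synaptic kernel parameters
#'
#' Rise and decay time constants (ms) of the difference-of-exponentials
#' conductance kernel, one pair per presynaptic class. The kernel is
#' normalized so that a single spike injects unit time-integral.
#'
#' @param tau_d_E,tau_r_E Decay / rise time constants of excitatory synapses (ms).
#' @param tau_d_I,tau_r_I Decay / rise time constants of inhibitory synapses (ms).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(tau_d_E = 6, tau_r_E = 1, tau_d_I = 2, tau_r_I = 0.5) {
  stopifnot(
    "excitatory kernel needs decay > rise > 0" = tau_d_E > tau_r_E && tau_r_E > 0,
    "inhibitory kernel needs decay > rise > 0" = tau_d_I > tau_r_I && tau_r_I > 0
  )
  structure(list(tau_d_E = tau_d_E, tau_r_E = tau_r_E,
                 tau_d_I = tau_d_I, tau_r_I = tau_r_I),
            class = "synapse_params")
}

#' External Poisson drive parameters
#'
#' Each neuron receives an independent Poisson spike train entering through an
#' external synapse; rates are in kHz (events per ms) and weights in pF.
#' During training, the stimulated sensory cluster's excitatory rate is
#' replaced by `stim_rate` for `stim_duration` ms.
#'
#' @param W_ext_E,W_ext_I External synaptic strength onto E / I neurons (pF).
#' @param r_ext_E Baseline rate of external input to E neurons (kHz). 5 kHz in
#'   the uniform sampler, 4 kHz in the sensory and read-out networks.
#' @param r_ext_I Rate of external input to I neurons (kHz).
#' @param stim_rate Rate applied to a stimulated cluster during training (kHz).
#' @param stim_duration Duration of a training stimulus (ms).
#' @return An object of class `external_drive`.
#' @export
external_drive <- function(W_ext_E = 1.6, W_ext_I = 1.52,
                           r_ext_E = 5, r_ext_I = 2.25,
                           stim_rate = 30, stim_duration = 50) {
  stopifnot(
    "rates must be non-negative" = r_ext_E >= 0 && r_ext_I >= 0,
    "stimulus rate must not be below the baseline rate" = stim_rate >= r_ext_E,
    "stimulus duration must be positive" = stim_duration > 0
  )
  structure(list(W_ext_E = W_ext_E, W_ext_I = W_ext_I,
                 r_ext_E = r_ext_E, r_ext_I = r_ext_I,
                 stim_rate = stim_rate, stim_duration = stim_duration),
            class = "external_drive")
}

#' Plasticity rule parameters
#'
#' Parameters of the Hebbian + soft-normalization rule acting on the weights
#' from the uniform sampler's excitatory neurons to the sensory network's
#' excitatory neurons. Both neurons are "eligible" when they fired within the
#' last `coincidence_window` ms; coincident eligibility potentiates the weight
#' at rate `A_p` (pF/ms) while each presynaptic neuron's total outgoing weight
#' relaxes toward `K_norm` with time constant `tau_n`, the deficit being
#' shared equally across its outgoing weights. Weights are clipped to
#' `[W_min, W_max]` after every Euler step.
#'
#' `K_norm = NULL` (the default) derives the normalization constant as
#' `W_max` times the number of neurons per sensory cluster, which equals the
#' canonical 500 pF at the full cluster size of 100 and keeps the
#' winner-take-all equilibrium (one fully potentiated cluster per presynaptic
#' neuron) exact at reduced sizes.
#'
#' @param A_p Potentiation amplitude (pF/ms of coincident eligibility).
#' @param K_norm Normalization constant (pF), or `NULL` to derive from the
#'   postsynaptic cluster size.
#' @param tau_n Normalization time constant (ms).
#' @param W_min,W_max Weight bounds (pF).
#' @param coincidence_window Eligibility window (ms).
#' @param enabled If `FALSE` the plastic weights are frozen.
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(A_p = 0.5, K_norm = NULL, tau_n = 100,
                              W_min = 0, W_max = 5,
                              coincidence_window = 15, enabled = TRUE) {
  stopifnot(
    "need W_min <= W_max" = W_min <= W_max,
    "tau_n must be positive" = tau_n > 0,
    "coincidence window must be positive" = coincidence_window > 0,
    "A_p must be non-negative" = A_p >= 0
  )
  structure(list(A_p = A_p, K_norm = K_norm, tau_n = tau_n,
                 W_min = W_min, W_max = W_max,
                 coincidence_window = coincidence_window,
                 enabled = isTRUE(enabled)),
            class = "plasticity_params")
}

#' Short-term plasticity parameters for the read-out synapses
#'
#' Every excitatory sensory neuron j projects to all excitatory read-out
#' neurons with a single effective weight `w_j`. Under depression, each spike
#' of j multiplies `w_j` by `1 - step_fraction` (floored at 0); under
#' facilitation each spike adds `step_fraction * w_j` (capped at `w_cap`).
#' Between spikes the weight relaxes back to `baseline` with time constant
#' `recovery_tau`.
#'
#' @param baseline Baseline read-out weight (pF).
#' @param step_fraction Fractional change per presynaptic spike.
#' @param recovery_tau Recovery time constant (ms).
#' @param mode `"depression"` or `"facilitation"`.
#' @param w_cap Upper bound under facilitation (pF).
#' @param enabled If `FALSE`, read-out weights stay at baseline.
#' @return An object of class `stp_params`.
#' @export
stp_params <- function(baseline = 4, step_fraction = 0.05,
                       recovery_tau = 2000,
                       mode = c("depression", "facilitation"),
                       w_cap = 6, enabled = TRUE) {
  mode <- match.arg(mode)
  stopifnot(
    "step_fraction must be in (0, 1)" = step_fraction > 0 && step_fraction < 1,
    "recovery_tau must be positive" = recovery_tau > 0,
    "baseline must be non-negative" = baseline >= 0
  )
  structure(list(baseline = baseline, step_fraction = step_fraction,
                 recovery_tau = recovery_tau, mode = mode, w_cap = w_cap,
                 enabled = isTRUE(enabled)),
            class = "stp_params")
}

#' Leaky-integrator configuration for decision read-out
#'
#' The decision variable follows
#' `r_t = (1 - dt/tau_r) * r_{t-1} + (dt/tau_r) * f(i, x_t)` on the simulation
#' grid, with `r_0 = 0`.
#'
#' @param tau_r Integration time constant (ms).
#' @param dt Time step (ms).
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(tau_r = 1000, dt = 0.1) {
  stopifnot("tau_r must be positive" = tau_r > 0, "dt must be positive" = dt > 0)
  structure(list(tau_r = tau_r, dt = dt), class = "integrator_config")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  print(unlist(x)); invisible(x)
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("<plasticity_params>",
      if (!x$enabled) "(frozen)" else "", "\n")
  vals <- x
  vals$K_norm <- if (is.null(x$K_norm)) "derived (W_max x cluster size)" else x$K_norm
  print(unlist(vals)); invisible(x)
}
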