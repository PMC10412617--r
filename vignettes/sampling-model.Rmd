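---
title: "Learning and sampling prior distributions in clustered spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning and sampling prior distributions in clustered spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spikesampler)
```

## The model

`spikesampler` simulates a two-network spiking implementation of inverse
transform sampling. Drawing from a discrete distribution $p(x)$ can be done by
drawing $u \sim \mathcal{U}[0,1]$ and returning $F^{-1}(u)$, where $F$ is the
cumulative distribution function. The model maps both steps onto clustered
networks of spiking neurons:

* A **uniform sampler network** of $C$ disjoint clusters of excitatory (E)
  neurons plus one inhibitory (I) pool. Strong within-cluster recurrence and
  lateral inhibition make exactly one cluster active at a time, and strong
  spike-triggered adaptation ($\beta = 100$ pA) fatigues the active cluster so
  that the network switches between clusters at random at a target rate of
  roughly 8 Hz. Each activation is a draw of $u$ discretized to $1/C$.
* A **sensory network** of 8 clusters encoding the discretized external
  variable. Its switches are steered by the uniform sampler through a plastic
  all-to-all weight matrix from uniform-sampler E neurons to sensory E
  neurons. The matrix stores $F^{-1}$: each uniform cluster points (with
  saturated weights) at exactly one sensory cluster, so the probability that
  bin $k$ is active equals $n_k / C$, the fraction of uniform clusters
  assigned to it.

Neurons are adaptive exponential integrate-and-fire (E) and leaky
integrate-and-fire (I) units with conductance-based synapses (difference-of-
exponentials kernel with unit time-integral; weights in pF, conductance traces
in pF/ms so that $g (E_{rev} - V) / C_{mem}$ is in mV/ms). All neuron and
synapse constants are the defaults of `neuron_params()` and
`synapse_params()`; the only constant that differs between sub-networks is
$\beta$ (100 pA in the uniform sampler, 0.805 pA elsewhere).

## Learning rule

The plastic weights follow a Hebbian term with a soft presynaptic
normalization:

$$\frac{dW_{ij}}{dt} = A_p\, y_i\, y_j + \frac{K - \sum_i W_{ij}}{\tau_n},$$

where $y = 1$ for neurons that fired in the last 15 ms and $K$ is the
normalization constant. The same scalar deficit drives every outgoing weight
of a presynaptic neuron, so while a new postsynaptic block is potentiated,
the surplus above $K$ depresses precisely the previously potentiated block
(entries already at the lower bound cannot fall further): probability mass is
re-attributed rather than created. Weights are clipped to
$[W_{min}, W_{max}]$ after every Euler step; with $n$ interior entries the
outgoing sum relaxes to $K$ at rate $n/\tau_n$. An alternative reading that
shares the deficit equally across the outgoing weights (sum relaxing at rate
$1/\tau_n$) was implemented first and rejected: with most entries clipped at
zero, the shared deficit is largely wasted on entries that cannot move, old
assignments erode an order of magnitude more slowly, and re-learning after a
distribution switch stalls. $K$ is derived as $W_{max}$ times the sensory cluster size (500 pF at
the full size of 100 neurons), which makes the winner-take-all state — one
fully saturated block per presynaptic neuron — an exact fixed point.

During training, a sample $x_k$ is presented every 200 ms by driving sensory
cluster $x_k$ with 30 kHz external input for 50 ms. The uniform cluster that
happens to be active potentiates its connections onto the stimulated cluster
("one-shot"), and normalization subsequently depresses that cluster's old
assignment — each observation re-attributes $1/C$ of probability mass.

Two unit conventions required a decision:

* **Potentiation amplitude.** $A_p$ is interpreted as 0.5 pF/ms of coincident
  eligibility. The functional constraint is that a single 50 ms pairing must
  saturate a weight ($W_{max} = 5$ pF); a pF/Hz reading would change weights
  by only ~0.03 pF per pairing and could not learn in one shot. An amplitude
  multiplier remains exposed in `plasticity_params()`.
* **Normalization sharing.** The deficit $K - \sum_i W_{ij}$ enters each
  outgoing weight in full, as written above; the test suite verifies the
  resulting relaxation of the outgoing sum against its scalar closed form,
  and a per-update cap keeps a column sum from crossing $K$ when the update
  is subsampled.

## Calibration of the operating point

The model's external Poisson drives are calibration knobs, not first
principles: the drive to the uniform sampler is tuned so that cluster
switching runs at the target rate (about 8 Hz), which also makes successive
200 ms observations see approximately independent uniform draws. In this
implementation, a drive of **4.35 kHz** (with the standard 1.6 pF external
synapses) produces clean metastable switching at 7–9 Hz for $C = 24$ with
100-neuron clusters (decoded-cluster dominance ≈ 0.99 of excitatory spikes);
5 kHz produces equally clean but slower (~2 Hz) switching, and below ~4.2 kHz
the network falls out of the active regime. The calibration was done once on
10 s runs across seeds and is the package default for the uniform sampler;
the sensory and read-out networks keep their 4 kHz drive, preserving the
design constraint that the sensory drive is slightly lower because it also
receives excitatory input from the uniform sampler. A halved integration step
leaves the switching rate unchanged, so the operating point is a property of
the dynamics, not of the integrator.

**Reduced sizes.** Networks can be built at reduced cluster sizes for quick
experiments. All recurrent weights (and the plastic/read-out weight scales)
are then multiplied by $\sqrt{100 / n_\text{per cluster}}$ — the same
square-root-of-size rule the architecture already uses across networks. At 50
neurons per cluster this restores the full-scale switching statistics, but
the *plasticity-on* steady state is not reliable below full scale: with few
within-cluster connections the sensory network follows the uniform sampler
less faithfully, and mis-attributed coincidences can make the stored
distribution collapse onto a single bin within tens of seconds. The
quantitative experiments in this package therefore run at the full scale
(100 neurons per cluster); reduced sizes are for smoke tests and unit tests.

## Target distributions

The four canonical 8-bin shapes (`target_distribution()`) are: uniform;
biased (70% of the mass on bins 1–4); unimodal (Binomial(7, 1/2), a symmetric
centre-peaked shape); and bimodal (an equal mixture of Binomial(3, 1/2) on
bins 1–4 and on bins 5–8). The two symmetric shapes have mean 4.5, so the
history-bias probe input $i = 4.5$ sits at the long-term mean, and the
unimodal shape concentrates more mass between inputs 3.5 and 5.5 than the
bimodal one, so its psychometric slope is steeper.

## Decision read-out and analyses

Samples are decoded from sensory spikes by convolving each cluster's spike
counts with a Gaussian ($\sigma$ = 20 ms, symmetric, truncated at $4\sigma$,
edge-renormalized), averaging within clusters and taking the per-step argmax;
exact ties keep the previous label, and label runs shorter than 5 ms are
absorbed before counting switches (both guards suppress decoder chatter; the
5 ms threshold is configurable). The decision variable integrates the
indicator $f(i, x) = \pm 1$ with a leaky integrator ($\tau_r = 1$ s) on the
simulation grid; inputs $i$ are restricted to half-integers so $f$ is never
evaluated at $i = x$. For an ideal sampler the long-run output is
$2F(i) - 1$, which the test suite verifies, together with the two
decision-time properties: the normalized slope of the psychometric curve is
invariant to decision time while its normalized variability decreases.

In the history experiments the sample stream pauses during each 2 s decision
probe (pausing keeps "the last five samples" well defined), and plasticity
remains active during probes unless the frozen control is requested. Outputs
are min–max normalized to [0, 1] across the probes of a run.

The short-term-plasticity read-out uses one effective weight per sensory E
neuron (the read-out connectivity is uniform, so a single shared conductance
drives all read-out E cells): depression multiplies the weight by 0.95 at
each presynaptic spike (floor 0), recovery has $\tau$ = 2 s, facilitation
multiplies by 1.05 (cap 6 pF). The facilitation variant relaxes toward the
baseline rather than zero — the depression rule explicitly recovers to
baseline, and a decay to zero would make facilitation non-stationary — which
preserves the intended contrast (read-out rate increasing instead of
decreasing with stored probability).

## Numerical choices

* Forward Euler at $\Delta t = 0.1$ ms (configurable; convergence checked at
  halved steps). Derivatives use start-of-step values throughout.
* Spikes are detected after the update, stamped at the end of the step, and
  reach postsynaptic kernel traces one step later.
* The AdEx exponential argument is capped (at 50) and the membrane clamped
  just above the 20 mV detection cutoff, so the spike blow-up stays finite
  between detection checks.
* During the 5 ms refractory period the membrane is clamped at the reset
  potential while the adaptive threshold, the adaptation current, and the
  synaptic traces keep evolving (linearity of the conductances is exact).
* Initial potentials are drawn uniformly between reset and threshold to avoid
  startup synchrony.
* The plasticity update is subsampled (every 1 ms by default, against time
  constants of 100 ms and a 15 ms eligibility window); columns without
  presynaptic eligibility only relax toward $K$ and are updated on a 10×
  coarser grid. Setting `plast_every = 1` gives the exact per-step rule, and
  the compiled path is verified trajectory-for-trajectory against a plain-R
  reference stepper in that mode.
* Initial cluster assignments use largest-remainder rounding of $C p_k$ with
  ties to the lowest bin.

## What the simulations do and do not show

The synthetic experiments reproduce the model's study conditions: i.i.d.
sample streams at 5 Hz from known 8-bin distributions, spontaneous sampling
epochs, decision probes evaluated mathematically on decoded cluster labels,
and a cluster-level reference chain (the `oracle_*` functions) in which each
observation reassigns one uniformly chosen cluster. Passing tests show the
spiking implementation matches this discrete picture in its stationary
statistics (assignment fractions, psychometric curves, forgetting scale) —
they do not show anything about real neural data: stimuli are noiseless
labels, clusters are hard-wired and disjoint, and the decision stage is a
mathematical integrator, not a circuit.

Known limitations worth keeping in mind:

* At $C = 24$ the stationary stored distribution fluctuates strongly (the
  discrete reference chain itself has a stationary L1 error of ~0.4 for the
  bimodal target); single runs wander visibly around the target.
* The plasticity-on steady state degrades below full cluster size (see
  above).
* History-bias estimates are statistically demanding: a 2 s decision
  integrates only ~16 effective samples, so at ~100 probes the span estimate
  carries a standard error of 10–14 percentage points of the output range.
* The short-term bias in this implementation is stronger than a few percent:
  the weight-level regression (noise-free, snapshots instead of decision
  probes) puts its span at ~20% of the output range. One likely contributor
  is the protocol choice to pause the sample stream during each decision,
  which preserves the recent-history perturbation of the weights through the
  whole probe; a protocol in which sampling continues during decisions would
  let it partially wash out and would measure a smaller span.
* With ongoing plasticity, pure replay slowly re-mixes the stored
  distribution; over minutes this is a random walk constrained by
  normalization, visible as the stationary fluctuation band.

## Problem sizes used by the tests and the acceptance script

Unit tests run miniature networks (3–4 clusters of 8–15 neurons). The
quantitative experiments use the full-scale model: a 25 s spontaneous run of
the C = 24 uniform sampler for the switching rate; three seeds of a
200-sample distribution switch (unimodal to bimodal, probes every 5th
sample, 1.5 s decisions) for the forgetting scale, summarized by the
settling estimator of
`slope_settling()` (seed-averaged series, centered width-5 moving average,
one-sided entry into the tail band); and a 550-sample steady-state bimodal
stream with 2 s probes at $i = 4.5$ for the history bias, plus a
frozen-plasticity control. In this implementation the measured forgetting
scale sits at the slow edge of (or slightly beyond) the expected ~100
samples, consistent with per-observation attribution below the idealized
$1/C$ (eligibility covers only part of the active uniform cluster during a
50 ms stimulus). Decision probes start 300 ms after the last
sample of a block so that stimulus-evoked activity has dissipated; the
frozen-plasticity control validates this choice (without the gap the control
shows a spurious output-history correlation carried by lingering attractor
activity rather than by the weights).
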