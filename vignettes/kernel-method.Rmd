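---
title: "Predicting LFP and EEG from population firing rates: the kernel method and its error"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting LFP and EEG from population firing rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(popkernel)
```

## The model

Extracellular brain signals — the local field potential (LFP) recorded at
depth and the EEG recorded outside the scalp — are generated by the
transmembrane currents that follow synaptic input to geometrically aligned
pyramidal cells. Because volume conduction is linear, the compound signal of
a population is the superposition of every individual postsynaptic
contribution. For passive cells with static current-based synapses each
action potential of a presynaptic neuron $j$ evokes the same spatiotemporal
response, so the compound signal can be written from the *presynaptic
perspective*

$$V(r,t) = \sum_{j=1}^{N_\mathrm{pre}} (k_j(r) * s_j)(t),$$

where $s_j$ is the spike train of presynaptic cell $j$ and the *single-cell
kernel* $k_j(r,t) = \sum_i h_{ij}(r,t)$ sums the responses of all of $j$'s
postsynaptic targets. This sum is the package's ground truth
(`ground_truth_signal()`).

If all kernels were identical they would equal the population mean
$\bar k = N_\mathrm{pre}^{-1}\sum_j k_j$, and the signal would be exactly
$\tilde V(r,t) = (\bar k(r) * R)(t)$ with $R(t)$ the summed population rate.
In reality kernels are only statistically similar, so the *kernel
approximation* (`kernel_approx_signal()`) carries an error. The error is
quantified as $E^2(r) = \mathrm{Var}_t[V - \tilde V]$ and, relative to the
signal, $E^2_\mathrm{rel}(r) = E^2(r) / \max_r \mathrm{Var}_t[V]$
(`empirical_error()`; the max-over-contacts normalization avoids huge but
irrelevant relative errors at near-silent contacts — a single-channel
"per-signal" mode is provided for the toy model).

The expected error follows from second-order statistics alone
(`expected_squared_error()`):

$$\langle E^2(r)\rangle = (N_\mathrm{pre}-1)\int d\tau\,
  (A_k(r,\tau) - C_k(r,\tau))\,(A_s(\tau) - C_s(\tau)),$$

with $A_k, C_k$ the lag-integrated auto- and cross-correlations of the
kernels (`kernel_correlations()`) and $A_s, C_s$ the population-averaged
spike-train auto- and cross-covariance densities
(`estimate_spike_covariances()`). The error vanishes when all kernels are
identical ($A_k = C_k$) or all neurons spike identically ($A_s = C_s$); it
grows with kernel heterogeneity and shrinks with spike-train correlation.
The matching relative-error expression (`expected_relative_error()`)
divides by the expected ground-truth variance
$N_\mathrm{pre}\int A_k A_s + N_\mathrm{pre}(N_\mathrm{pre}-1)\int C_k C_s$.

## Spike-train generators

Three generators supply controlled presynaptic statistics:

* `generate_poisson()` — independent homogeneous Poisson trains.
* `generate_mip()` — the multiple-interaction process: a Poisson mother
  train at rate $\nu$ is thinned per spike with probability $f$ into each
  child, topped up with an independent Poisson train at $(1-f)\nu$. Every
  child has rate $\nu$ and every pair has count correlation $c = f^2$; the
  covariance densities are exactly $A_s = \nu\delta(\tau)$,
  $C_s = f^2\nu\delta(\tau)$, which `mip_spike_covariances()` carries in
  analytic form so the theory integrals involve no bin-width artifacts.
* `simulate_brunel()` — a sparse balanced network of leaky
  integrate-and-fire neurons with delta synapses (classical parameters:
  10,000 excitatory and 2,500 inhibitory cells, in-degrees 1,000/250,
  $\tau_m = 20$ ms, $\theta = 20$ mV, reset 10 mV, refractory 2 ms, delay
  1.5 ms, 0.1 ms resolution), delivering the asynchronous-irregular
  (`g = 5, eta = 2`) and slow synchronous-irregular (`g = 4.5, eta = 0.9`)
  regimes. A 500 ms warm-up is discarded (the transient handling is
  configurable; 500 ms is several membrane and synaptic time scales). The
  `"test"` preset shrinks the network five-fold with `J` scaled by the
  in-degree ratio, which preserves the mean drives and hence the regime
  map; finite-size correlations are then larger, so quantitative
  correlation checks use the full-scale network.

The MIP is implemented as independent per-spike thinning (not exact-count
subsampling) because that construction yields $c = f^2$ exactly, and the
child background rate is $(1-f)\nu$ so the total child rate is $\nu$ in
expectation.

## Biophysical kernels

Kernels for a cortical layer-5 population are built from a passive
multicompartment model coupled to volume-conductor forward models:

* **Morphology** (`build_stylized_l5()`): a programmatically generated,
  seeded stylized pyramidal cell (~170 segments: basal bush, ~1 mm apical
  trunk with obliques, apical tuft). It is a synthetic stand-in, not a
  reconstruction: what the population-level analysis needs is the
  basal/apical input asymmetry, the ~1.2–1.3 mm depth extent and a
  realistic segment graph, all of which it provides. Exact kernel
  waveforms therefore differ from any particular reconstructed cell, and
  the package's checks are property-based (polarity, scaling laws,
  theory/simulation agreement) rather than waveform-matching.
* **Cable dynamics** (`solve_passive()`): linear compartmental dynamics
  with passive parameters $R_m = 30\,\mathrm{k\Omega\,cm^2}$,
  $C_m = 1\,\mathrm{\mu F/cm^2}$, $R_a = 150\,\mathrm{\Omega\,cm}$ (typical
  cortical pyramidal values), integrated with the Crank–Nicolson scheme at
  $2^{-4}$ ms. Crank–Nicolson is unconditionally stable, exactly linear,
  and second order — a first-order implicit scheme at this step size could
  not meet the package's own 0.1% single-compartment oracle. Transmembrane
  currents are evaluated as the net axial inflow, so they sum to zero
  across segments to machine precision by construction.
* **Forward models**: the line-source closed form for every dendritic
  segment (soma as a point source) in an infinite homogeneous medium with
  $\sigma = 0.3$ S/m, 16 contacts at 100 µm spacing spanning depths 0 to
  −1500 µm (chosen so both the soma layer at −1270 µm and the tufts lie
  inside the span); the current dipole moment
  $p(t) = \sum_n I_n(t)\,r_n$; and the analytical four-sphere head model
  (brain/CSF/skull/scalp radii 79/80/85/90 mm, conductivities
  0.3/1.5/0.015/0.3 S/m — standard published values) evaluated at a scalp
  electrode directly above the population, where by symmetry only the
  radial dipole component contributes. Each spherical-harmonic order is
  solved as a well-scaled 7×7 boundary system and the series is truncated
  adaptively with a convergence check.
* **Population sampling** (`sample_population_realization()`): per
  presynaptic neuron, `k_out` (default 500) postsynaptic cells with soma
  depths from a capped normal (mean −1270 µm, SD 100 µm, truncated at
  ±2 SD so no cell protrudes from the cortex; the cap bound is a package
  choice), horizontal positions uniform on a disc of radius 250 µm, and a
  random rotation about the vertical axis. Each target cell receives one
  synapse whose segment is drawn depth-weighted by a normal profile
  (default mean −1270 µm, SD 100 µm — basal input; −200 µm for apical), or
  uniformly over segments for the "uniform" case ("uniform" is defined
  over the morphology, not by a fitted normal). Weights are lognormal with
  distribution mean 0.1 nA and shape $s = 0.4$ (the scale parameter is
  solved from the mean; the alternative reading of "mean" as the scale
  parameter changes amplitudes by only $e^{s^2/2} \approx 8\%$). Time
  constants and delays are normal, $\tau_\mathrm{syn} \sim N(2, 0.2)$ ms
  (the mean is a package default — typical excitatory current decay — as
  only the SD is standard) and delay $\sim N(1, 0.2)$ ms, floored at
  0.1 ms and 0 ms respectively to keep the model well-posed.

Building a kernel calls the cable solver once per *segment*, not per
synapse: `segment_propagator()` caches the discrete impulse response of
every segment, and each synapse's contribution is the convolution of that
response with its own exponential current, scaled by $J$ and shifted by its
delay (rounded to the lag grid). Because the discretized system is linear
and time invariant this cached path reproduces the direct simulation to
floating-point accuracy — asserted in the tests — which is what makes banks
of 50–100 kernels with hundreds of synapses each tractable.

## Numerical conventions

* Spikes are binned as unit impulses on the kernel grid before convolution;
  sub-bin timing is not interpolated. Population rates divide counts by the
  bin width (spikes/ms).
* Convolutions use FFTs with causal padding; exactness against direct
  summation is asserted in tests.
* Variances are the population (1/N) convention in both numerators and
  denominators, so ratios are estimator-free.
* Discrete lag integrals are $\sum \cdot \Delta\tau$; analytic MIP delta
  covariances are applied exactly rather than as $1/\Delta\tau$ bin spikes.
* Covariance and correlation estimators subtract means and average over all
  ordered pairs (computed via the pair-sum FFT identity); they match
  brute-force nested-loop oracles exactly on tiny ensembles.
* The pairwise count-correlation standard error uses a delete-one-window
  jackknife: correlated ensembles share the mother process, so the naive
  pair-count SE would be far too small.
* Line/point sources clamp the source–contact distance at 5 µm to avoid
  the $1/r$ singularity.
* The theory's relative error defaults to the same max-over-contacts
  normalization as the empirical measure (a per-channel mode exists; the
  multi-contact convention is also applied to the theory so the two columns
  of a sweep are comparable).

## The rate model

`integrate_rate_model()` integrates the exact mean-field description of an
all-to-all QIF population,
$\tau^2\dot r = \Delta/\pi + 2\tau v r$,
$\tau\dot v = v^2 + J\tau r + \eta + I(t) - \pi^2\tau^2 r^2$,
with a fixed-step 4th-order Runge–Kutta scheme (default $dt = \tau/1000$;
determinism is wanted for tests and the dynamics are only mildly stiff).
Endpoint stages sample just inside each step so grid-aligned square-pulse
edges do not degrade the order. The bistable-switching preset uses
$\Delta = 2$, $\eta = -10$, $\tau = 100$ ms and $J = 15\sqrt\Delta$: with
the model's scaling invariance the stated $\eta = -5\Delta$ pins the
bistable regime at $J \propto \sqrt\Delta$, so the occasionally quoted
$J = 15\Delta$ reads like a typeset loss of a radical; both values are
shipped as presets (both happen to be bistable, with different high-branch
rates). `rate_to_brain_signal()` converts the rate from s⁻¹ to expected
spikes per time step, scales by the assumed presynaptic population size,
and convolves with a population kernel — the same operation as the kernel
approximation applied to binned spikes.

## What the generators emulate — and what they do not

The synthetic spike ensembles reproduce controlled second-order statistics
(rates, delta-shaped or network-shaped correlations); real spike trains
carry rate nonstationarities, higher-order correlations and refractory
structure that the theory deliberately ignores. The stylized cell
reproduces input-region asymmetry, not any specific reconstructed
morphology; conductance-based synapses, active dendrites, extracellular
spikes and inhomogeneous media are out of scope (the linearity assumption
is what makes the single-cell kernel well defined in the first place).
Passing tests therefore certify the kernel-method mathematics and the
implementation's physics, not the fidelity of any particular cortical
model.

## Problem sizes used by the test suite

The packaged checks run the toy theory/simulation grid with 1000-kernel
banks, 20 s MIP ensembles and 20 kernel redraws per cell; biophysical
scaling and heterogeneity experiments with 50-kernel banks at out-degrees
100–500 (10 s of uncorrelated input, 6 s for the config × spike-type
sweep); and the full-scale balanced network for 2 s when checking its
correlation structure. These sizes give Monte-Carlo errors comfortably
inside the asserted tolerances while keeping the whole suite in the
ten-minute range.

## Known limitations

* One synapse per connection; composite multi-synapse contacts would scale
  amplitudes but not change the error structure.
* Delays are realized on the kernel lag grid ($2^{-4}$ ms), so sub-grid
  delay dispersion is quantized.
* The four-sphere EEG is evaluated at the vertex electrode only; off-axis
  electrodes would need the tangential-component series as well.
* The error theory is second order: ensembles with strong higher-order
  structure (bursting, network oscillations) are handled only through
  their measured second-order covariances.
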