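# popkernel

Population rate-to-LFP/EEG kernels and a predictive theory for their
accuracy.

## The problem

Local field potentials (LFP) and EEG are generated by the spatially
distributed membrane currents of pyramidal-cell populations. Point-neuron
networks and firing-rate models — the workhorses of population-level
simulation — carry no spatial information, so these signals cannot be
computed from them directly. The *kernel method* closes the gap: compute,
once, the average extracellular response to a single presynaptic spike for
each synaptic pathway (the population kernel k̄), then predict the signal
by convolving k̄ with the population firing rate,

    V̂(r,t) = (k̄(r) ∗ R)(t),    k̄ = (1/N_pre) Σ_j k_j,

where the single-cell kernel k_j sums the responses h_ij of all
postsynaptic targets of cell j. The ground truth in the fully linear
setting is V(r,t) = Σ_j (k_j ∗ s_j)(t) with s_j the individual spike
trains. The approximation is exact when all kernels are identical or all
trains are identical; in between, its expected squared error is

    ⟨E²(r)⟩ = (N_pre − 1) ∫ dτ (A_k − C_k)(r,τ) · (A_s − C_s)(τ),

a product of kernel heterogeneity (auto- minus cross-correlation of the
kernels) and spike-train decorrelation (auto- minus cross-covariance of
the trains). This package is for computational neuroscientists who want to
(a) generate such kernels — from a parametric toy family or from passive
multicompartment simulations of a stylized layer-5 population with
line-source LFP, current-dipole and four-sphere EEG forward models —
(b) synthesize ground-truth and kernel-approximated signals from
controlled spike ensembles (Poisson, multiple-interaction processes, a
balanced LIF network), and (c) predict the approximation error before
ever running the expensive simulation.

## Worked example

```r
library(popkernel)
# 200 single-cell kernels: double-exponential, amplitudes ~ N(1.0, 0.5) uV
bank <- sample_toy_bank(toy_kernel_params(amp_mean = 1, amp_sd = 0.5),
                        n = 200, seed = 1)
# correlated presynaptic spiking: MIP, 10 s^-1, c = f^2 = 0.01, 10 s
spikes <- generate_mip(rate = 10, f = 0.1, duration = 10000,
                       n_trains = 200, seed = 2)
V    <- ground_truth_signal(bank, spikes)     # sum_j k_j * s_j
Vhat <- kernel_approx_signal(bank, spikes)    # kbar * R
err  <- empirical_error(V, Vhat, mode = "per_signal")
theo <- expected_relative_error(kernel_correlations(bank),
                                mip_spike_covariances(10, 0.1),
                                n_pre = 200, mode = "per_signal")
round(c(E_sim = err$E, E_theory = theo$E,
        E_rel_sim = err$E_rel, E_rel_theory = theo$E_rel), 4)
#>        E_sim     E_theory    E_rel_sim E_rel_theory
#>       0.6351       0.6293       0.2672       0.2534
```

The simulated error of the rate-based prediction (0.64 µV absolute, 27% of
the signal's standard deviation) agrees with the analytical expectation
computed purely from the kernel bank's second-order statistics and the
spike generator's analytic covariances — no signal synthesis needed. The
spike ensemble itself behaves as designed:

```r
cc <- count_correlation(spikes)
round(c(corr = cc$mean, se = cc$se), 4)
#>   corr     se
#> 0.0083 0.0019
```

the pairwise count correlation sits at the multiple-interaction-process
value c = f² = 0.01 within its jackknife standard error.

Biophysical banks work the same way: `build_kernel_bank(
population_config())` returns per-presynaptic-cell LFP kernels on a
16-contact depth profile plus scalp EEG kernels, `run_sweep()` drives
whole configuration × spike-statistics grids, and `integrate_rate_model()`
plus `rate_to_brain_signal()` turn a mean-field QIF rate trace into LFP
and EEG. See the vignette (`vignettes/kernel-method.Rmd`) for the model
details and numerical conventions.

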