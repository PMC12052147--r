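#' Spike-ensemble specifications for sweeps
#'
#' @param type `"poisson"`, `"mip"` or `"brunel"`.
#' @param rate firing rate (s^-1) for Poisson/MIP.
#' @param f MIP copy probability.
#' @param g,eta balanced-network regime parameters for `"brunel"`.
#' @param preset network-size preset for `"brunel"`.
#' @return a `spike_spec` list.
#' @export
spike_spec <- function(type = c("poisson", "mip", "brunel"), rate = 10,
                       f = 0, g = 5, eta = 2, preset = "test") {
  type <- match.arg(type)
  structure(list(type = type, rate = rate, f = f, g = g, eta = eta,
                 preset = preset), class = "spike_spec")
}

.make_spikes <- function(spec, n_trains, duration, seed) {
  switch(spec$type,
    poisson = generate_poisson(spec$rate, duration, n_trains, seed = seed),
    mip = generate_mip(spec$rate, spec$f, duration, n_trains, seed = seed),
    brunel = simulate_brunel(brunel_params(
      g = spec$g, eta = spec$eta, preset = spec$preset,
      duration = duration, n_record = n_trains, seed = seed)))
}

.theory_spike_cov <- function(spec, spikes, dt, max_lag) {
  if (spec$type %in% c("poisson", "mip"))
    mip_spike_covariances(spec$rate, if (spec$type == "mip") spec$f else 0)
  else
    estimate_spike_covariances(spikes, binsize = dt,
                               max_lag = min(max_lag,
                                             spikes$duration / 2 - dt))
}

#' Sweep kernel configurations against spike-train ensembles
#'
#' For every (kernel bank, spike specification) pair: generates the spike
#' ensemble, computes the ground-truth and population-kernel signals, the
#' empirical error measures, and the theoretical error predicted from the
#' bank's kernel correlations and the ensemble's spike covariances
#' (analytic delta covariances for Poisson/MIP, estimated covariances for
#' network spikes). Amplitude is the ground-truth standard deviation over
#' time per channel.
#'
#' @param banks named list of [kernel_bank()]s (one per configuration).
#' @param spike_specs named list of [spike_spec()]s.
#' @param duration spike-train duration (ms).
#' @param seed integer seed; each (bank, spec) pair gets a distinct derived
#'   seed.
#' @param mode relative-error normalization (see [empirical_error()]).
#' @return data.frame with one row per (config, spike spec, channel):
#'   columns `config`, `spikes`, `channel`, `channel_z`, `amplitude`, `E`,
#'   `E_rel`, `th_E`, `th_E_rel`.
#' @export
run_sweep <- function(banks, spike_specs, duration = 10000, seed = 1,
                      mode = "max") {
  stopifnot(is.list(banks), is.list(spike_specs))
  rows <- list()
  combo <- 0L
  for (bn in names(banks)) {
    bank <- banks[[bn]]
    kc <- kernel_correlations(bank)
    for (sn in names(spike_specs)) {
      combo <- combo + 1L
      spec <- spike_specs[[sn]]
      spikes <- .make_spikes(spec, bank$n_kernels, duration,
                             seed = seed + 1000L * combo)
      V <- ground_truth_signal(bank, spikes)
      Vhat <- kernel_approx_signal(bank, spikes)
      err <- empirical_error(V, Vhat, mode = mode)
      sc <- .theory_spike_cov(spec, spikes, bank$dt,
                              max_lag = max(kc$lags))
      th <- expected_relative_error(kc, sc, bank$n_kernels, mode = mode)
      nch <- bank$n_channels
      rows[[length(rows) + 1L]] <- data.frame(
        config = bn, spikes = sn, channel = seq_len(nch),
        channel_z = if (!is.null(bank$channels)) bank$channels else NA_real_,
        amplitude = err$sd_ground_truth,
        E = err$E, E_rel = err$E_rel, th_E = th$E, th_E_rel = th$E_rel)
    }
  }
  do.call(rbind, rows)
}
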