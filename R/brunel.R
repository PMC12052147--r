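#' Parameters for the balanced random LIF network
#'
#' Sparse random network of excitatory and inhibitory leaky integrate-and-fire
#' neurons with instantaneous (delta) current jumps, following the classical
#' balanced-network setup: relative inhibition strength `g`, external drive
#' `eta` (in units of the rate needed to reach threshold), synaptic efficacy
#' `J` (mV), fixed in-degrees `c_e`/`c_i`, transmission delay, and standard
#' membrane constants.
#'
#' The `"full"` preset is the classical network (10,000 excitatory + 2,500
#' inhibitory neurons, in-degrees 1,000/250). The `"test"` preset scales the
#' network to 2,000 + 500 neurons with in-degrees 200/50 and rescales `J` by
#' `1000/200` so the mean recurrent and external drives — and hence the
#' regime map over `(g, eta)` — are preserved; input fluctuations and
#' pairwise correlations are larger than at full scale (finite-size
#' effects), so quantitative correlation statistics should use `"full"`.
#'
#' Classical regimes: asynchronous irregular `g = 5, eta = 2.0, J = 0.1`;
#' slow synchronous irregular `g = 4.5, eta = 0.9, J = 0.1`.
#'
#' @param g relative inhibitory strength (> 0).
#' @param eta external drive relative to threshold rate (> 0).
#' @param J synaptic efficacy (mV, > 0); rescaled internally for the
#'   `"test"` preset.
#' @param preset `"full"` or `"test"` network size.
#' @param duration simulated time after warm-up (ms).
#' @param warmup discarded initial transient (ms).
#' @param delay transmission delay (ms).
#' @param tau_m,theta,v_reset,t_ref membrane time constant (ms), threshold
#'   (mV), reset (mV), refractory period (ms).
#' @param dt simulation time step (ms), default 0.1.
#' @param n_record number of excitatory neurons whose spike trains are kept.
#' @param seed integer seed.
#' @return an object of class `brunel_params`.
#' @export
brunel_params <- function(g = 5, eta = 2.0, J = 0.1,
                          preset = c("test", "full"),
                          duration = 2000, warmup = 500,
                          delay = 1.5, tau_m = 20, theta = 20, v_reset = 10,
                          t_ref = 2, dt = 0.1, n_record = 100, seed = 1) {
  preset <- match.arg(preset)
  if (g <= 0 || eta < 0 || J <= 0) stop("g, J must be > 0 and eta >= 0")
  dims <- if (preset == "full")
    list(n_e = 10000L, n_i = 2500L, c_e = 1000L, c_i = 250L, j_scale = 1)
  else
    list(n_e = 2000L, n_i = 500L, c_e = 200L, c_i = 50L,
         j_scale = 1000 / 200)
  structure(c(list(g = g, eta = eta, J = J, preset = preset,
                   duration = duration, warmup = warmup, delay = delay,
                   tau_m = tau_m, theta = theta, v_reset = v_reset,
                   t_ref = t_ref, dt = dt, n_record = n_record, seed = seed),
              dims),
            class = "brunel_params")
}

#' Simulate the balanced LIF network
#'
#' Integrates the network with the exact subthreshold propagator at time step
#' `dt`, discards the warm-up window, and returns the spike trains of the
#' first `n_record` excitatory neurons. The external Poisson drive per neuron
#' has rate `eta * nu_thr * c_e`, where `nu_thr = theta / (J * c_e * tau_m)`
#' is the rate at which the external input alone reaches threshold.
#'
#' @param params a [brunel_params()].
#' @return a [spike_train_set()]; attribute `rate_hz` carries the mean
#'   excitatory population rate.
#' @export
simulate_brunel <- function(params) {
  stopifnot(inherits(params, "brunel_params"))
  p <- params
  set.seed(p$seed)
  J_eff <- p$J * p$j_scale
  nu_thr <- p$theta / (J_eff * p$c_e * p$tau_m)      # per ms per input
  nu_ext <- p$eta * nu_thr * p$c_e                   # summed external, per ms
  steps <- as.integer(round((p$duration + p$warmup) / p$dt))
  delay_steps <- max(1L, as.integer(round(p$delay / p$dt)))
  res <- brunel_cpp(p$n_e, p$n_i, p$c_e, p$c_i, J_eff, p$g, nu_ext,
                    delay_steps, p$dt, steps, p$tau_m, p$theta, p$v_reset,
                    as.integer(round(p$t_ref / p$dt)), p$n_record)
  keep <- res$times >= p$warmup
  times <- res$times[keep] - p$warmup
  ids <- res$ids[keep]
  # mean excitatory rate after warm-up, for stability flagging
  w0 <- as.integer(round(p$warmup / p$dt))
  rate_hz <- sum(res$e_count[(w0 + 1):steps]) / p$n_e / (p$duration / 1000)
  if (rate_hz > 400)
    stop("network rate diverged (", round(rate_hz), " s^-1); ",
         "unstable parameters")
  trains <- lapply(seq_len(p$n_record), function(i) times[ids == i])
  out <- spike_train_set(
    trains, p$duration,
    provenance = list(generator = "brunel", g = p$g, eta = p$eta, J = p$J,
                      preset = p$preset, seed = p$seed))
  attr(out, "rate_hz") <- rate_hz
  out
}
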