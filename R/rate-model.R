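#' Parameters of the QIF mean-field rate model
#'
#' Two-dimensional firing-rate model that is the exact macroscopic limit of
#' an all-to-all coupled population of quadratic integrate-and-fire neurons
#' with Lorentzian-distributed inputs:
#' `tau^2 dr/dt = Delta/pi + 2 tau v r` and
#' `tau dv/dt = v^2 + J tau r + eta + I(t) - pi^2 tau^2 r^2`,
#' with `r` the population rate and `v` the mean membrane potential.
#'
#' The bistable-switching preset uses `Delta = 2`, `eta = -10`,
#' `J = 15 sqrt(Delta)` and `tau = 100 ms`, with a square current pulse of
#' amplitude 4 starting at 1 s for 3 s.
#'
#' @param tau membrane time constant (ms).
#' @param Delta half-width of the Lorentzian input distribution.
#' @param eta center of the input distribution.
#' @param J recurrent coupling strength.
#' @param stim_amp,stim_onset,stim_duration square stimulus pulse: amplitude
#'   (model units), onset and duration (ms).
#' @param dt integration step (ms); default `tau / 1000`.
#' @param T total integrated time (ms).
#' @param r0,v0 initial state (`r0` in model units of 1/ms, must be >= 0).
#' @param relax pre-relaxation time at `I = 0` before `t = 0` (ms), so the
#'   trace starts from the low-activity attractor.
#' @return an object of class `rate_model_params`.
#' @export
rate_model_params <- function(tau = 100, Delta = 2, eta = -10,
                              J = 15 * sqrt(2),
                              stim_amp = 0, stim_onset = 0,
                              stim_duration = 0,
                              dt = tau / 1000, T = 6000,
                              r0 = 1e-3, v0 = -1, relax = 1000) {
  if (tau <= 0 || Delta < 0 || dt <= 0 || T <= 0 || r0 < 0)
    stop("need tau > 0, Delta >= 0, dt > 0, T > 0, r0 >= 0")
  structure(as.list(environment()), class = "rate_model_params")
}

#' Preset: stimulus-induced bistable switching
#'
#' @param J_printed use the literal coupling `J = 15 * Delta` instead of the
#'   bistable-regime value `J = 15 * sqrt(Delta)`.
#' @param ... overrides passed to [rate_model_params()].
#' @export
rate_model_preset_switching <- function(J_printed = FALSE, ...) {
  J <- if (J_printed) 15 * 2 else 15 * sqrt(2)
  args <- utils::modifyList(
    list(tau = 100, Delta = 2, eta = -10, J = J, stim_amp = 4,
         stim_onset = 1000, stim_duration = 3000, T = 6000),
    list(...))
  do.call(rate_model_params, args)
}

#' Integrate the QIF mean-field rate model
#'
#' Deterministic fixed-step 4th-order Runge-Kutta integration. The model is
#' first relaxed for `relax` ms without stimulus; the returned trace starts
#' at `t = 0` from the relaxed state. Integration aborts with an error
#' naming the step if the membrane potential diverges.
#'
#' @param p a [rate_model_params()].
#' @return An object of class `rate_trace`: data.frame with `t` (ms), `r`
#'   (firing rate, s^-1) and `v` (model units). The raw model-unit rate
#'   (1/ms) is `r` divided by 1000.
#' @export
integrate_rate_model <- function(p) {
  stopifnot(inherits(p, "rate_model_params"))
  tau <- p$tau; Delta <- p$Delta; eta <- p$eta; J <- p$J
  deriv <- function(r, v, I) {
    c((Delta / pi + 2 * tau * v * r) / tau^2,
      (v^2 + J * tau * r + eta + I - pi^2 * tau^2 * r^2) / tau)
  }
  dt <- p$dt
  n_relax <- as.integer(round(p$relax / dt))
  n <- as.integer(round(p$T / dt)) + 1L
  stim <- function(t) {
    if (p$stim_amp != 0 && t >= p$stim_onset &&
        t < p$stim_onset + p$stim_duration) p$stim_amp else 0
  }
  step <- function(r, v, t, I_fun) {
    # endpoint stages sample just inside the step, so square-pulse edges
    # aligned with the grid do not degrade the integration order
    I1 <- I_fun(t + 1e-9 * dt); I2 <- I_fun(t + dt / 2)
    I3 <- I_fun(t + dt * (1 - 1e-9))
    k1 <- deriv(r, v, I1)
    k2 <- deriv(r + dt / 2 * k1[1], v + dt / 2 * k1[2], I2)
    k3 <- deriv(r + dt / 2 * k2[1], v + dt / 2 * k2[2], I2)
    k4 <- deriv(r + dt * k3[1], v + dt * k3[2], I3)
    c(r + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]),
      v + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2]))
  }
  s <- c(p$r0, p$v0)
  for (k in seq_len(n_relax)) {
    s <- step(s[1], s[2], 0, function(t) 0)
    if (!all(is.finite(s)) || abs(s[2]) > 1e6)
      stop("rate model diverged during relaxation at step ", k)
  }
  out_r <- numeric(n); out_v <- numeric(n)
  out_r[1L] <- s[1]; out_v[1L] <- s[2]
  for (k in seq_len(n - 1L)) {
    s <- step(s[1], s[2], (k - 1L) * dt, stim)
    if (!all(is.finite(s)) || abs(s[2]) > 1e6)
      stop("rate model diverged at step ", k, " (t = ", (k - 1) * dt, " ms)")
    out_r[k + 1L] <- s[1]; out_v[k + 1L] <- s[2]
  }
  tr <- data.frame(t = (seq_len(n) - 1L) * dt, r = out_r * 1000, v = out_v)
  class(tr) <- c("rate_trace", "data.frame")
  tr
}

#' Convert a rate trace to LFP/EEG via a population kernel
#'
#' Resamples the rate to the kernel grid, converts from s^-1 to expected
#' spikes per time step for the assumed presynaptic population size
#' (`R = r * 1e-3 * dt * n_presyn`), and convolves with the population
#' kernel — the same operation as [kernel_approx_signal()] applied to a
#' binned spike ensemble.
#'
#' @param trace a `rate_trace` from [integrate_rate_model()].
#' @param bank a [kernel_bank()] (its population kernel is used), or a plain
#'   channels x lags matrix together with `dt`.
#' @param n_presyn assumed presynaptic population size.
#' @param dt kernel time step (ms) when `bank` is a plain matrix.
#' @param include_eeg also return the EEG trace when the bank has EEG
#'   kernels.
#' @return list with `lfp` (a [signal_set()]) and, if available, `eeg`
#'   (a single-channel [signal_set()] in pV).
#' @export
rate_to_brain_signal <- function(trace, bank, n_presyn = 10000, dt = NULL,
                                 include_eeg = TRUE) {
  stopifnot(inherits(trace, "rate_trace"))
  if (inherits(bank, "kernel_bank")) dt <- bank$dt
  if (is.null(dt)) stop("`dt` must be given when `bank` is a plain matrix")
  t_out <- seq(0, max(trace$t), by = dt)
  r_hz <- stats::approx(trace$t, trace$r, xout = t_out)$y
  R <- r_hz * 1e-3 * dt * n_presyn          # expected spikes per bin
  lfp <- kernel_approx_signal(
    if (inherits(bank, "kernel_bank")) population_kernel(bank) else bank,
    R, dt = dt)
  lfp$channels <- if (inherits(bank, "kernel_bank")) bank$channels
  out <- list(lfp = lfp)
  if (include_eeg && inherits(bank, "kernel_bank") && !is.null(bank$eeg)) {
    eeg <- kernel_approx_signal(matrix(population_kernel(bank, "eeg"),
                                       nrow = 1L), R, dt = dt)
    eeg$unit <- "pV"
    out$eeg <- eeg
  }
  out
}
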