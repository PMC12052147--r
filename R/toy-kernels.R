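#' Bank of single-cell spike-to-signal kernels
#'
#' Container for `n_kernels` causal spatiotemporal kernels on a common
#' channel x lag grid (signal units per presynaptic spike), their arithmetic
#' mean (the population kernel), and optionally matching EEG kernels.
#'
#' @param kernels numeric array `[n_kernels x n_channels x n_lags]`.
#' @param dt lag grid step (ms); lag 0 is the presynaptic spike time.
#' @param channels optional channel positions (contact depths, um).
#' @param eeg optional matrix `[n_kernels x n_lags]` of EEG kernels (pV).
#' @param unit signal unit of `kernels`.
#' @param config provenance: the generating configuration.
#' @return an object of class `kernel_bank`.
#' @export
kernel_bank <- function(kernels, dt, channels = NULL, eeg = NULL,
                        unit = "uV", config = NULL) {
  stopifnot(is.array(kernels), length(dim(kernels)) == 3L)
  dims <- dim(kernels)
  mean_k <- colMeans(kernels)                     # n_ch x n_lags
  structure(
    list(kernels = kernels, n_kernels = dims[1L], n_channels = dims[2L],
         n_lags = dims[3L], dt = dt, lags = (seq_len(dims[3L]) - 1L) * dt,
         channels = channels, unit = unit,
         mean = mean_k,
         eeg = eeg, eeg_mean = if (!is.null(eeg)) colMeans(eeg),
         config = config),
    class = "kernel_bank")
}

#' @export
print.kernel_bank <- function(x, ...) {
  cat("kernel_bank:", x$n_kernels, "kernels x", x$n_channels,
      "channel(s) x", x$n_lags, "lags (dt =", x$dt, "ms,", x$unit, ")",
      if (!is.null(x$eeg)) "+ EEG kernels", "\n")
  invisible(x)
}

#' Population (mean) kernel of a bank
#'
#' @param bank a [kernel_bank()].
#' @param signal `"lfp"` for the channel x lag mean kernel, `"eeg"` for the
#'   mean EEG kernel (vector over lags).
#' @return matrix (channels x lags) or numeric vector.
#' @export
population_kernel <- function(bank, signal = c("lfp", "eeg")) {
  stopifnot(inherits(bank, "kernel_bank"))
  signal <- match.arg(signal)
  if (signal == "lfp") bank$mean
  else {
    if (is.null(bank$eeg)) stop("bank has no EEG kernels")
    bank$eeg_mean
  }
}

#' Toy kernel parameters
#'
#' Double-exponential kernel family (rise `tau1`, decay `tau2`) whose
#' members differ only in peak amplitude.
#'
#' @param amp_mean mean peak amplitude (uV), default 1.0.
#' @param amp_sd amplitude standard deviation (uV).
#' @param tau1 rise time constant (ms), default 0.2.
#' @param tau2 decay time constant (ms), default 1.
#' @param dt lag grid step (ms), default 0.1.
#' @param length kernel length (ms), default 10.
#' @export
toy_kernel_params <- function(amp_mean = 1, amp_sd = 0, tau1 = 0.2,
                              tau2 = 1, dt = 0.1, length = 10) {
  if (tau1 <= 0 || tau2 <= 0 || dt <= 0 || length <= 0)
    stop("time constants, dt and length must be > 0")
  if (tau1 == tau2)
    stop("tau1 = tau2 is the degenerate alpha-function limit; ",
         "use distinct time constants")
  if (tau1 > tau2) stop("rise time `tau1` must be smaller than decay `tau2`")
  if (amp_sd < 0) stop("`amp_sd` must be >= 0")
  structure(list(amp_mean = amp_mean, amp_sd = amp_sd, tau1 = tau1,
                 tau2 = tau2, dt = dt, length = length),
            class = "toy_kernel_params")
}

# normalized double-exponential waveform on the lag grid (peak value 1 at
# the analytic extremum t* = tau1 tau2 / (tau2 - tau1) * log(tau2 / tau1))
.toy_waveform <- function(params) {
  tt <- seq(0, params$length - params$dt, by = params$dt)
  w <- -exp(-tt / params$tau1) + exp(-tt / params$tau2)
  tstar <- params$tau1 * params$tau2 / (params$tau2 - params$tau1) *
    log(params$tau2 / params$tau1)
  wmax <- -exp(-tstar / params$tau1) + exp(-tstar / params$tau2)
  w / wmax
}

#' Single toy kernel
#'
#' `k(t) = A * (-exp(-t/tau1) + exp(-t/tau2)) / max(.)` for `t > 0` and 0
#' otherwise; the normalization by the analytic maximum makes the peak value
#' exactly `A`.
#'
#' @param A peak amplitude (uV).
#' @param params a [toy_kernel_params()].
#' @return numeric vector over lags `0, dt, ..., length - dt`.
#' @export
toy_kernel <- function(A, params = toy_kernel_params()) {
  stopifnot(inherits(params, "toy_kernel_params"))
  A * .toy_waveform(params)
}

#' Sample a bank of toy kernels
#'
#' Draws `n` amplitudes from `Normal(amp_mean, amp_sd)` and returns the
#' corresponding single-channel kernel bank.
#'
#' @param params a [toy_kernel_params()].
#' @param n number of kernels.
#' @param seed optional integer seed.
#' @param amplitudes optional explicit amplitudes (overrides sampling).
#' @return a [kernel_bank()] with one channel; the drawn amplitudes are in
#'   `config$amplitudes`.
#' @export
sample_toy_bank <- function(params = toy_kernel_params(), n = 1000,
                            seed = NULL, amplitudes = NULL) {
  stopifnot(inherits(params, "toy_kernel_params"))
  if (is.null(amplitudes)) {
    if (!is.null(seed)) set.seed(seed)
    amplitudes <- stats::rnorm(n, params$amp_mean, params$amp_sd)
  } else n <- length(amplitudes)
  w <- .toy_waveform(params)
  kern <- array(0, dim = c(n, 1L, length(w)))
  kern[, 1L, ] <- outer(amplitudes, w)
  kernel_bank(kern, dt = params$dt,
              config = list(type = "toy", params = params,
                            amplitudes = amplitudes, seed = seed))
}
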