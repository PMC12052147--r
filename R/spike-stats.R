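#' Population-averaged spike-train auto- and cross-covariances
#'
#' Estimates the population-averaged autocovariance density `A_s(tau)` and the
#' pair-averaged cross-covariance density `C_s(tau)` of a spike ensemble from
#' binned spike trains. Densities are scaled so that the discrete sum over
#' lags times `binsize` approximates the continuous-time integral: for a
#' multiple interaction process with rate `nu` (spikes/ms) and copy
#' probability `f`, the integrated `A_s` is approximately `nu` and the
#' integrated `C_s` approximately `f^2 * nu`.
#'
#' @param spikes a [spike_train_set()].
#' @param binsize bin width (ms).
#' @param max_lag maximum lag (ms); must be less than half the duration.
#' @return An object of class `spike_covariances`: list with `lags` (ms,
#'   symmetric about 0), `A_s`, `C_s` (densities, spikes^2/ms^2 so that
#'   `sum(A_s) * binsize` is spikes/ms), `binsize`, `analytic = FALSE`.
#' @export
estimate_spike_covariances <- function(spikes, binsize, max_lag) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (binsize <= 0) stop("`binsize` must be positive")
  if (max_lag >= spikes$duration / 2)
    stop("`max_lag` must be less than half the duration")
  if (spikes$n_trains < 2L)
    stop("cross-covariance requires at least two trains")
  x <- .bin_count_matrix(spikes, binsize)
  n <- nrow(x); nb <- ncol(x)
  x <- x - rowMeans(x)
  m <- floor(max_lag / binsize)
  nfft <- stats::nextn(nb + m, 2)
  xp <- cbind(x, matrix(0, n, nfft - nb))
  F <- t(apply(xp, 1L, stats::fft))           # n x nfft complex
  auto_spec <- colSums(Re(F * Conj(F)))
  Fsum <- colSums(F)
  cross_spec <- Re(Fsum * Conj(Fsum)) - auto_spec
  # inverse FFT of real, even-in-frequency spectra -> covariances at lags
  auto_cov <- Re(stats::fft(auto_spec, inverse = TRUE)) / nfft / (n * nb)
  cross_cov <- Re(stats::fft(cross_spec, inverse = TRUE)) / nfft /
    (n * (n - 1) * nb)
  lag_idx <- if (m > 0) c((nfft - m + 1):nfft, 1:(m + 1)) else 1L  # lags -m..m
  lags <- (-m:m) * binsize
  structure(
    list(lags = lags,
         A_s = auto_cov[lag_idx] / binsize^2,
         C_s = cross_cov[lag_idx] / binsize^2,
         binsize = binsize, analytic = FALSE),
    class = "spike_covariances")
}

#' Analytic MIP spike covariances
#'
#' The multiple interaction process has delta-shaped covariance densities
#' `A_s(tau) = nu * delta(tau)` and `C_s(tau) = f^2 * nu * delta(tau)`. This
#' constructor records the integrated delta weights exactly (no bin-width
#' artifacts); theory functions consume them analytically.
#'
#' @param rate firing rate (events per second).
#' @param f MIP copy probability.
#' @return A `spike_covariances` object with `analytic = TRUE` and fields
#'   `A0 = nu` and `C0 = f^2 * nu` in spikes/ms (the delta weights).
#' @export
mip_spike_covariances <- function(rate, f = 0) {
  if (f < 0 || f > 1) stop("`f` must lie in [0, 1]")
  nu <- rate / 1000
  structure(
    list(A0 = nu, C0 = f^2 * nu, rate = rate, f = f, analytic = TRUE),
    class = "spike_covariances")
}

#' @export
print.spike_covariances <- function(x, ...) {
  if (isTRUE(x$analytic)) {
    cat("spike_covariances (analytic MIP): nu =", x$A0, "spikes/ms, f =",
        x$f, "\n")
  } else {
    cat("spike_covariances: lags", min(x$lags), "..", max(x$lags),
        "ms, binsize", x$binsize, "ms\n")
    cat("  integrated A_s:", sum(x$A_s) * x$binsize,
        " integrated C_s:", sum(x$C_s) * x$binsize, "spikes/ms\n")
  }
  invisible(x)
}

#' Population-rate power spectrum
#'
#' Periodogram of the binned population rate, used to compare dynamical
#' regimes of network simulations (e.g. the slow synchronous-irregular regime
#' shows a low-frequency peak absent in the asynchronous-irregular regime).
#'
#' @param spikes a [spike_train_set()].
#' @param dt bin width (ms).
#' @return data.frame with `freq_hz` and `power` columns.
#' @export
population_rate_spectrum <- function(spikes, dt = 1) {
  r <- bin_population_rate(spikes, dt)
  r <- r - mean(r)
  n <- length(r)
  sp <- abs(stats::fft(r))^2 / n
  k <- seq_len(floor(n / 2))
  data.frame(freq_hz = (k - 1) / (n * dt) * 1000, power = sp[k])
}
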