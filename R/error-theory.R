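#' Kernel auto- and cross-correlations
#'
#' Per channel, the lag-integrated autocorrelation
#' `A_k(r, tau) = mean_i int k_i(r, t) k_i(r, t + tau) dt` and the
#' pair-averaged cross-correlation `C_k` over distinct ordered kernel pairs,
#' estimated from the finite bank (plug-in expectation). Discrete integrals
#' are lag sums times `dt`.
#'
#' @param bank a [kernel_bank()].
#' @param signal `"lfp"` or `"eeg"` kernels.
#' @return An object of class `kernel_correlations`: list with `lags`
#'   (symmetric, ms), `A_k` and `C_k` (channels x lags, signal^2 ms),
#'   `dt`, `n_kernels`.
#' @export
kernel_correlations <- function(bank, signal = c("lfp", "eeg")) {
  stopifnot(inherits(bank, "kernel_bank"))
  signal <- match.arg(signal)
  if (bank$n_kernels < 2L)
    stop("cross-correlation requires at least two kernels")
  K <- if (signal == "lfp") bank$kernels
  else array(bank$eeg, dim = c(bank$n_kernels, 1L, bank$n_lags))
  n <- dim(K)[1L]; n_ch <- dim(K)[2L]; L <- dim(K)[3L]
  nfft <- stats::nextn(2L * L, 2)
  A <- matrix(0, n_ch, 2L * L - 1L)
  C <- matrix(0, n_ch, 2L * L - 1L)
  lag_idx <- c((nfft - L + 2L):nfft, 1L:L)        # lags -(L-1) .. L-1
  for (ch in seq_len(n_ch)) {
    X <- matrix(0, n, nfft)
    X[, seq_len(L)] <- K[, ch, ]
    F <- t(apply(X, 1L, stats::fft))
    if (n == 1L) F <- matrix(F, nrow = 1L)
    auto <- colSums(Re(F * Conj(F)))
    Fs <- colSums(F)
    cross <- Re(Fs * Conj(Fs)) - auto
    A[ch, ] <- (Re(stats::fft(auto, inverse = TRUE)) / nfft)[lag_idx] /
      n * bank$dt
    C[ch, ] <- (Re(stats::fft(cross, inverse = TRUE)) / nfft)[lag_idx] /
      (n * (n - 1)) * bank$dt
  }
  structure(list(lags = seq(-(L - 1L), L - 1L) * bank$dt, A_k = A, C_k = C,
                 dt = bank$dt, n_kernels = n, signal = signal),
            class = "kernel_correlations")
}

#' @export
print.kernel_correlations <- function(x, ...) {
  cat("kernel_correlations:", nrow(x$A_k), "channel(s),",
      length(x$lags), "lags,", x$n_kernels, "kernels\n")
  i0 <- which(x$lags == 0)
  cat("  A_k(0):", signif(x$A_k[, i0], 4), "\n  C_k(0):",
      signif(x$C_k[, i0], 4), "\n")
  invisible(x)
}

# integral over tau of X_k(tau) * S(tau) for spike covariances S: analytic
# delta covariances are applied exactly (weight times the lag-0 value);
# empirical covariances are interpolated onto the kernel lag grid and summed
.lag_integral <- function(kc, s_weights) {
  i0 <- which(kc$lags == 0)
  if (s_weights$analytic) {
    list(AA = kc$A_k[, i0] * s_weights$A0,
         CC = kc$C_k[, i0] * s_weights$C0,
         DD = (kc$A_k[, i0] - kc$C_k[, i0]) * (s_weights$A0 - s_weights$C0))
  } else {
    As <- stats::approx(s_weights$lags, s_weights$A_s, xout = kc$lags,
                        rule = 2)$y
    Cs <- stats::approx(s_weights$lags, s_weights$C_s, xout = kc$lags,
                        rule = 2)$y
    dt <- kc$dt
    list(AA = as.numeric(kc$A_k %*% As) * dt,
         CC = as.numeric(kc$C_k %*% Cs) * dt,
         DD = as.numeric((kc$A_k - kc$C_k) %*% (As - Cs)) * dt)
  }
}

#' Expected squared error of the population-kernel approximation
#'
#' `<E^2(r)> = (Npre - 1) * int dtau (A_k - C_k)(r, tau) (A_s - C_s)(tau)`:
#' the expected time-variance of the difference between the ground-truth
#' signal and the population-kernel approximation, from kernel and
#' spike-train second-order statistics alone. The error vanishes when all
#' kernels are identical (`A_k = C_k`) or the population spikes in a fully
#' correlated manner (`A_s = C_s`).
#'
#' @param kc a [kernel_correlations()].
#' @param sc a `spike_covariances` object — either estimated
#'   ([estimate_spike_covariances()]) or analytic ([mip_spike_covariances()],
#'   applied exactly with no bin-width artifacts).
#' @param n_pre presynaptic population size (number of kernels/trains).
#' @return An object of class `theory_error_report`: list with per-channel
#'   `E2`, `E` and provenance.
#' @export
expected_squared_error <- function(kc, sc, n_pre) {
  stopifnot(inherits(kc, "kernel_correlations"),
            inherits(sc, "spike_covariances"))
  li <- .lag_integral(kc, sc)
  E2 <- pmax((n_pre - 1) * li$DD, 0)
  structure(list(E2 = E2, E = sqrt(E2), n_pre = n_pre,
                 spike_stats = if (sc$analytic) "analytic" else "empirical"),
            class = "theory_error_report")
}

#' Expected relative error of the population-kernel approximation
#'
#' Ratio of the expected squared error to the expected ground-truth
#' variance `Npre int A_k A_s + Npre (Npre - 1) int C_k C_s`. With
#' `mode = "max"` (multi-contact convention) every channel is normalized by
#' the maximum expected ground-truth variance across channels; with
#' `"per_signal"` each channel uses its own.
#'
#' @inheritParams expected_squared_error
#' @param mode normalization convention, as in [empirical_error()].
#' @return a `theory_error_report` with `E2_rel`, `E_rel` and the
#'   ground-truth variance `var_gt` added.
#' @export
expected_relative_error <- function(kc, sc, n_pre,
                                    mode = c("max", "per_signal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(kc, "kernel_correlations"),
            inherits(sc, "spike_covariances"))
  li <- .lag_integral(kc, sc)
  E2 <- pmax((n_pre - 1) * li$DD, 0)
  var_gt <- n_pre * li$AA + n_pre * (n_pre - 1) * li$CC
  denom <- if (mode == "max") rep(max(var_gt), length(E2)) else var_gt
  E2_rel <- ifelse(denom > 0, E2 / denom, NA_real_)
  structure(list(E2 = E2, E = sqrt(E2), E2_rel = E2_rel,
                 E_rel = sqrt(E2_rel), var_gt = var_gt, n_pre = n_pre,
                 mode = mode,
                 spike_stats = if (sc$analytic) "analytic" else "empirical"),
            class = "theory_error_report")
}

#' @export
print.theory_error_report <- function(x, ...) {
  cat("theory_error_report (n_pre = ", x$n_pre, ", ", x$spike_stats,
      " spike statistics):\n", sep = "")
  cat("  E:     ", paste(signif(x$E, 4), collapse = " "), "\n")
  if (!is.null(x$E_rel))
    cat("  E_rel: ", paste(signif(x$E_rel, 4), collapse = " "), "\n")
  invisible(x)
}

#' Out-degree decomposition of kernel correlations
#'
#' Structural approximation of the kernel statistics in terms of the
#' out-degree and the synaptic-weight moments:
#' `A_k ~ Kout (Var J + Mean(J)^2) A_chi + Kout^2 Mean(J)^2 chibar2` and
#' `C_k ~ Kout^2 Mean(J)^2 chibar2`, so that
#' `A_k - C_k ~ Kout (Var J + Mean(J)^2) A_chi`. The impulse-response
#' statistics are estimated from a bank built with unit weights
#' (`j_mean = 1`, `j_s = 0`): `A_chi` is that bank's per-kernel
#' autocorrelation divided by its out-degree, and `chibar2` its mean-kernel
#' self-correlation divided by the out-degree squared. The decomposition
#' exposes the predicted scalings: error ~ sqrt(Kout), signal ~ Kout,
#' relative error ~ 1/sqrt(Kout).
#'
#' @param j_mean,j_var mean and variance of the synaptic weight (nA, nA^2).
#' @param chi_stats list with `A_chi` and `chibar2` (channels x lags), e.g.
#'   from [unit_weight_chi_stats()].
#' @param k_out out-degree.
#' @return list with approximated `A_k`, `C_k` and `A_minus_C`
#'   (channels x lags).
#' @export
kout_decomposition <- function(j_mean, j_var, chi_stats, k_out) {
  A_chi <- chi_stats$A_chi
  chibar2 <- chi_stats$chibar2
  second_moment <- j_var + j_mean^2
  C_k <- k_out^2 * j_mean^2 * chibar2
  A_k <- k_out * second_moment * A_chi + C_k
  list(A_k = A_k, C_k = C_k, A_minus_C = k_out * second_moment * A_chi)
}

#' Impulse-response statistics from a unit-weight kernel bank
#'
#' Helper for [kout_decomposition()]: given a bank built with unit synaptic
#' weights, returns the per-synapse autocorrelation `A_chi` (the bank's
#' mean single-kernel autocorrelation divided by its out-degree) and the
#' squared-mean statistic `chibar2` (the cross-kernel correlation divided by
#' the out-degree squared).
#'
#' @param unit_bank a [kernel_bank()] built with `j_mean = 1, j_s = 0`.
#' @param k_out the out-degree the unit bank was built with.
#' @return list with `A_chi`, `chibar2` (channels x lags) and `lags`.
#' @export
unit_weight_chi_stats <- function(unit_bank, k_out) {
  kc <- kernel_correlations(unit_bank)
  # with unit weights: A_k = Kout A_chi + Kout^2 chibar2, C_k = Kout^2 chibar2
  chibar2 <- kc$C_k / k_out^2
  A_chi <- (kc$A_k - kc$C_k) / k_out
  list(A_chi = A_chi, chibar2 = chibar2, lags = kc$lags)
}
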