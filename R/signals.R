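#' Multi-channel signal container
#'
#' @param traces numeric matrix, channels x time steps (a vector is treated
#'   as a single channel).
#' @param dt time step (ms).
#' @param channels optional channel positions (e.g. contact depths, um).
#' @param label signal label (`"ground_truth"`, `"kernel_approx"`,
#'   `"difference"`, ...).
#' @param unit signal unit string (`"uV"` for LFP, `"pV"` for EEG).
#' @return an object of class `signal_set`.
#' @export
signal_set <- function(traces, dt, channels = NULL, label = "signal",
                       unit = "uV") {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1L)
  traces <- as.matrix(traces)
  if (!all(is.finite(traces))) stop("signal traces must be finite")
  structure(list(traces = traces, dt = dt, channels = channels,
                 label = label, unit = unit),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat("signal_set [", x$label, "]: ", nrow(x$traces), " channel(s) x ",
      ncol(x$traces), " steps (dt = ", x$dt, " ms, ", x$unit, ")\n",
      sep = "")
  invisible(x)
}

# spike times -> 1-based bin indices on a dt grid with nb bins
.spike_bins <- function(spikes, dt, nb) {
  lapply(spikes$trains, function(tt) {
    idx <- as.integer(floor(tt / dt)) + 1L
    idx[idx >= 1L & idx <= nb]
  })
}

#' Ground-truth signal: per-cell kernels convolved with their own spike trains
#'
#' Computes the compound signal as the sum over presynaptic cells of the
#' convolution of each single-cell kernel with that cell's spike train
#' (spikes discretized as unit impulses on the kernel time grid). This is the
#' presynaptic-perspective signal; it is algebraically identical to summing
#' every individual postsynaptic response.
#'
#' @param bank a [kernel_bank()]; `n_kernels` must equal the number of
#'   trains.
#' @param spikes a [spike_train_set()].
#' @return a [signal_set()] labelled `"ground_truth"` covering the spike
#'   duration plus the kernel length.
#' @export
ground_truth_signal <- function(bank, spikes) {
  stopifnot(inherits(bank, "kernel_bank"), inherits(spikes, "spike_train_set"))
  if (bank$n_kernels != spikes$n_trains)
    stop("number of kernels (", bank$n_kernels,
         ") must match number of trains (", spikes$n_trains, ")")
  nb <- floor(spikes$duration / bank$dt + 1e-9)
  n_time <- nb + bank$n_lags - 1L
  bins <- .spike_bins(spikes, bank$dt, nb)
  traces <- spike_conv_cpp(bank$kernels, bins, bank$n_channels, bank$n_lags,
                           as.integer(n_time))
  signal_set(traces, dt = bank$dt, channels = bank$channels,
             label = "ground_truth", unit = bank$unit)
}

#' Kernel approximation: population kernel convolved with the population rate
#'
#' @param kbar population kernel: matrix channels x lags (or a
#'   [kernel_bank()], whose population kernel is used).
#' @param R population rate in spikes per bin on the kernel time grid (e.g.
#'   `bin_population_rate(spikes, dt) * dt`), or a [spike_train_set()] that
#'   is binned internally.
#' @param dt kernel time step (ms); taken from the bank when one is given.
#' @return a [signal_set()] labelled `"kernel_approx"`.
#' @export
kernel_approx_signal <- function(kbar, R, dt = NULL) {
  channels <- NULL; unit <- "uV"
  if (inherits(kbar, "kernel_bank")) {
    dt <- kbar$dt; channels <- kbar$channels; unit <- kbar$unit
    kbar <- population_kernel(kbar)
  }
  if (is.null(dt)) stop("`dt` must be given when `kbar` is a plain matrix")
  if (is.vector(kbar)) kbar <- matrix(kbar, nrow = 1L)
  if (inherits(R, "spike_train_set")) {
    nb <- floor(R$duration / dt + 1e-9)
    R <- .bin_counts(unlist(R$trains, use.names = FALSE), dt, nb)
  }
  n_lag <- ncol(kbar)
  n_time <- length(R) + n_lag - 1L
  traces <- .causal_conv(kbar, R, n_time)
  signal_set(traces, dt = dt, channels = channels, label = "kernel_approx",
             unit = unit)
}

# causal FFT convolution of each kernel row with input x, output length n_time
.causal_conv <- function(K, x, n_time) {
  nfft <- stats::nextn(n_time, 2)
  fx <- stats::fft(c(x, numeric(nfft - length(x))))
  out <- matrix(0, nrow(K), n_time)
  for (ch in seq_len(nrow(K))) {
    fk <- stats::fft(c(K[ch, ], numeric(nfft - ncol(K))))
    full <- Re(stats::fft(fk * fx, inverse = TRUE)) / nfft
    out[ch, ] <- full[seq_len(n_time)]
  }
  out
}

#' Empirical absolute and relative approximation error
#'
#' Per channel, `E(r) = sd_t[V - Vhat]` (standard deviation across time,
#' population convention 1/N). The relative error normalizes by the
#' ground-truth standard deviation: in `"max"` mode by the maximum over
#' channels (multi-contact convention, which avoids inflated errors at
#' near-silent contacts), in `"per_signal"` mode channel by channel (the toy
#' single-channel convention).
#'
#' @param V ground-truth [signal_set()].
#' @param Vhat approximation [signal_set()] on the same grid.
#' @param mode `"max"` or `"per_signal"` normalization.
#' @return An object of class `error_report`: list with per-channel `E`,
#'   `E_rel`, the normalization `mode`, the ground-truth sd used, and a
#'   `flagged` logical marking channels whose own variance is < 1e-12 of the
#'   maximum (where a per-signal relative error would be meaningless).
#'   Channels with zero normalization get `E_rel = NA`.
#' @export
empirical_error <- function(V, Vhat, mode = c("max", "per_signal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(V, "signal_set"), inherits(Vhat, "signal_set"))
  if (!all(dim(V$traces) == dim(Vhat$traces)) || V$dt != Vhat$dt)
    stop("signals must share the same channel/time grid")
  d <- V$traces - Vhat$traces
  nt <- ncol(d)
  var_biased <- function(m) rowMeans(m^2) - rowMeans(m)^2
  E <- sqrt(pmax(var_biased(d), 0))
  v_gt <- pmax(var_biased(V$traces), 0)
  denom2 <- if (mode == "max") rep(max(v_gt), length(E)) else v_gt
  E_rel <- ifelse(denom2 > 0, E / sqrt(denom2), NA_real_)
  structure(list(E = E, E_rel = E_rel, mode = mode,
                 sd_ground_truth = sqrt(v_gt),
                 flagged = v_gt < 1e-12 * max(v_gt)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("error_report (", x$mode, " normalization):\n", sep = "")
  cat("  E:     ", paste(signif(x$E, 4), collapse = " "), "\n")
  cat("  E_rel: ", paste(signif(x$E_rel, 4), collapse = " "), "\n")
  invisible(x)
}

#' Linear superposition of per-pathway signals
#'
#' Sums the signals of several synaptic pathways, each given as a
#' `(kernel bank, spike trains)` pair (evaluated as ground truth) or an
#' already-computed [signal_set()]. Inhibitory pathways are represented by
#' sign-flipped kernels (`sign = -1`).
#'
#' @param pathways list; each element is either a `signal_set` or a list
#'   with elements `bank`, `spikes` and optionally `sign` (+1/-1).
#' @return a [signal_set()] labelled `"superposition"`.
#' @export
superpose_pathways <- function(pathways) {
  sigs <- lapply(pathways, function(pw) {
    if (inherits(pw, "signal_set")) return(pw)
    s <- ground_truth_signal(pw$bank, pw$spikes)
    if (!is.null(pw$sign) && pw$sign < 0) s$traces <- -s$traces
    s
  })
  ref <- sigs[[1L]]
  for (s in sigs[-1L]) {
    if (!all(dim(s$traces) == dim(ref$traces)) || s$dt != ref$dt)
      stop("pathways must share dt and channel layout")
    ref$traces <- ref$traces + s$traces
  }
  ref$label <- "superposition"
  ref
}
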