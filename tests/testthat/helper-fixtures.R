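# Shared fixtures built once per test run. The stylized morphology and its
# cable propagator are the expensive pieces; every test file reuses them.

.fixture_env <- new.env(parent = emptyenv())

fixture_morphology <- function() {
  if (is.null(.fixture_env$m))
    .fixture_env$m <- build_stylized_l5(seed = 42)
  .fixture_env$m
}

fixture_propagator <- function() {
  if (is.null(.fixture_env$prop))
    .fixture_env$prop <- segment_propagator(fixture_morphology(),
                                            passive_params(),
                                            dt = 2^-4, T = 30)
  .fixture_env$prop
}

# hand-rolled spike trains for brute-force covariance checks
fixture_tiny_trains <- function() {
  spike_train_set(list(c(5, 12.5, 40, 77, 90),
                       c(5, 30, 62),
                       c(12.5, 30.1, 55, 88)),
                  duration = 100)
}

# brute-force binned auto/cross covariance densities (nested loops)
oracle_spike_covariances <- function(spikes, binsize, max_lag) {
  nb <- floor(spikes$duration / binsize + 1e-9)
  x <- t(vapply(spikes$trains, function(tt) {
    idx <- floor(tt / binsize) + 1
    tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  }, numeric(nb)))
  x <- x - rowMeans(x)
  n <- nrow(x)
  m <- floor(max_lag / binsize)
  lags <- -m:m
  A <- C <- numeric(length(lags))
  for (li in seq_along(lags)) {
    lg <- lags[li]
    tsrc <- if (lg >= 0) seq_len(nb - lg) else seq(1 - lg, nb)
    tdst <- tsrc + lg
    for (i in seq_len(n)) {
      A[li] <- A[li] + sum(x[i, tsrc] * x[i, tdst])
      for (j in seq_len(n)) if (j != i)
        C[li] <- C[li] + sum(x[i, tsrc] * x[j, tdst])
    }
  }
  list(lags = lags * binsize,
       A_s = A / n / nb / binsize^2,
       C_s = C / (n * (n - 1)) / nb / binsize^2)
}

# direct R spike-kernel convolution sum (presynaptic perspective, slow path)
oracle_ground_truth <- function(bank, spikes) {
  nb <- floor(spikes$duration / bank$dt + 1e-9)
  nt <- nb + bank$n_lags - 1L
  out <- matrix(0, bank$n_channels, nt)
  for (j in seq_len(bank$n_kernels)) {
    kj <- matrix(bank$kernels[j, , ], bank$n_channels, bank$n_lags)
    for (s in spikes$trains[[j]]) {
      b <- floor(s / bank$dt) + 1
      idx <- b:(b + bank$n_lags - 1L)
      out[, idx] <- out[, idx] + kj
    }
  }
  out
}

# nested-loop kernel auto/cross correlation oracle
oracle_kernel_correlations <- function(bank) {
  K <- bank$kernels
  n <- bank$n_kernels; nch <- bank$n_channels; L <- bank$n_lags
  lags <- -(L - 1):(L - 1)
  A <- C <- matrix(0, nch, length(lags))
  for (ch in seq_len(nch)) {
    for (li in seq_along(lags)) {
      lg <- lags[li]
      tsrc <- if (lg >= 0) seq_len(L - lg) else seq(1 - lg, L)
      tdst <- tsrc + lg
      for (i in seq_len(n)) {
        A[ch, li] <- A[ch, li] + sum(K[i, ch, tsrc] * K[i, ch, tdst])
        for (j in seq_len(n)) if (j != i)
          C[ch, li] <- C[ch, li] + sum(K[i, ch, tsrc] * K[j, ch, tdst])
      }
    }
  }
  list(lags = lags * bank$dt, A_k = A / n * bank$dt,
       C_k = C / (n * (n - 1)) * bank$dt)
}

# small multi-channel bank with explicit random kernels
fixture_random_bank <- function(n = 5, nch = 2, L = 40, dt = 0.5, seed = 1) {
  set.seed(seed)
  kern <- array(stats::rnorm(n * nch * L), dim = c(n, nch, L))
  kernel_bank(kern, dt = dt)
}
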