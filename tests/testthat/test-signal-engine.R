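test_that("ground truth is the exact impulse superposition of kernels", {
  bank <- fixture_random_bank(n = 3, nch = 2, L = 20, dt = 0.5, seed = 2)
  # single spike in one train: the output is that kernel, shifted
  sp <- spike_train_set(list(numeric(0), c(10.2), numeric(0)), duration = 40)
  V <- ground_truth_signal(bank, sp)
  b <- floor(10.2 / 0.5) + 1
  expect_true(all(V$traces[, seq_len(b - 1)] == 0))
  expect_equal(V$traces[, b:(b + 19)],
               matrix(bank$kernels[2, , ], 2, 20), tolerance = 1e-15)

  # exact match with the direct R accumulation oracle
  set.seed(3)
  sp2 <- generate_poisson(40, 200, 3, seed = 31)
  V2 <- ground_truth_signal(bank, sp2)
  expect_equal(V2$traces, oracle_ground_truth(bank, sp2), tolerance = 1e-13)

  expect_error(ground_truth_signal(bank, generate_poisson(10, 100, 5,
                                                          seed = 1)),
               "match")
})

test_that("presynaptic and postsynaptic perspectives give identical signals", {
  # construct explicit per-(postsynaptic, presynaptic) responses h_ij and
  # single-cell kernels k_j = sum_i h_ij; the compound signal computed per
  # presynaptic cell (kernel convolution) must equal the double sum over
  # postsynaptic contributions
  set.seed(11)
  n_post <- 4; n_pre <- 5; L <- 30; dt <- 0.25
  h <- array(rnorm(n_post * n_pre * L), dim = c(n_post, n_pre, L))
  kern <- array(0, dim = c(n_pre, 1, L))
  kern[, 1, ] <- apply(h, c(2, 3), sum)
  bank <- kernel_bank(kern, dt = dt)
  sp <- generate_poisson(30, 500, n_pre, seed = 12)
  V_pre <- ground_truth_signal(bank, sp)

  nb <- floor(500 / dt)
  nt <- nb + L - 1
  V_post <- matrix(0, 1, nt)
  for (i in seq_len(n_post)) {
    vi <- numeric(nt)
    for (j in seq_len(n_pre)) {
      for (s in sp$trains[[j]]) {
        b0 <- floor(s / dt) + 1
        idx <- b0:(b0 + L - 1)
        vi[idx] <- vi[idx] + h[i, j, ]
      }
    }
    V_post[1, ] <- V_post[1, ] + vi
  }
  expect_lt(max(abs(V_pre$traces - V_post)) / max(abs(V_post)), 1e-12)
})

test_that("kernel approximation convolves the population rate", {
  bank <- sample_toy_bank(toy_kernel_params(amp_sd = 0.3), n = 20, seed = 4)
  # zero rate gives a zero signal
  z <- kernel_approx_signal(bank, numeric(1000))
  expect_true(all(z$traces == 0))

  # FFT convolution equals direct summation
  set.seed(5)
  R <- rpois(400, 0.5)
  va <- kernel_approx_signal(bank, R)
  kbar <- population_kernel(bank)[1, ]
  direct <- numeric(length(R) + length(kbar) - 1)
  for (t in seq_along(R)) if (R[t] > 0)
    direct[t:(t + length(kbar) - 1)] <-
      direct[t:(t + length(kbar) - 1)] + R[t] * kbar
  expect_equal(va$traces[1, ], direct, tolerance = 1e-10)

  # identical kernels: approximation equals ground truth for any spikes
  b0 <- sample_toy_bank(toy_kernel_params(amp_sd = 0), n = 10, seed = 6)
  sp <- generate_mip(20, 0.3, 2000, 10, seed = 7)
  V <- ground_truth_signal(b0, sp)
  Vh <- kernel_approx_signal(b0, sp)
  expect_lt(max(abs(V$traces - Vh$traces)), 1e-10 * max(abs(V$traces)))

  # identical trains: approximation equals ground truth for any kernels
  bh <- sample_toy_bank(toy_kernel_params(amp_sd = 0.5), n = 10, seed = 8)
  spi <- generate_mip(20, 1, 2000, 10, seed = 9)
  Vi <- ground_truth_signal(bh, spi)
  Vhi <- kernel_approx_signal(bh, spi)
  expect_lt(max(abs(Vi$traces - Vhi$traces)), 1e-10 * max(abs(Vi$traces)))
})

test_that("error measures implement the variance definitions", {
  mk <- function(x) signal_set(matrix(x, nrow = 1), dt = 1)
  # worked 4-sample example
  err <- empirical_error(mk(c(0, 1, 0, 1)), mk(c(0, 0, 0, 0)),
                         mode = "per_signal")
  expect_equal(err$E, 0.5)
  expect_equal(err$E_rel, 1)

  # exact agreement and mean-shift invariance
  expect_equal(empirical_error(mk(1:4), mk(1:4))$E, 0)
  expect_equal(empirical_error(mk(1:4), mk(1:4 + 7))$E, 0)

  # zero ground-truth variance: relative error is undefined, not infinite
  e0 <- empirical_error(mk(rep(2, 4)), mk(c(1, 2, 1, 2)),
                        mode = "per_signal")
  expect_true(is.na(e0$E_rel))
  expect_gt(e0$E, 0)

  # max-over-channels normalization
  V <- signal_set(rbind(c(0, 1, 0, 1), c(0, 10, 0, 10)), dt = 1)
  Vh <- signal_set(matrix(0, 2, 4), dt = 1)
  em <- empirical_error(V, Vh, mode = "max")
  expect_equal(em$E_rel, c(0.5, 5) / 5)
  expect_error(empirical_error(mk(1:4), mk(1:5)), "grid")
})

test_that("pathway superposition is linear and sign-aware", {
  bank <- fixture_random_bank(n = 4, nch = 3, L = 15, dt = 1, seed = 13)
  sp <- generate_poisson(25, 300, 4, seed = 14)
  one <- superpose_pathways(list(list(bank = bank, spikes = sp)))
  expect_equal(one$traces, ground_truth_signal(bank, sp)$traces)

  # a pathway plus its sign-flipped self cancels exactly
  two <- superpose_pathways(list(list(bank = bank, spikes = sp),
                                 list(bank = bank, spikes = sp, sign = -1)))
  expect_true(all(two$traces == 0))

  # excitatory + inhibitory pathways equal the sum of separate signals
  bank2 <- fixture_random_bank(n = 4, nch = 3, L = 15, dt = 1, seed = 15)
  sp2 <- generate_mip(15, 0.4, 300, 4, seed = 16)
  s12 <- superpose_pathways(list(list(bank = bank, spikes = sp),
                                 list(bank = bank2, spikes = sp2, sign = -1)))
  expect_equal(s12$traces,
               ground_truth_signal(bank, sp)$traces -
                 ground_truth_signal(bank2, sp2)$traces,
               tolerance = 1e-12)
})

test_that("sweeps produce one row per configuration, spike type and channel", {
  m <- fixture_morphology()
  prop <- fixture_propagator()
  bank <- build_kernel_bank(population_config(k_out = 30, n_kernels = 8,
                                              seed = 17),
                            m, prop, include_eeg = FALSE)
  res <- run_sweep(list(default = bank),
                   list(pois = spike_spec("poisson", rate = 10),
                        mip = spike_spec("mip", rate = 10, f = 0.5)),
                   duration = 2000, seed = 3)
  expect_equal(nrow(res), 2 * bank$n_channels)
  expect_true(all(c("config", "spikes", "amplitude", "E", "E_rel",
                    "th_E", "th_E_rel") %in% names(res)))
  expect_true(all(res$E >= 0 & res$amplitude >= 0))
  # correlated input raises the signal amplitude
  expect_gt(max(res$amplitude[res$spikes == "mip"]),
            max(res$amplitude[res$spikes == "pois"]))
  # theory tracks simulation to leading order
  expect_lt(abs(max(res$th_E_rel[res$spikes == "pois"]) -
                  max(res$E_rel[res$spikes == "pois"])),
            0.5 * max(res$E_rel[res$spikes == "pois"]))
  # single-config grid is consistent with direct calls
  sp <- popkernel:::.make_spikes(spike_spec("poisson", rate = 10),
                                 bank$n_kernels, 2000, seed = 3 + 1000L)
  err <- empirical_error(ground_truth_signal(bank, sp),
                         kernel_approx_signal(bank, sp))
  expect_equal(res$E[res$spikes == "pois"], err$E, tolerance = 1e-12)
})
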