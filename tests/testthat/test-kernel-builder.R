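test_that("toy kernels are causal double exponentials with exact peak", {
  p <- toy_kernel_params(dt = 0.001)
  k <- toy_kernel(2.5, p)
  expect_equal(k[1], 0)                               # zero at lag 0
  tstar <- 0.2 * 1 / (1 - 0.2) * log(1 / 0.2)
  expect_equal((which.max(k) - 1) * 0.001, tstar, tolerance = 1e-3)
  expect_equal(max(k), 2.5, tolerance = 1e-5)
  expect_true(all(toy_kernel(0, p) == 0))
  expect_error(toy_kernel_params(tau1 = 1, tau2 = 1), "alpha")
  expect_error(toy_kernel_params(tau1 = 2, tau2 = 1), "rise")
})

test_that("toy banks sample amplitudes and store an exact mean kernel", {
  b0 <- sample_toy_bank(toy_kernel_params(amp_sd = 0), n = 50, seed = 1)
  for (j in 1:50)
    expect_equal(b0$kernels[j, 1, ], b0$mean[1, ], tolerance = 1e-12)

  b <- sample_toy_bank(toy_kernel_params(amp_sd = 0.5), n = 1000, seed = 2)
  pk <- apply(b$kernels[, 1, ], 1, max)
  expect_lt(abs(sd(pk) / 0.5 - 1), 0.1)
  expect_lt(abs(mean(pk) - 1), 0.05)
  # mean consistency is exact, not approximate
  expect_identical(b$mean, colMeans(b$kernels))

  # explicit two-kernel bank
  b2 <- sample_toy_bank(amplitudes = c(0.5, 1.5))
  w <- toy_kernel(1)
  expect_equal(b2$kernels[1, 1, ], 0.5 * w, tolerance = 1e-12)
  expect_equal(b2$kernels[2, 1, ], 1.5 * w, tolerance = 1e-12)
  expect_equal(population_kernel(b2)[1, ], w, tolerance = 1e-12)
})

test_that("population realizations follow the configured distributions", {
  m <- fixture_morphology()
  # near-delta synapse depth profile concentrates synapses at the target z
  cfg <- population_config(k_out = 200, syn_z_sd = 0.5, soma_z_sd = 0,
                           syn_z_mean = -1270)
  rl <- sample_population_realization(cfg, m, seed = 1)
  zg <- (m$z0[rl$segment] + m$z1[rl$segment]) / 2 + rl$soma_z
  expect_lt(max(abs(zg + 1270)), 15)       # within a segment length

  # uniform flag: segment usage frequency is flat across segments
  cfgu <- population_config(k_out = 20000, syn_uniform = TRUE)
  rlu <- sample_population_realization(cfgu, m, seed = 2)
  tab <- tabulate(rlu$segment, nbins = nrow(m))
  expect_gt(suppressWarnings(chisq.test(tab)$p.value), 0.01)

  # depth-weighted sampling frequencies track the weighting law
  cfgw <- population_config(k_out = 50000, soma_z_sd = 0)
  rlw <- sample_population_realization(cfgw, m, seed = 3)
  w <- dnorm((m$z0 + m$z1) / 2 - 1270, -1270, 100)
  freq <- tabulate(rlw$segment, nbins = nrow(m)) / 50000
  expect_gt(cor(freq, w / sum(w)), 0.99)

  # weight, time constant and delay distributions
  cfgd <- population_config(k_out = 50000)
  rld <- sample_population_realization(cfgd, m, seed = 4)
  expect_lt(abs(mean(rld$J) - 0.1) / 0.1, 0.05)
  expect_lt(abs(sd(log(rld$J)) - 0.4) / 0.4, 0.05)
  expect_lt(abs(mean(rld$tau_syn) - 2), 0.02)
  expect_lt(abs(mean(rld$delay) - 1), 0.02)
  expect_true(all(rld$delay >= 0 & rld$tau_syn > 0))
  # soma depths capped at +/- 2 SD
  expect_true(all(abs(rld$soma_z + 1270) <= 2 * 100 + 1e-9))
  expect_true(all(sqrt(rld$x^2 + rld$y^2) <= 250))

  expect_error(sample_population_realization(
    population_config(syn_z_mean = 1e6, syn_z_sd = 1e-3), m, seed = 1),
    "zero weight")
})

test_that("single-cell kernels equal direct simulation and scale linearly", {
  m <- fixture_morphology()
  prop <- fixture_propagator()
  e <- electrode_array()
  cfg <- population_config(k_out = 1, n_kernels = 1)
  real <- sample_population_realization(cfg, m, seed = 99)
  real$delay <- round(real$delay / prop$dt) * prop$dt
  k1 <- build_single_cell_kernel(cfg, m, prop, e, head = NULL,
                                 realization = real)
  mp <- place_morphology(m, soma_z = real$soma_z, x = real$x, y = real$y,
                         rotation = real$rotation)
  sol <- solve_passive(mp, passive_params(),
                       list(synaptic_event(real$segment, real$J,
                                           real$tau_syn, real$delay)),
                       dt = prop$dt, T = 30)
  lfp <- lfp_line_source(sol, mp, e)
  expect_lt(max(abs(k1$lfp - lfp$traces)), 1e-9 * max(abs(lfp$traces)))

  # doubling every weight doubles the kernel
  real5 <- sample_population_realization(
    population_config(k_out = 5, n_kernels = 1), m, seed = 5)
  ka <- build_single_cell_kernel(cfg, m, prop, e, head = NULL,
                                 realization = real5)
  real5b <- real5; real5b$J <- 2 * real5b$J
  kb <- build_single_cell_kernel(cfg, m, prop, e, head = NULL,
                                 realization = real5b)
  expect_equal(kb$lfp, 2 * ka$lfp, tolerance = 1e-12)

  # causality: zero before the smallest (grid-rounded) synaptic delay
  lag_ms <- (seq_len(ncol(ka$lfp)) - 1) * prop$dt
  dmin <- min(round(real5$delay / prop$dt)) * prop$dt
  expect_true(all(ka$lfp[, lag_ms < dmin] == 0))
  expect_gt(max(abs(ka$lfp[, lag_ms >= dmin])), 0)
})

test_that("kernel banks have exact means and input-region structure", {
  m <- fixture_morphology()
  prop <- fixture_propagator()
  cfg1 <- population_config(k_out = 30, n_kernels = 1, seed = 3)
  b1 <- build_kernel_bank(cfg1, m, prop, include_eeg = FALSE)
  expect_equal(b1$mean, matrix(b1$kernels[1, , ], b1$n_channels, b1$n_lags),
               tolerance = 1e-15)

  mk_bank <- function(...) build_kernel_bank(
    population_config(k_out = 60, n_kernels = 15, seed = 5, ...),
    m, prop, include_eeg = FALSE)
  basal <- mk_bank()
  apical <- mk_bank(syn_z_mean = -200, name = "apical")
  unif <- mk_bank(syn_uniform = TRUE, name = "uniform")
  expect_identical(basal$mean, colMeans(basal$kernels))

  # basal and apical inputs give opposite-polarity responses at the
  # uppermost contact
  pk <- function(b, ch) {
    v <- b$mean[ch, ]; v[which.max(abs(v))]
  }
  expect_lt(pk(basal, 1) * pk(apical, 1), 0)
  # uniform input: weak population kernel at every depth
  expect_true(all(apply(abs(unif$mean), 1, max) <
                    apply(abs(basal$mean), 1, max)))

  # EEG kernels exist, are causal, and are orders of magnitude below the
  # LFP peak even after unit conversion (pV vs uV)
  be <- build_kernel_bank(population_config(k_out = 40, n_kernels = 3,
                                            seed = 6), m, prop)
  expect_equal(dim(be$eeg), c(3, be$n_lags))
  expect_equal(be$eeg_mean, colMeans(be$eeg))
  expect_lt(max(abs(be$eeg_mean)) * 1e-6,      # pV -> uV
            1e-2 * max(abs(be$mean)))
})
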