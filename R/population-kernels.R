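#' Population / connectivity configuration for biophysical kernels
#'
#' All heterogeneity sources entering a synaptic pathway's single-cell
#' kernels: population geometry, out-degree, synaptic weight, time-constant
#' and delay distributions, and the synapse depth profile.
#'
#' Defaults are the basal-input "default" configuration: postsynaptic somas
#' at depth Normal(-1270, 100) um capped at +/- 2 SD, horizontal positions
#' uniform on a disc of radius 250 um, out-degree 500, one synapse per
#' postsynaptic cell whose segment is drawn from all segments weighted by a
#' Normal(-1270, 100) depth profile, synaptic weight lognormal with mean
#' 0.1 nA and shape `s = 0.4`, time constant Normal(2, 0.2) ms (floored at
#' 0.1 ms), delay Normal(1, 0.2) ms (floored at 0).
#'
#' @param r_pop population disc radius (um).
#' @param k_out out-degree: number of postsynaptic target cells per
#'   presynaptic neuron.
#' @param soma_z_mean,soma_z_sd soma depth distribution (um).
#' @param soma_z_cap cap (in SDs) of the soma depth distribution.
#' @param syn_z_mean,syn_z_sd synapse depth-profile Normal (um); ignored if
#'   `syn_uniform`.
#' @param syn_uniform if `TRUE`, synapses are drawn uniformly over all
#'   segments of the morphology instead of depth-weighted.
#' @param j_mean,j_s lognormal synaptic weight: distribution mean (nA) and
#'   shape parameter `s` (sdlog).
#' @param tau_syn_mean,tau_syn_sd synaptic decay time constant Normal (ms).
#' @param delay_mean,delay_sd synaptic delay Normal (ms).
#' @param n_kernels number of single-cell kernels per bank.
#' @param kernel_length kernel duration (ms).
#' @param dt kernel time resolution (ms), default 2^-4.
#' @param seed integer seed for bank building.
#' @param name configuration label.
#' @return an object of class `population_config`.
#' @export
population_config <- function(r_pop = 250, k_out = 500,
                              soma_z_mean = -1270, soma_z_sd = 100,
                              soma_z_cap = 2,
                              syn_z_mean = -1270, syn_z_sd = 100,
                              syn_uniform = FALSE,
                              j_mean = 0.1, j_s = 0.4,
                              tau_syn_mean = 2, tau_syn_sd = 0.2,
                              delay_mean = 1, delay_sd = 0.2,
                              n_kernels = 100, kernel_length = 30,
                              dt = 2^-4, seed = 1, name = "default") {
  if (k_out < 1) stop("`k_out` must be >= 1")
  if (r_pop <= 0) stop("`r_pop` must be > 0")
  if (any(c(soma_z_sd, syn_z_sd, tau_syn_sd, delay_sd, j_s) < 0))
    stop("standard deviations must be >= 0")
  structure(as.list(environment()), class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat("population_config [", x$name, "]: k_out = ", x$k_out,
      ", r_pop = ", x$r_pop, " um, syn z ",
      if (x$syn_uniform) "uniform" else
        paste0("N(", x$syn_z_mean, ", ", x$syn_z_sd, ")"),
      ", ", x$n_kernels, " kernels\n", sep = "")
  invisible(x)
}

#' The standard configuration variants
#'
#' Named list of the default basal-input configuration and its standard
#' variants: apical and uniform input regions, halved/doubled population
#' radius, out-degree, synaptic-parameter variability, and input-region
#' width.
#'
#' @param ... overrides applied to every configuration (e.g. reduced
#'   `k_out` or `n_kernels` for quick experiments).
#' @return named list of [population_config()]s.
#' @export
table1_configs <- function(...) {
  base <- list(...)
  mk <- function(name, ...) {
    args <- utils::modifyList(c(list(name = name), base), list(...))
    do.call(population_config, args)
  }
  base_kout <- if (!is.null(base$k_out)) base$k_out else 500
  list(
    default            = mk("default"),
    apical             = mk("apical", syn_z_mean = -200),
    uniform            = mk("uniform", syn_uniform = TRUE),
    small_radius       = mk("small_radius", r_pop = 125),
    large_radius       = mk("large_radius", r_pop = 500),
    small_kout         = mk("small_kout", k_out = max(1L, base_kout %/% 2)),
    large_kout         = mk("large_kout", k_out = base_kout * 2L),
    similar_synapses   = mk("similar_synapses", tau_syn_sd = 0.1,
                            delay_sd = 0.1, j_s = 0.2),
    variable_synapses  = mk("variable_synapses", tau_syn_sd = 0.4,
                            delay_sd = 0.4, j_s = 0.8),
    narrow_input       = mk("narrow_input", syn_z_sd = 50),
    broad_input        = mk("broad_input", syn_z_sd = 200))
}

# truncated-normal draw via inverse CDF, bounds in SDs around the mean
.rnorm_capped <- function(n, mean, sd, cap) {
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(-cap), stats::pnorm(cap))
  mean + sd * stats::qnorm(u)
}

#' Sample one population realization for a presynaptic neuron
#'
#' Draws the `k_out` postsynaptic cells reached by one presynaptic axon:
#' their placements (soma depth from the capped normal, horizontal position
#' uniform on the population disc, random z rotation) and, for the single
#' synapse on each cell, the target segment (depth-weighted or uniform over
#' segments), lognormal weight `J`, normal `tau_syn` (floored at 0.1 ms) and
#' normal delay (floored at 0).
#'
#' @param cfg a [population_config()].
#' @param m the postsynaptic `morphology` (local coordinates, soma at 0).
#' @param seed optional integer seed.
#' @return data.frame with one row per postsynaptic cell: `soma_z`, `x`,
#'   `y`, `rotation`, `segment`, `J`, `tau_syn`, `delay`.
#' @export
sample_population_realization <- function(cfg, m, seed = NULL) {
  stopifnot(inherits(cfg, "population_config"), inherits(m, "morphology"))
  if (!is.null(seed)) set.seed(seed)
  k <- cfg$k_out
  soma_z <- .rnorm_capped(k, cfg$soma_z_mean, cfg$soma_z_sd, cfg$soma_z_cap)
  rr <- cfg$r_pop * sqrt(stats::runif(k))
  phi <- stats::runif(k, 0, 2 * pi)
  rot <- stats::runif(k, 0, 2 * pi)
  seg_z_local <- (m$z0 + m$z1) / 2
  segment <- integer(k)
  for (i in seq_len(k)) {
    w <- if (cfg$syn_uniform) rep(1, nrow(m))
    else stats::dnorm(seg_z_local + soma_z[i], cfg$syn_z_mean, cfg$syn_z_sd)
    if (!any(w > 0))
      stop("synapse depth profile assigns zero weight to every segment")
    segment[i] <- sample.int(nrow(m), 1L, prob = w)
  }
  # lognormal with distribution mean j_mean and shape s: scale solved from
  # mean = scale * exp(s^2 / 2)
  meanlog <- log(cfg$j_mean) - cfg$j_s^2 / 2
  J <- stats::rlnorm(k, meanlog, cfg$j_s)
  tau_syn <- pmax(stats::rnorm(k, cfg$tau_syn_mean, cfg$tau_syn_sd), 0.1)
  delay <- pmax(stats::rnorm(k, cfg$delay_mean, cfg$delay_sd), 0)
  data.frame(soma_z = soma_z, x = rr * cos(phi), y = rr * sin(phi),
             rotation = rot, segment = segment, J = J, tau_syn = tau_syn,
             delay = delay)
}

# four-sphere vertex transfer (V per A m) as a smooth function of soma
# depth, interpolated on a 2-um grid spanning the capped soma distribution
.eeg_transfer_interp <- function(cfg, head) {
  zr <- cfg$soma_z_mean + c(-1, 1) * (cfg$soma_z_cap * cfg$soma_z_sd + 10)
  zg <- seq(zr[1], zr[2], by = 2)
  tf <- vapply(zg, function(z)
    .four_sphere_transfer(head$radii[1L] + z * 1e-3, head), numeric(1L))
  stats::approxfun(zg, tf, rule = 2)
}

# internal line-source mapping on raw endpoint matrices (a, b: n x 3)
.lfp_mapping_fast <- function(a, b, len, is_soma, pos, sigma, r_min) {
  n_el <- nrow(pos)
  n_seg <- nrow(a)
  ds <- b - a
  mid <- (a + b) / 2
  M <- matrix(0, n_el, n_seg)
  for (i in seq_len(n_el)) {
    rel <- a - matrix(pos[i, ], n_seg, 3, byrow = TRUE)
    lproj <- -(rel[, 1] * ds[, 1] + rel[, 2] * ds[, 2] +
                 rel[, 3] * ds[, 3]) / len
    r <- pmax(sqrt(pmax(rowSums(rel^2) - lproj^2, 0)), r_min)
    l <- lproj; h <- lproj - len
    M[i, ] <- 1e3 / (4 * pi * sigma * len) *
      log((sqrt(l^2 + r^2) + l) / (sqrt(h^2 + r^2) + h))
    if (any(is_soma)) {
      rs <- sqrt(rowSums((mid[is_soma, , drop = FALSE] -
                            matrix(pos[i, ], sum(is_soma), 3,
                                   byrow = TRUE))^2))
      M[i, is_soma] <- 1e3 / (4 * pi * sigma * pmax(rs, r_min))
    }
  }
  M
}

# convolution of the per-segment one-step impulse response x with the
# sampled synaptic current J exp(-(t - delay)/tau), delay rounded to the
# grid, under the Crank-Nicolson trapezoid input rule: the effective input
# sequence is (w_k + w_{k+1})/2, i.e. J/2 at the bin before onset plus
# J (1 + a)/2 times the decaying exponential from the onset bin. This makes
# the cached path bit-compatible with solve_passive.
.syn_filter <- function(x, J, tau, delay, dt) {
  a <- exp(-dt / tau)
  z <- t(stats::filter(t(x), a, method = "recursive"))
  db <- as.integer(round(delay / dt))
  nt <- ncol(x)
  shift <- function(m, k) {
    if (k <= 0) return(m)
    cbind(matrix(0, nrow(m), k), m[, seq_len(nt - k), drop = FALSE])
  }
  y <- J * (1 + a) / 2 * shift(z, db)
  if (db >= 1L) y <- y + J / 2 * shift(x, db - 1L)
  y
}

#' Build one single-cell spike-to-signal kernel
#'
#' The kernel of presynaptic neuron `j` is the summed extracellular response
#' of its `k_out` postsynaptic targets to one spike at lag 0. Each target's
#' response is computed from the cached per-segment impulse responses of the
#' cable model (`propagator`), projected through that cell's line-source
#' mapping, convolved with its synaptic current waveform
#' `J exp(-(t - delay)/tau_syn)` (delay rounded to the lag grid), exploiting
#' the linearity of the cable and volume-conductor models. EEG kernels use
#' the z component of each cell's current dipole and the four-sphere
#' transfer at the cell's depth.
#'
#' @param cfg a [population_config()].
#' @param m postsynaptic `morphology` (local coordinates).
#' @param propagator a [segment_propagator()] for `m` at the kernel grid.
#' @param electrodes an [electrode_array()].
#' @param head a [four_sphere_params()], or `NULL` to skip EEG kernels.
#' @param seed seed for the population realization.
#' @param realization optional precomputed
#'   [sample_population_realization()] output.
#' @param eeg_transfer optional precomputed four-sphere vertex transfer as a
#'   function of soma depth (built internally when omitted).
#' @return list with `lfp` (channels x lags, uV per spike) and `eeg`
#'   (vector over lags, pV per spike, or `NULL`).
#' @export
build_single_cell_kernel <- function(cfg, m, propagator,
                                     electrodes = electrode_array(),
                                     head = four_sphere_params(),
                                     seed = NULL, realization = NULL,
                                     eeg_transfer = NULL) {
  stopifnot(inherits(propagator, "cable_propagator"))
  if (is.null(realization))
    realization <- sample_population_realization(cfg, m, seed)
  if (!is.null(head) && is.null(eeg_transfer))
    eeg_transfer <- .eeg_transfer_interp(cfg, head)
  dt <- propagator$dt
  nt <- propagator$n_steps
  a0 <- cbind(m$x0, m$y0, m$z0)
  b0 <- cbind(m$x1, m$y1, m$z1)
  geo <- .segment_geometry(m)
  is_soma <- m$label == "soma"
  n_el <- nrow(electrodes$pos)
  lfp <- matrix(0, n_el, nt)
  eeg <- if (!is.null(head)) numeric(nt)
  soma_z <- realization$soma_z; xs <- realization$x; ys <- realization$y
  rots <- realization$rotation; segs <- realization$segment
  Js <- realization$J; taus <- realization$tau_syn
  delays <- realization$delay
  for (i in seq_along(soma_z)) {
    cs <- cos(rots[i]); sn <- sin(rots[i])
    a <- cbind(cs * a0[, 1] - sn * a0[, 2] + xs[i],
               sn * a0[, 1] + cs * a0[, 2] + ys[i], a0[, 3] + soma_z[i])
    b <- cbind(cs * b0[, 1] - sn * b0[, 2] + xs[i],
               sn * b0[, 1] + cs * b0[, 2] + ys[i], b0[, 3] + soma_z[i])
    H <- propagator$H[[segs[i]]]
    M <- .lfp_mapping_fast(a, b, geo$len, is_soma, electrodes$pos,
                           electrodes$sigma, electrodes$r_min)
    if (!is.null(head)) M <- rbind(M, (a[, 3] + b[, 3]) / 2)
    resp <- .syn_filter(M %*% H, Js[i], taus[i], delays[i], dt)
    lfp <- lfp + resp[seq_len(n_el), , drop = FALSE]
    if (!is.null(head))
      # dipole z in nA um (1e-15 A m) through the scalp transfer, in pV
      eeg <- eeg + resp[n_el + 1L, ] * 1e-3 * eeg_transfer(soma_z[i])
  }
  # tail-energy check: the kernel should essentially decay within its window
  tail_e <- sum(lfp[, max(1L, nt - 15L):nt]^2)
  if (tail_e > 0.01 * sum(lfp^2))
    warning("kernel length may be too short: >1% of the kernel energy ",
            "lies in the final milliseconds")
  list(lfp = lfp, eeg = eeg)
}

#' Build a bank of biophysical single-cell kernels
#'
#' Draws `cfg$n_kernels` independent population realizations and assembles
#' their single-cell LFP (and EEG) kernels and the population-mean kernel.
#' The morphology, cable propagator, electrode array and head model may be
#' shared across configurations (they do not depend on `cfg`); when omitted
#' they are built with standard settings.
#'
#' @inheritParams build_single_cell_kernel
#' @param p a [passive_params()] (used when `propagator` is `NULL`).
#' @param include_eeg build EEG kernels as well.
#' @return a [kernel_bank()].
#' @export
build_kernel_bank <- function(cfg, m = NULL, propagator = NULL,
                              electrodes = electrode_array(),
                              p = passive_params(),
                              head = four_sphere_params(),
                              include_eeg = TRUE) {
  stopifnot(inherits(cfg, "population_config"))
  if (is.null(m)) m <- build_stylized_l5(seed = 42)
  if (is.null(propagator))
    propagator <- segment_propagator(m, p, dt = cfg$dt, T = cfg$kernel_length)
  nt <- propagator$n_steps
  n_el <- nrow(electrodes$pos)
  kern <- array(0, dim = c(cfg$n_kernels, n_el, nt))
  eeg <- if (include_eeg) matrix(0, cfg$n_kernels, nt)
  tf <- if (include_eeg) .eeg_transfer_interp(cfg, head)
  for (j in seq_len(cfg$n_kernels)) {
    kj <- build_single_cell_kernel(
      cfg, m, propagator, electrodes,
      head = if (include_eeg) head,
      seed = cfg$seed * 100003L + j, eeg_transfer = tf)
    kern[j, , ] <- kj$lfp
    if (include_eeg) eeg[j, ] <- kj$eeg
  }
  kernel_bank(kern, dt = propagator$dt, channels = electrodes$pos[, "z"],
              eeg = eeg, unit = "uV", config = cfg)
}
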