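#' Passive membrane parameters
#'
#' @param rm membrane resistivity (Ohm cm^2).
#' @param cm specific capacitance (uF/cm^2).
#' @param ra axial resistivity (Ohm cm).
#' @return an object of class `passive_params`.
#' @export
passive_params <- function(rm = 30000, cm = 1, ra = 150) {
  if (rm <= 0 || cm <= 0 || ra <= 0) stop("all passive parameters must be > 0")
  structure(list(rm = rm, cm = cm, ra = ra), class = "passive_params")
}

#' A synaptic event (current-based, exponential decay)
#'
#' Current `J * exp(-(t - delay)/tau_syn)` for `t >= delay`, injected at one
#' segment. The sign of `J` encodes excitatory (positive, inward) versus
#' inhibitory input.
#'
#' @param segment target segment index (row of the morphology).
#' @param J peak synaptic current (nA).
#' @param tau_syn decay time constant (ms, > 0).
#' @param delay onset delay (ms, >= 0).
#' @export
synaptic_event <- function(segment, J, tau_syn = 2, delay = 0) {
  if (tau_syn <= 0) stop("`tau_syn` must be > 0")
  if (delay < 0) stop("`delay` must be >= 0")
  structure(list(segment = as.integer(segment), J = J, tau_syn = tau_syn,
                 delay = delay), class = "synaptic_event")
}

# conductance-structure of the compartmental tree:
# cap (nF), g_leak (uS), Laplacian L of axial conductances (uS)
.cable_system <- function(m, p) {
  geo <- .segment_geometry(m)
  area_cm2 <- geo$area * 1e-8
  cap <- p$cm * area_cm2 * 1e3          # nF
  g_leak <- area_cm2 / p$rm * 1e6       # uS
  # axial half-segment resistances (Ohm)
  l_cm <- geo$len * 1e-4
  r_cm <- m$diam / 2 * 1e-4
  r_half <- p$ra * (l_cm / 2) / (pi * r_cm^2)
  n <- nrow(m)
  ii <- which(m$parent > 0L)
  g_ax <- 1 / (r_half[ii] + r_half[m$parent[ii]]) * 1e6   # uS
  L <- Matrix::sparseMatrix(
    i = c(ii, m$parent[ii], ii, m$parent[ii]),
    j = c(m$parent[ii], ii, ii, m$parent[ii]),
    x = c(-g_ax, -g_ax, g_ax, g_ax), dims = c(n, n))
  list(cap = cap, g_leak = g_leak, L = L, n = n)
}

#' Solve passive cable dynamics for synaptic input
#'
#' Linear compartmental dynamics on the morphology tree, integrated with the
#' unconditionally stable Crank-Nicolson (trapezoidal) scheme. The returned
#' transmembrane currents (capacitive + leak + synaptic, outward positive)
#' are computed as the net axial inflow, so they sum to zero across segments
#' at every time step to machine precision. Responses are exactly linear in
#' the events.
#'
#' @param m a `morphology`.
#' @param p a [passive_params()].
#' @param events list of [synaptic_event()]s.
#' @param dt time step (ms).
#' @param T total simulated time (ms).
#' @param return_v also return membrane potentials.
#' @return An object of class `membrane_currents`: list with `I` (nA,
#'   segments x time), `dt`, `t` (ms), and optionally `V` (mV).
#' @export
solve_passive <- function(m, p, events, dt = 2^-4, T = 30,
                          return_v = FALSE) {
  stopifnot(inherits(m, "morphology"), inherits(p, "passive_params"))
  sys <- .cable_system(m, p)
  n <- sys$n
  nt <- as.integer(round(T / dt)) + 1L
  tvec <- (seq_len(nt) - 1L) * dt
  # sampled synaptic currents per segment (only rows that receive input)
  isyn <- matrix(0, n, nt)
  for (ev in events) {
    if (!inherits(ev, "synaptic_event")) stop("events must be synaptic_event")
    if (ev$segment < 1L || ev$segment > n)
      stop("event targets nonexistent segment ", ev$segment)
    on <- tvec >= ev$delay - 1e-12
    isyn[ev$segment, on] <- isyn[ev$segment, on] +
      ev$J * exp(-(tvec[on] - ev$delay) / ev$tau_syn)
  }
  G <- sys$L + Matrix::Diagonal(n, sys$g_leak)
  Cdt <- Matrix::Diagonal(n, sys$cap / dt)
  M1 <- Cdt + G / 2
  M2 <- Cdt - G / 2
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M1), LDL = FALSE)
  V <- matrix(0, n, nt)
  v <- numeric(n)
  for (k in seq_len(nt - 1L)) {
    rhs <- M2 %*% v + (isyn[, k] + isyn[, k + 1L]) / 2
    v <- as.numeric(Matrix::solve(ch, rhs))
    V[, k + 1L] <- v
  }
  I <- -as.matrix(sys$L %*% V)
  out <- list(I = I, dt = dt, t = tvec)
  if (return_v) out$V <- V
  class(out) <- "membrane_currents"
  out
}

#' @export
print.membrane_currents <- function(x, ...) {
  cat("membrane_currents:", nrow(x$I), "segments x", ncol(x$I),
      "time steps (dt =", x$dt, "ms)\n")
  invisible(x)
}

#' Per-segment discrete impulse-response propagator
#'
#' Transmembrane-current responses of every segment to a unit current (1 nA
#' for one time step) injected at each segment in turn, computed with the
#' same Crank-Nicolson discretization as [solve_passive()]. Because the
#' discretized system is linear and time invariant, the response to any
#' sampled input current sequence is the discrete convolution of these
#' impulse responses with that sequence — which is how kernel building
#' reuses one cable solution for arbitrarily many synapses.
#'
#' @inheritParams solve_passive
#' @param segments input segment indices (default: all).
#' @return An object of class `cable_propagator`: list with `H` (list over
#'   input segments of segments x time current matrices, nA), `segments`,
#'   `dt`, `n_steps`.
#' @export
segment_propagator <- function(m, p, dt = 2^-4, T = 30, segments = NULL) {
  sys <- .cable_system(m, p)
  n <- sys$n
  if (is.null(segments)) segments <- seq_len(n)
  nt <- as.integer(round(T / dt)) + 1L
  G <- sys$L + Matrix::Diagonal(n, sys$g_leak)
  Cdt <- Matrix::Diagonal(n, sys$cap / dt)
  M1 <- Cdt + G / 2
  M2 <- Cdt - G / 2
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(M1), LDL = FALSE)
  ns <- length(segments)
  V <- matrix(0, n, ns)
  # raw one-step impulse response (full weight); the kernel builder applies
  # the Crank-Nicolson trapezoid weighting of the synaptic current sequence
  # itself, so cached convolution reproduces solve_passive exactly
  U0 <- matrix(0, n, ns)
  U0[cbind(segments, seq_len(ns))] <- 1
  H <- array(0, dim = c(n, ns, nt))
  for (k in seq_len(nt - 1L)) {
    rhs <- M2 %*% V
    if (k == 1L) rhs <- rhs + U0
    V <- as.matrix(Matrix::solve(ch, rhs))
    H[, , k + 1L] <- -as.matrix(sys$L %*% V)
  }
  Hl <- lapply(seq_len(ns), function(j) H[, j, ])
  names(Hl) <- as.character(segments)
  structure(list(H = Hl, segments = segments, dt = dt, n_steps = nt),
            class = "cable_propagator")
}
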