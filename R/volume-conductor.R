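#' Linear multi-contact electrode array
#'
#' Default layout: 16 contacts on a vertical axis, 100 um apart, spanning
#' depths 0 to -1500 um, in an infinite homogeneous volume conductor of
#' conductivity `sigma`.
#'
#' @param z contact depths (um).
#' @param x,y horizontal contact position (um).
#' @param sigma extracellular conductivity (S/m), default 0.3.
#' @param r_min minimum source-contact distance (um); distances are clamped
#'   to avoid the line/point-source singularity.
#' @return an object of class `electrode_array` with `pos` (n x 3) and
#'   `sigma`.
#' @export
electrode_array <- function(z = seq(0, -1500, by = -100), x = 0, y = 0,
                            sigma = 0.3, r_min = 5) {
  if (sigma <= 0) stop("`sigma` must be > 0")
  pos <- cbind(x = rep(x, length.out = length(z)),
               y = rep(y, length.out = length(z)), z = z)
  structure(list(pos = pos, sigma = sigma, r_min = r_min),
            class = "electrode_array")
}

#' Line-source mapping matrix
#'
#' Matrix `M` (contacts x segments) such that `M %*% I` gives the
#' extracellular potential in uV from transmembrane currents `I` in nA.
#' Dendritic segments contribute as uniform line sources (closed form for a
#' finite line of current in an infinite homogeneous medium); the soma
#' segment is treated as a point source at its midpoint.
#'
#' @param m a `morphology` (already placed in global coordinates).
#' @param e an [electrode_array()].
#' @return numeric matrix, n_contacts x n_segments.
#' @export
lfp_mapping <- function(m, e) {
  stopifnot(inherits(m, "morphology"), inherits(e, "electrode_array"))
  n_el <- nrow(e$pos)
  n_seg <- nrow(m)
  geo <- .segment_geometry(m)
  M <- matrix(0, n_el, n_seg)
  a <- cbind(m$x0, m$y0, m$z0)
  b <- cbind(m$x1, m$y1, m$z1)
  ds <- b - a
  len <- geo$len
  is_soma <- m$label == "soma"
  # scale 1e3: nA, um, S/m -> uV
  for (i in seq_len(n_el)) {
    ep <- e$pos[i, ]
    rel <- sweep(a, 2L, ep, "-")            # a - e
    # longitudinal coordinate of the electrode along each segment axis
    lproj <- -(rel[, 1] * ds[, 1] + rel[, 2] * ds[, 2] +
                 rel[, 3] * ds[, 3]) / len
    d2 <- rowSums(rel^2)
    r2 <- pmax(d2 - lproj^2, 0)
    r <- pmax(sqrt(r2), e$r_min)
    l <- lproj
    h <- lproj - len
    num <- sqrt(l^2 + r^2) + l
    den <- sqrt(h^2 + r^2) + h
    M[i, ] <- 1e3 / (4 * pi * e$sigma * len) * log(num / den)
    if (any(is_soma)) {
      mid <- geo$mid[is_soma, , drop = FALSE]
      rs <- sqrt(rowSums(sweep(mid, 2L, ep, "-")^2))
      M[i, is_soma] <- 1e3 / (4 * pi * e$sigma * pmax(rs, e$r_min))
    }
  }
  M
}

#' Extracellular potentials via the line-source approximation
#'
#' @param currents a `membrane_currents` object from [solve_passive()].
#' @param m the (placed) `morphology` the currents belong to.
#' @param e an [electrode_array()].
#' @return a [signal_set()] in uV (contacts x time).
#' @export
lfp_line_source <- function(currents, m, e) {
  stopifnot(inherits(currents, "membrane_currents"))
  M <- lfp_mapping(m, e)
  signal_set(M %*% currents$I, dt = currents$dt, channels = e$pos[, "z"],
             label = "lfp", unit = "uV")
}

#' Current dipole moment of a membrane-current distribution
#'
#' `p(t) = sum_n I_n(t) r_n` with `r_n` the segment midpoints. For
#' current-conserving distributions (the cable solver guarantees
#' `sum_n I_n = 0`) the dipole moment is independent of the coordinate
#' origin; a warning is issued otherwise.
#'
#' @inheritParams lfp_line_source
#' @return an object of class `dipole_trace`: list with `p` (3 x time,
#'   nA um), `dt`.
#' @export
current_dipole <- function(currents, m) {
  stopifnot(inherits(currents, "membrane_currents"))
  geo <- .segment_geometry(m)
  net <- max(abs(colSums(currents$I)))
  scale <- max(abs(currents$I), 1e-300)
  if (net > 1e-8 * scale)
    warning("net membrane current is nonzero; dipole moment is ",
            "origin-dependent")
  structure(list(p = t(geo$mid) %*% currents$I, dt = currents$dt),
            class = "dipole_trace")
}

#' Concentric four-sphere head model
#'
#' @param radii outer radii of brain, CSF, skull and scalp shells (mm).
#' @param sigma conductivities of the four shells (S/m).
#' @return an object of class `four_sphere_params`.
#' @export
four_sphere_params <- function(radii = c(79, 80, 85, 90),
                               sigma = c(0.3, 1.5, 0.015, 0.3)) {
  if (length(radii) != 4L || length(sigma) != 4L)
    stop("need four radii and four conductivities")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (any(sigma <= 0)) stop("conductivities must be > 0")
  structure(list(radii = radii, sigma = sigma), class = "four_sphere_params")
}

# per-unit radial dipole transfer (V per A m) for a dipole on the z axis at
# radius rz_mm, electrode on the scalp surface at polar angle theta.
# Analytical spherical-harmonic series; each order solved as a well-scaled
# 7x7 boundary-value system.
.four_sphere_transfer <- function(rz_mm, head, theta = 0, n_max = 300,
                                  tol = 1e-9) {
  r4 <- head$radii[4L]
  x1 <- head$radii[1L] / r4
  x2 <- head$radii[2L] / r4
  x3 <- head$radii[3L] / r4
  rho <- rz_mm / r4
  if (rho <= 0 || rho >= x1)
    stop("dipole must lie strictly inside the brain sphere")
  s <- head$sigma
  t2 <- x1 / x2; t3 <- x2 / x3; t4 <- x3
  cth <- cos(theta)
  Pnm1 <- 1; Pn <- cth                       # P_0, P_1
  total <- 0; small <- 0L
  for (n in seq_len(n_max)) {
    Sx1 <- n * exp((n - 1) * log(rho) - (n + 1) * log(x1))
    A <- matrix(0, 7, 7)
    rhs <- numeric(7)
    # unknowns: a1, a2, b2, a3, b3, a4, b4 (shell-scaled)
    A[1, ] <- c(1, -t2^n, -1, 0, 0, 0, 0);            rhs[1] <- -Sx1
    A[2, ] <- c(s[1] * n, -s[2] * n * t2^n, s[2] * (n + 1), 0, 0, 0, 0)
    rhs[2] <- s[1] * (n + 1) * Sx1
    A[3, ] <- c(0, 1, t2^(n + 1), -t3^n, -1, 0, 0)
    A[4, ] <- c(0, s[2] * n, -s[2] * (n + 1) * t2^(n + 1),
                -s[3] * n * t3^n, s[3] * (n + 1), 0, 0)
    A[5, ] <- c(0, 0, 0, 1, t3^(n + 1), -t4^n, -1)
    A[6, ] <- c(0, 0, 0, s[3] * n, -s[3] * (n + 1) * t3^(n + 1),
                -s[4] * n * t4^n, s[4] * (n + 1))
    A[7, ] <- c(0, 0, 0, 0, 0, n, -(n + 1) * t4^(n + 1))
    u <- solve(A, rhs)
    term <- (u[6] + u[7] * t4^(n + 1)) * Pn
    total <- total + term
    small <- if (abs(term) < tol * max(abs(total), 1e-300)) small + 1L else 0L
    if (small >= 3L) break
    if (n == n_max && small < 3L)
      stop("four-sphere series did not converge at order ", n_max)
    # advance Legendre recurrence to P_{n+1}
    Pnext <- ((2 * n + 1) * cth * Pn - n * Pnm1) / (n + 1)
    Pnm1 <- Pn; Pn <- Pnext
  }
  r4_m <- r4 * 1e-3
  total / (4 * pi * s[1] * r4_m^2)           # V per (A m)
}

#' Scalp EEG from a current dipole in the four-sphere head model
#'
#' Places the dipole on the vertical axis through the population at radius
#' `r_brain + z` (with `z` the cortical depth in um, negative below the
#' surface) and evaluates the analytical concentric-sphere series at a scalp
#' electrode directly above the population (polar angle `theta = 0` from the
#' dipole axis, where by symmetry only the radial (z) dipole component
#' contributes; tangential components cancel).
#'
#' @param dipole a `dipole_trace` (nA um).
#' @param location cortical depth z of the dipole (um, <= 0), or a 3-vector
#'   whose z component is used.
#' @param head a [four_sphere_params()].
#' @param theta scalp electrode polar angle (radians) from the dipole axis.
#' @param n_max,tol series truncation order and relative tolerance.
#' @return numeric vector: scalp potential over time in pV.
#' @export
eeg_four_sphere <- function(dipole, location, head = four_sphere_params(),
                            theta = 0, n_max = 300, tol = 1e-9) {
  stopifnot(inherits(dipole, "dipole_trace"))
  z <- if (length(location) == 3L) location[3L] else location[1L]
  rz_mm <- head$radii[1L] + z * 1e-3
  tf <- .four_sphere_transfer(rz_mm, head, theta = theta, n_max = n_max,
                              tol = tol)
  # nA um = 1e-15 A m; V -> pV is 1e12
  as.numeric(dipole$p[3L, ] * 1e-15 * tf * 1e12)
}
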