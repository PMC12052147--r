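test_that("stylized morphology is deterministic, connected and placeable", {
  m <- fixture_morphology()
  expect_identical(m, build_stylized_l5(seed = 42))
  expect_false(identical(m, build_stylized_l5(seed = 43)))

  # tree: single root, every child starts at its parent's end point
  expect_equal(sum(m$parent == 0), 1)
  for (i in which(m$parent > 0)) {
    pr <- m[m$parent[i], ]
    d_end <- sqrt((m$x0[i] - pr$x1)^2 + (m$y0[i] - pr$y1)^2 +
                    (m$z0[i] - pr$z1)^2)
    d_start <- sqrt((m$x0[i] - pr$x0)^2 + (m$y0[i] - pr$y0)^2 +
                      (m$z0[i] - pr$z0)^2)
    expect_lt(min(d_end, d_start), 1e-9)
  }
  geo <- popkernel:::.segment_geometry(m)
  expect_true(all(geo$len > 0))

  # rotation about z leaves depths unchanged
  mr <- place_morphology(m, rotation = 1.1)
  expect_equal(mr$z0, m$z0, tolerance = 1e-12)
  expect_equal(mr$z1, m$z1, tolerance = 1e-12)

  # placed at -1270 um the tuft reaches the upper electrodes
  mp <- place_morphology(m, soma_z = -1270)
  expect_gt(max(pmax(mp$z0, mp$z1)), -300)
  ext <- diff(range(c(mp$z0, mp$z1)))
  expect_gt(ext, 1100); expect_lt(ext, 1500)
})

test_that("morphologies round-trip through the SWC-like text format", {
  m <- fixture_morphology()
  path <- tempfile(fileext = ".swc")
  write_morphology(m, path)
  m2 <- read_morphology(path)
  expect_equal(m2$x1, m$x1, tolerance = 1e-7)
  expect_equal(m2$z0, m$z0, tolerance = 1e-7)
  expect_equal(m2$diam, m$diam, tolerance = 1e-7)
  expect_identical(m2$parent, m$parent)
  expect_identical(as.character(m2$label), as.character(m$label))
  unlink(path)
})

test_that("passive solver conserves current, is linear and matches RC theory", {
  m <- place_morphology(fixture_morphology(), soma_z = -1270)
  p <- passive_params()
  ev <- list(synaptic_event(50, 0.2, 2, 1), synaptic_event(120, -0.1, 3, 0.5))

  s0 <- solve_passive(m, p, list(), dt = 2^-4, T = 5)
  expect_true(all(s0$I == 0))

  sol <- solve_passive(m, p, ev, dt = 2^-4, T = 25)
  expect_lt(max(abs(colSums(sol$I))), 1e-8 * max(abs(sol$I)))

  sA <- solve_passive(m, p, ev[1], dt = 2^-4, T = 25)
  sB <- solve_passive(m, p, ev[2], dt = 2^-4, T = 25)
  expect_lt(max(abs(sol$I - sA$I - sB$I)), 1e-10 * max(abs(sol$I)))

  expect_error(solve_passive(m, p, list(synaptic_event(9999, 1, 2, 0))),
               "nonexistent")

  # single-compartment reduction against the closed-form RC response
  soma <- m[1, , drop = FALSE]
  class(soma) <- c("morphology", "data.frame")
  rc <- solve_passive(soma, p, list(synaptic_event(1, 0.5, 2, 0)),
                      dt = 2^-4, T = 40, return_v = TRUE)
  geo <- popkernel:::.segment_geometry(soma)
  g <- geo$area * 1e-8 / p$rm * 1e6
  C <- p$cm * geo$area * 1e-8 * 1e3
  vex <- 0.5 / (g - C / 2) * (exp(-rc$t / 2) - exp(-rc$t * g / C))
  expect_lt(max(abs(rc$V[1, ] - vex)) / max(abs(vex)), 1e-3)
})

test_that("line-source potentials match monopole and quadrature oracles", {
  m <- place_morphology(fixture_morphology(), soma_z = -1270)
  e <- electrode_array()
  M <- lfp_mapping(m, e)

  # soma is a point source: 1/(4 pi sigma r) exactly
  geo <- popkernel:::.segment_geometry(m)
  r1 <- sqrt(sum((geo$mid[1, ] - e$pos[14, ])^2))
  expect_equal(M[14, 1], 1e3 / (4 * pi * e$sigma * r1), tolerance = 1e-12)

  # dendritic segments: dense point-source quadrature within 1%
  for (seg in c(30, 60, 100, 150)) {
    a <- c(m$x0[seg], m$y0[seg], m$z0[seg])
    b <- c(m$x1[seg], m$y1[seg], m$z1[seg])
    pts <- sapply(1:3, function(d) a[d] + (b[d] - a[d]) * ((1:200) - 0.5) / 200)
    for (i in c(1, 8, 16)) {
      r <- sqrt(colSums((t(pts) - e$pos[i, ])^2))
      if (min(r) < geo$len[seg]) next   # oracle valid beyond a segment length
      vq <- mean(1e3 / (4 * pi * e$sigma * r))
      expect_lt(abs(M[i, seg] - vq) / abs(vq), 0.01)
    }
  }

  # linearity: scaling all currents scales potentials
  ev <- list(synaptic_event(40, 0.2, 2, 0))
  sol <- solve_passive(m, passive_params(), ev, dt = 2^-4, T = 20)
  lfp <- lfp_line_source(sol, m, e)
  sol2 <- sol; sol2$I <- 3 * sol2$I
  lfp2 <- lfp_line_source(sol2, m, e)
  expect_equal(lfp2$traces, 3 * lfp$traces, tolerance = 1e-12)
  expect_error(electrode_array(sigma = -1), "sigma")
})

test_that("current dipole obeys two-monopole, translation and far-field laws", {
  # +I at origin, -I at (0,0,d): p = (0, 0, -I d)
  mono <- structure(list(I = matrix(c(2, -2), 2, 1), dt = 1, t = 0),
                    class = "membrane_currents")
  md <- data.frame(id = 1:2, label = c("basal", "basal"),
                   x0 = 0, y0 = 0, z0 = c(-0.5, 99.5),
                   x1 = 0, y1 = 0, z1 = c(0.5, 100.5),
                   diam = 1, parent = c(0L, 1L))
  class(md) <- c("morphology", "data.frame")
  dp <- current_dipole(mono, md)
  expect_equal(as.numeric(dp$p), c(0, 0, -2 * 100), tolerance = 1e-12)

  m <- place_morphology(fixture_morphology(), soma_z = -1270)
  sol <- solve_passive(m, passive_params(),
                       list(synaptic_event(125, 0.3, 2, 0)), dt = 2^-4, T = 20)
  dp1 <- current_dipole(sol, m)
  m2 <- m; m2$x0 <- m2$x0 + 500; m2$x1 <- m2$x1 + 500
  m2$z0 <- m2$z0 + 500; m2$z1 <- m2$z1 + 500
  dp2 <- current_dipole(sol, m2)
  expect_lt(max(abs(dp1$p - dp2$p)), 1e-9 * max(abs(dp1$p)))

  # nonzero net current triggers the origin-dependence warning
  bad <- sol; bad$I[1, ] <- bad$I[1, ] + 0.1 * max(abs(bad$I))
  expect_warning(current_dipole(bad, m), "origin")

  # far-field LFP decays as the dipole prediction along the axis
  sigma <- 0.3
  tpk <- which.max(abs(dp1$p[3, ]))
  ctr <- colMeans(popkernel:::.segment_geometry(m)$mid)
  for (rr in c(15000, 30000)) {
    epos <- ctr + c(0, 0, rr)
    ef <- electrode_array(z = epos[3], x = epos[1], y = epos[2],
                          sigma = sigma)
    v_full <- lfp_line_source(sol, m, ef)$traces[1, tpk]
    rel <- epos - ctr
    v_dip <- 1e3 * sum(dp1$p[, tpk] * rel) / (4 * pi * sigma * rr^3)
    expect_lt(abs(v_full - v_dip) / abs(v_dip), 0.05)
  }
})

test_that("four-sphere series matches the homogeneous-sphere oracle", {
  # equal conductivities + central dipole has a closed form:
  # 3 p cos(theta) / (4 pi sigma R^2) at the outer surface
  hd <- four_sphere_params(sigma = c(0.3, 0.3, 0.3, 0.3))
  tf <- popkernel:::.four_sphere_transfer(1e-5, hd)
  expect_equal(tf, 3 / (4 * pi * 0.3 * 0.09^2), tolerance = 1e-6)

  # self-convergence: doubling the maximum order leaves the value unchanged
  hd2 <- four_sphere_params()
  t1 <- popkernel:::.four_sphere_transfer(77.7, hd2, n_max = 300, tol = 1e-9)
  t2 <- popkernel:::.four_sphere_transfer(77.7, hd2, n_max = 600, tol = 1e-13)
  expect_lt(abs(t1 / t2 - 1), 1e-3)

  dip <- structure(list(p = matrix(c(0, 0, 5, 0, 0, 10), 3, 2), dt = 1),
                   class = "dipole_trace")
  v <- eeg_four_sphere(dip, location = -1270)
  expect_equal(v[2], 2 * v[1], tolerance = 1e-12)  # linear in the moment
  expect_error(eeg_four_sphere(dip, location = 5000), "inside the brain")
  expect_error(four_sphere_params(radii = c(90, 85, 80, 79)), "increasing")
})
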