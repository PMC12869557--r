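test_that("duct series solution reaches the parallel-plate limit and vanishes at zero pressure", {
  # wide duct: max velocity -> h^2 dp / (8 eta L)
  d <- rectangular_duct_flow(width = 1000, depth = 10, length_mm = 11.7,
                             dp = 690)
  u_plate <- (10e-6)^2 * 690 / (8 * 0.0010016 * 11.7e-3) * 1e6
  expect_equal(d$u_max, u_plate, tolerance = 1e-3)
  expect_equal(round(u_plate), 736)
  d0 <- rectangular_duct_flow(200, 10, 11.7, dp = 0)
  expect_true(all(d0$u == 0))
  expect_error(rectangular_duct_flow(-1, 10, 1, 100), "positive")
})

test_that("duct series matches a finite-difference Poisson oracle within 0.1%", {
  eta <- 0.0010016
  series <- rectangular_duct_flow(10, 10, 1, 1000, fl = fluid(997, eta),
                                  n_terms = 301, ny = 81, nz = 81)
  fd <- fd_duct_max_velocity(10, 10, 1, 1000, eta, nn = 81)
  expect_equal(series$u_max, fd, tolerance = 1e-3)
})

test_that("duct solution satisfies no-slip, flux consistency and width/depth symmetry", {
  d <- rectangular_duct_flow(30, 10, 2, 500, ny = 81, nz = 81)
  expect_true(all(abs(d$u[1, ]) < 1e-8 * d$u_max))   # side walls
  expect_true(all(abs(d$u[, 1]) < 1e-8 * d$u_max))   # bottom wall
  expect_true(all(abs(d$u[, 81]) < 1e-8 * d$u_max))  # top wall
  expect_gte(d$u_max, d$u_mean)
  # cross-section integral of the velocity field reproduces Q
  hy <- diff(d$y_um)[1]; hz <- diff(d$z_um)[1]
  wy <- rep(1, 81); wy[c(1, 81)] <- 0.5
  Q_trapz <- sum(outer(wy, wy) * d$u) * hy * hz
  expect_equal(Q_trapz, d$Q, tolerance = 2e-3)
  expect_equal(duct_flow_rate(20, 10, 1, 100, n_terms = 400),
               duct_flow_rate(10, 20, 1, 100, n_terms = 400),
               tolerance = 1e-8)
})

test_that("tapered-network flow is linear in pressure, converged in segments, and consistent with a uniform duct", {
  p <- channel_profile()
  n1 <- network_flow(p, 690)
  n2 <- network_flow(p, 1380)
  expect_equal(n2$Q, 2 * n1$Q, tolerance = 1e-12)
  r50 <- network_flow(p, 690, n_segments = 50)$R_total
  r500 <- network_flow(p, 690, n_segments = 500)$R_total
  expect_lt(abs(r500 - r50) / r500, 0.005)
  # disabled taper: network resistance equals the single-duct resistance
  pu <- channel_profile(inner_width_r0 = 100, inner_width_rmax = 100)
  expect_equal(network_flow(pu, 690)$R_total,
               duct_resistance(100, 10, 11.7), tolerance = 1e-9)
})

test_that("Reynolds and Peclet numbers combine units correctly and scale linearly", {
  dh <- hydraulic_diameter(200, 10)
  expect_equal(dh, 2 * 200 * 10 / 210)
  expect_equal(reynolds_number(100, dh), 997 * 100e-6 * dh * 1e-6 / 0.0010016)
  expect_equal(reynolds_number(100, dh), 1.90e-3, tolerance = 0.005)
  expect_equal(reynolds_number(0, dh), 0)
  expect_equal(peclet_number(1, 100, 100), 1)
  set.seed(3)
  u <- runif(10, 0, 500)
  expect_equal(reynolds_number(2 * u[1], dh), 2 * reynolds_number(u[1], dh))
  expect_equal(peclet_number(u, 10, 450), u * 10 / 450)
  expect_equal(peclet_number(1, 100, 200), peclet_number(1, 100, 100) / 2)
})

test_that("radial Darcy flow conserves volume flux across shells and is zero without pressure", {
  dom <- spheroid_domain()
  mats <- default_materials()
  f0 <- darcy_radial_flow(dom, mats$organoid, mats$membrane, dp = 0)
  expect_true(all(f0$u_um_s == 0))
  f <- darcy_radial_flow(dom, mats$organoid, mats$membrane, dp = 690)
  # continuity: r^2 u(r) constant in the source-free region
  r2u <- f$r_um^2 * f$u_um_s
  expect_lt(max(abs(r2u - r2u[1])) / r2u[1], 1e-6)
  expect_equal(f$u_max, f$u_um_s[1])
  expect_equal(f$r_at_max, dom$r_source_um)
  # linear in the applied pressure
  f2 <- darcy_radial_flow(dom, mats$organoid, mats$membrane, dp = 1380)
  expect_equal(f2$Q, 2 * f$Q, tolerance = 1e-12)
})
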