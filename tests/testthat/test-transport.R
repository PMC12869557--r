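ag <- porous_material("agarose", 0.99, 8.2e-16)
srb <- solute("srb", 470, 10)

test_that("half-space limit reproduces the erfc solution within 1% RMS", {
  g <- build_phantom_grid(phantom_domain(membrane = NULL), dx_max = 10)
  cfg <- transport_config(g, list(agarose = ag), srb,
                          bc_left = list(type = "dirichlet", value = 10),
                          bc_right = list(type = "dirichlet", value = 0),
                          times = c(0, 500, 1000, 2000),
                          rtol = 1e-9, track_fluxes = FALSE)
  res <- solve_transport(cfg)
  for (t in c(500, 1000, 2000)) {
    num <- profile_at(res, res$x, t)[1, ]
    ana <- halfspace_profile(res$x, t, 10, 470)  # apparent D = eps*D/eps
    expect_lt(sqrt(mean((num - ana)^2)) / 10, 0.01)
  }
})

test_that("zero source concentration yields an identically zero field", {
  res <- solve_phantom(sol = solute("srb", 470, 0),
                       times = seq(0, 4000, 2000))
  expect_true(all(abs(res$conc) < 1e-12))
})

test_that("long-time slab with fixed ends settles to the linear steady profile within 0.5%", {
  g <- build_phantom_grid(phantom_domain(membrane = NULL), dx_max = 50)
  cfg <- transport_config(g, list(agarose = ag), srb,
                          bc_left = list(type = "dirichlet", value = 10),
                          bc_right = list(type = "dirichlet", value = 0),
                          times = c(0, 2e5), track_fluxes = FALSE)
  res <- solve_transport(cfg)
  num <- res$conc[2, ]
  ana <- 10 * (1 - res$x / 5000)
  expect_lt(max(abs(num - ana)) / 10, 0.005)
})

test_that("porosity-weighted mass balance closes to 1e-8 of delivered mass on every tracked solve", {
  # membrane + agarose phantom
  r1 <- solve_phantom(times = seq(0, 24000, 4800))
  expect_lt(max(abs(r1$mass_residual)), 1e-8)
  # spherical organoid with a clamped source shell
  r2 <- solve_organoid_radial(times = c(0, 1800, 3600))
  expect_lt(max(abs(r2$mass_residual)), 1e-8)
  # organoid with Darcy advection coupled in
  mats <- default_materials()
  adv <- darcy_radial_flow(spheroid_domain(), mats$organoid, mats$membrane, 690)
  r3 <- solve_organoid_radial(times = c(0, 1800, 3600), advection = adv)
  expect_lt(max(abs(r3$mass_residual)), 1e-8)
})

test_that("discrete maximum principle: concentrations stay within [0, source]", {
  r1 <- solve_phantom(times = seq(0, 24000, 2400))
  expect_gte(min(r1$conc), -1e-8 * 10)
  expect_lte(max(r1$conc), 10 * (1 + 1e-8))
  r2 <- solve_organoid_radial(times = c(0, 900, 3600))
  expect_gte(min(r2$conc), -1e-8 * 5600)
  expect_lte(max(r2$conc), 5600 * (1 + 1e-8))
})

test_that("spatial convergence on the erfc benchmark is at least second order", {
  err <- vapply(c(40, 20, 10), function(dx) {
    g <- build_phantom_grid(phantom_domain(membrane = NULL), dx_max = dx)
    cfg <- transport_config(g, list(agarose = ag), srb,
                            bc_left = list(type = "dirichlet", value = 10),
                            bc_right = list(type = "dirichlet", value = 0),
                            times = c(0, 1000), rtol = 1e-10,
                            atol = 1e-13, track_fluxes = FALSE)
    res <- solve_transport(cfg)
    ana <- halfspace_profile(res$x, 1000, 10, 470)
    sqrt(mean((res$conc[2, ] - ana)^2))
  }, numeric(1))
  order <- log2(err[-3] / err[-1])
  expect_gte(min(order), 1.9)
})

test_that("implicit BDF integration agrees with an explicit RK4 brute force on a 50-cell instance", {
  # uniform 50-cell slab of membrane material with the time-dependent
  # saturation law, so the stiff path and the brute force see identical
  # spatial operators but independent time integration
  g <- uniform_membrane_slab(length_mm = 5, dx = 100)
  pete_like <- porous_material("membrane", 0.99, 1.2e-16)
  satm <- saturation_model(s0 = 0.075, ks = 3.7e-5)
  cfg <- transport_config(g, list(membrane = pete_like), srb,
                          saturation = satm,
                          bc_left = list(type = "dirichlet", value = 10),
                          bc_right = list(type = "dirichlet", value = 0),
                          times = c(0, 2000), rtol = 1e-11, atol = 1e-13,
                          track_fluxes = FALSE)
  expect_equal(cfg$grid$n, 50)
  res <- solve_transport(cfg)
  Dfun <- function(t) rep(saturation_at(satm, t) * 0.99 * 470, 50)
  ref <- explicit_rk4_reference(g$faces, rep(0.99, 50), Dfun,
                                cb_left = 10, cb_right = 0,
                                t_end = 2000, dt = 0.25)
  expect_lt(max(abs(res$conc[2, ] - ref$c)) / max(ref$c), 1e-6)
})

test_that("closed sphere with uniform initial concentration stays in equilibrium", {
  dom <- spheroid_domain(outer_bc = "closed")
  g <- build_spheroid_radial_grid(dom, dr = 20)
  mats <- default_materials()
  cfg <- transport_config(g, list(organoid = mats$organoid),
                          solute("magnevist", 450, 5600),
                          bc_left = list(type = "closed"),
                          bc_right = list(type = "closed"),
                          init = 7, times = c(0, 5000), track_fluxes = FALSE)
  res <- solve_transport(cfg)
  expect_lt(max(abs(res$conc[2, ] - 7)), 1e-6 * 7)
})

test_that("organoid delivery peaks inside the source shell and matches the steady 1/r oracle", {
  dom <- spheroid_domain()
  res <- solve_organoid_radial(times = c(0, 3600), dr = 5)
  prof <- res$conc[2, ]
  rs <- dom$r_source_um
  inner <- prof[res$x < rs]
  # interior concentration >= exterior at equal distance from the shell
  d_in <- rs - res$x[res$x < rs]
  d_out <- res$x[res$x > rs] - rs
  for (d in c(50, 100, 200)) {
    ci <- approx(d_in[order(d_in)], inner[order(d_in)], d)$y
    co <- approx(d_out, prof[res$x > rs], d)$y
    expect_gte(ci, co)
  }
  # steady two-region solution: interior uniform at c_m, 1/r decay outside
  res_ss <- solve_organoid_radial(times = c(0, 5e5), dr = 5,
                                  track_fluxes = FALSE)
  r_anchor <- res_ss$x[attr(res_ss$grid, "source_cell")]
  ana <- spherical_steady_profile(res_ss$x, r_anchor,
                                  max(res_ss$grid$faces), 5600)
  expect_lt(max(abs(res_ss$conc[2, ] - ana)) / 5600, 0.005)
})

test_that("slower solutes lag: the iohexol front trails the contrast-agent front at equal times", {
  mats <- default_materials()
  # early times, before either front feels the outer sink (the steady
  # profile is diffusivity-independent, so late-time depths coincide)
  run <- function(sol) {
    solve_agarose_3d_embedding(sol = sol, times = c(0, 60, 120),
                               dr = 10, track_fluxes = FALSE)
  }
  io <- run(solute("iohexol", 250, 1000))
  mg <- run(solute("magnevist", 450, 1000))
  for (i in 2:3) {
    d_io <- penetration_depth_at(io, io$times[i])
    d_mg <- penetration_depth_at(mg, mg$times[i])
    expect_lt(d_io, d_mg)
  }
  # t = 0 returns the initial condition unchanged
  expect_true(all(io$conc[1, -attr(io$grid, "source_cell")] == 0))
  expect_equal(io$conc[1, attr(io$grid, "source_cell")], 1000)
})

test_that("advection input is validated and strong advection triggers the cell-Peclet guard", {
  mats <- default_materials()
  adv <- darcy_radial_flow(spheroid_domain(), mats$organoid, mats$membrane, 690)
  small <- spheroid_domain(r0_mm = 0.5, r0z_mm = 0.5, r_source_um = 200)
  g_small <- build_spheroid_radial_grid(small, dr = 10)
  expect_error(
    transport_config(g_small, list(organoid = mats$organoid),
                     solute("m", 450, 100),
                     advection = rep(1, 5), times = c(0, 10)),
    "mismatch")
  big <- darcy_radial_flow(spheroid_domain(), mats$organoid, mats$membrane,
                           dp = 50 * 690)
  expect_warning(
    solve_organoid_radial(times = c(0, 10), advection = big,
                          track_fluxes = FALSE),
    "Peclet")
})
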