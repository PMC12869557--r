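ag <- porous_material("agarose", 0.99, 8.2e-16)
srb <- solute("srb", 470, 10)

slab_result <- function(D = 470, times = seq(0, 6e4, 1200), init = 0) {
  g <- build_phantom_grid(phantom_domain(membrane = NULL), dx_max = 50)
  cfg <- transport_config(g, list(agarose = ag), solute("dye", D, 10),
                          bc_left = list(type = "dirichlet", value = 10),
                          bc_right = list(type = "dirichlet", value = 0),
                          init = init, times = times, track_fluxes = FALSE)
  solve_transport(cfg)
}

test_that("steady-state time matches the slab eigenfunction-expansion oracle within one output interval", {
  res <- slab_result()
  ss <- steady_state_time(res, rel_tol = 0.05)
  # oracle: evaluate the Fourier-series transient on a fine grid
  xf <- seq(0, 5000, 5)
  D_app <- 470  # eps*D/eps
  dev <- vapply(res$times[-1], function(t) {
    max(abs(slab_series_profile(xf, t, 10, D_app, 5000) - 10 * (1 - xf / 5000))) / 10
  }, numeric(1))
  t_oracle <- res$times[-1][which(dev <= 0.05)[1]]
  expect_lte(abs(ss$time_s - t_oracle), diff(res$times)[1])
  expect_true(ss$converged)
})

test_that("steady-state time is zero when the initial condition is already steady, and decreases with D", {
  g <- build_phantom_grid(phantom_domain(membrane = NULL), dx_max = 50)
  centers <- g$centers
  res0 <- slab_result(times = seq(0, 5000, 1000), init = 10 * (1 - centers / 5000))
  expect_equal(steady_state_time(res0)$time_s, 0)
  t_fast <- steady_state_time(slab_result(D = 940))$time_s
  t_slow <- steady_state_time(slab_result(D = 470))$time_s
  expect_lt(t_fast, t_slow)
})

test_that("steady slab interface flux matches the analytic D_eff * c0 / L to 0.5%", {
  # homogeneous 5 mm slab (membrane layer given agarose properties, fully
  # saturated) so the analytic J = 465.3 * 10 / 5000 = 0.9306 uM.um/s applies
  res <- solve_phantom(sol = srb,
                       saturation = saturation_model(s0 = 1, ks = 0),
                       materials = list(membrane = ag, agarose = ag),
                       domain = phantom_domain(length_mm = 4.99),
                       times = c(0, 60, 240, 900, 3000,
                                 seq(6e3, 2.4e5, 6e3)))
  fx <- interface_flux(res)
  expect_equal(fx$steady_value, 0.9306, tolerance = 0.005)
  # average lies within the series range; conventions are all reported
  expect_gte(fx$average_to_steady, min(fx$flux))
  expect_lte(fx$average_to_steady, max(fx$flux))
  expect_type(fx$whole_run_average, "double")
})

test_that("interface flux is zero without a concentration difference and errors without an interface", {
  res0 <- solve_phantom(sol = solute("srb", 470, 0), times = seq(0, 9000, 3000))
  fx0 <- interface_flux(res0)
  expect_lt(abs(fx0$steady_value), 1e-12)
  slab <- slab_result(times = seq(0, 3000, 1000))
  expect_error(interface_flux(slab), "no membrane interface")
  res <- solve_phantom(times = seq(0, 24000, 4800))
  expect_error(interface_flux(res, window = c(0, 1e6)), "window")
})

test_that("penetration depth inverts the erfc profile and handles degenerate inputs", {
  x <- seq(0, 3000, 10)
  Dt <- 470 * 1000
  prof <- 10 * (2 * pnorm(-x / (2 * sqrt(Dt)) * sqrt(2)))
  depth <- penetration_depth(x, prof, threshold = 0.1)
  depth_ana <- 2 * sqrt(Dt) * erfcinv_(0.1)
  expect_lt(abs(depth - depth_ana), 10)  # within one sample spacing
  expect_equal(penetration_depth(x, rep(0, length(x))), 0)
  expect_warning(d0 <- penetration_depth(c(0, 1), c(0, 0.1), threshold = 0.5),
                 "below threshold")
  expect_equal(d0, 0)
})

test_that("penetration depth grows like sqrt(t) in the pure-diffusion phantom", {
  res <- slab_result(times = c(0, seq(200, 2000, 200)))
  t <- res$times[-1]
  depth <- vapply(t, function(tt) penetration_depth_at(res, tt), numeric(1))
  expect_true(all(diff(depth) > 0))       # front advances monotonically
  fit <- lm(I(depth^2) ~ t)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("profile normalisation divides by the reference and round-trips", {
  expect_equal(normalize_profile(c(5600, 2800, 0), 5600), c(1, 0.5, 0))
  expect_equal(normalize_profile(rep(7, 4), 7), rep(1, 4))
  p <- runif(10)
  expect_equal(normalize_profile(p, 2.5) * 2.5, p)
  expect_error(normalize_profile(1:3, 0), "positive")
})
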