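truth <- c(s0 = 0.075, ks = 3.7e-5)

test_that("noiseless self-consistency: the fit recovers the generating parameters within 1%", {
  synth <- generate_phantom_profiles(s0 = truth["s0"], ks = truth["ks"],
                                     noise = c(0, 0), seed = 1)
  fit <- fit_saturation(synth$data)
  rel <- abs(coef(fit) - truth) / truth
  expect_lt(rel[["s0"]], 0.01)
  expect_lt(rel[["ks"]], 0.01)
  # residuals at the optimum are at solver-tolerance level
  expect_lt(sqrt(fit$loss / nrow(synth$data)), 1e-4)
})

test_that("degenerate rate: data generated with ks = 0 yields a near-zero ks estimate and recovers s0", {
  synth <- generate_phantom_profiles(s0 = 0.2, ks = 0, noise = c(0, 0), seed = 2)
  fit <- fit_saturation(synth$data, start = c(s0 = 0.1, ks = 1e-5))
  expect_lt(abs(coef(fit)[["s0"]] - 0.2) / 0.2, 0.01)
  expect_lt(coef(fit)[["ks"]], 1e-7)  # below any meaningful rate
})

test_that("residual interface: zero at truth, consistent with the reported loss, and of the right length", {
  synth <- generate_phantom_profiles(noise = c(0, 0), seed = 3,
                                     times = seq(0, 24000, 4800),
                                     x = seq(0, 5000, 250))
  r <- profile_residuals(truth, synth$data)
  expect_length(r, length(seq(0, 24000, 4800)) * length(seq(0, 5000, 250)))
  expect_lt(max(abs(r)), 1e-3)  # solver-tolerance level, not exact zeros
  fit <- fit_saturation(synth$data)
  r_at_fit <- profile_residuals(coef(fit), synth$data)
  expect_equal(sum(r_at_fit^2), fit$loss, tolerance = 1e-6)
  expect_error(profile_residuals(c(s0 = 2, ks = 0), synth$data), "bounds")
})

test_that("estimates converge to truth as the noise level decreases", {
  sd_rel <- c(0, 0.005, 0.01, 0.05)
  bound <- c(0.005, 0.05, 0.1, 0.5)
  for (i in seq_along(sd_rel)) {
    synth <- generate_phantom_profiles(noise = c(sd_rel[i], sd_rel[i] / 2),
                                       seed = 100 + i)
    fit <- fit_saturation(synth$data)
    rel <- abs(coef(fit) - truth) / truth
    expect_lt(max(rel), bound[i])
  }
})

test_that("the fit is invariant to uniform rescaling of the concentrations", {
  synth <- generate_phantom_profiles(noise = c(0.01, 0.005), seed = 11)
  fit1 <- fit_saturation(synth$data)
  scaled <- synth$data
  scaled$value <- scaled$value * 37
  sol_scaled <- solute("srb", 470, 10 * 37)
  fit2 <- fit_saturation(scaled, sol = sol_scaled)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-4)
})

test_that("multistart from seeded initial points agrees on the optimum", {
  synth <- generate_phantom_profiles(noise = c(0.01, 0.005), seed = 21,
                                     times = seq(0, 24000, 4800),
                                     x = seq(0, 5000, 200))
  fit <- fit_saturation(synth$data, multistart = 4, seed = 99)
  best <- min(fit$multistart_deviances)
  expect_true(all(fit$multistart_deviances / best - 1 < 1e-3))
  rel <- abs(coef(fit) - truth) / truth
  expect_lt(max(rel), 0.1)
})

test_that("standard errors from the residual Jacobian cover the truth at reasonable scale", {
  synth <- generate_phantom_profiles(noise = c(0.01, 0.005), seed = 31)
  fit <- fit_saturation(synth$data)
  se <- sqrt(diag(vcov(fit)))
  expect_true(all(is.finite(se)))
  # truth within 4 standard errors (loose sanity bound, not a coverage test)
  expect_lt(abs(coef(fit)[["s0"]] - truth[["s0"]]), 4 * se[["s0"]] + 0.01)
  expect_lt(abs(coef(fit)[["ks"]] - truth[["ks"]]), 4 * se[["ks"]] + 1e-6)
  s <- summary(fit)
  expect_s3_class(s, "summary.saturation_fit")
  expect_false(s$convergence$singular_jacobian)
})

test_that("predict, fitted and residuals methods are mutually consistent", {
  synth <- generate_phantom_profiles(noise = c(0.005, 0), seed = 41,
                                     times = seq(0, 24000, 8000),
                                     x = seq(0, 5000, 500))
  fit <- fit_saturation(synth$data)
  expect_equal(fitted(fit) + residuals(fit), synth$data$value)
  pr <- predict(fit)
  expect_named(pr, c("time", "x", "value"))
  idx <- match(paste(synth$data$time, synth$data$x),
               paste(pr$time, pr$x))
  expect_equal(pr$value[idx], unname(fitted(fit)), tolerance = 1e-8)
})
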