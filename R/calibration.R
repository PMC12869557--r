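# Calibration of the membrane saturation law (s0, ks), optionally with the
# free diffusivity, against concentration-profile time series, by bounded
# Levenberg-Marquardt least squares with the phantom PDE as forward model.

.fit_scales <- function(fit_D) {
  s <- c(s0 = 1, ks = 1e-4)   # bring ks to order one for the optimizer
  if (fit_D) s <- c(s, D = 100)
  s
}

.forward_predict <- function(par, observations, sol, saturation_ignored,
                             materials, domain, dx_max, membrane_cells,
                             rtol) {
  satm <- saturation_model(s0 = par[["s0"]], ks = par[["ks"]])
  sl <- if ("D" %in% names(par))
    solute(sol$name, diffusivity = par[["D"]], c_source = sol$c_source)
  else sol
  times <- sort(unique(c(0, observations$time)))
  res <- solve_phantom(sol = sl, saturation = satm, materials = materials,
                       domain = domain, times = times, dx_max = dx_max,
                       membrane_cells = membrane_cells,
                       rtol = rtol, track_fluxes = FALSE)
  # simulated value at each observed (time, x)
  pred <- numeric(nrow(observations))
  for (tt in unique(observations$time)) {
    sel <- observations$time == tt
    pred[sel] <- profile_at(res, observations$x[sel], tt)[1, ]
  }
  pred
}

#' Residuals of the phantom forward model at given parameters
#'
#' Observed minus simulated concentration at each observed (time, position)
#' pair; observation positions are interpolated linearly on the solver
#' grid.
#'
#' @param par named vector with `s0`, `ks` and optionally `D` (um^2/s).
#' @param observations data.frame with columns `time` (s), `x` (um) and
#'   `value` (uM).
#' @param sol the [solute()] being delivered (its source concentration
#'   fixes the channel boundary).
#' @param materials named list with `membrane` and `agarose` entries.
#' @param domain a [phantom_domain()].
#' @param dx_max,membrane_cells,rtol forward-model resolution and solver
#'   tolerance.
#' @return numeric residual vector of length `nrow(observations)`.
#' @export
profile_residuals <- function(par, observations,
                              sol = default_solutes()$srb,
                              materials = default_materials(),
                              domain = phantom_domain(),
                              dx_max = 50, membrane_cells = 5,
                              rtol = 1e-7) {
  stopifnot(all(c("time", "x", "value") %in% names(observations)))
  if (par[["s0"]] < 0 || par[["s0"]] > 1 || par[["ks"]] < 0)
    stop("parameters out of bounds", call. = FALSE)
  pred <- .forward_predict(par, observations, sol, NULL, materials, domain,
                           dx_max, membrane_cells, rtol)
  observations$value - pred
}

#' Fit the membrane saturation law to concentration profiles
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with the transient
#' phantom diffusion solve as forward model. The free parameters are the
#' initial saturation `s0` in [0, 1] and the saturation rate `ks >= 0`
#' (1/s), optionally also the solute's free diffusivity `D`. Parameters are
#' rescaled internally to order one for conditioning. Approximate standard
#' errors come from the residual Jacobian at the optimum; a near-singular
#' Jacobian (non-identifiable regime, e.g. observations that do not span
#' the transient) is reported in the summary rather than failing.
#'
#' @param observations data.frame with columns `time` (s), `x` (um) and
#'   `value` (uM); at least two distinct observation times spanning the
#'   transient are required for `ks` to be identifiable.
#' @param start named starting values (`s0`, `ks`, and `D` when `fit_D`);
#'   default `s0 = 0.1`, `ks = 1e-5`.
#' @param fit_D also fit the free diffusivity.
#' @param lower,upper named bounds; defaults `s0` in [0, 1], `ks` in
#'   [0, 0.01], `D` in [10, 5000].
#' @param sol,materials,domain,dx_max,membrane_cells,rtol forward model, as
#'   in [profile_residuals()].
#' @param multistart number of seeded starting points (> 1 guards against
#'   local minima; all starts are reported in the trace).
#' @param seed integer seed for the multistart draws.
#' @param control a [minpack.lm::nls.lm.control()] list.
#' @return an object of class `saturation_fit`, with methods `print`,
#'   `summary`, `coef`, `vcov`, `predict`, `fitted`, `residuals`, `plot`
#'   and `simulate`.
#' @examples
#' \donttest{
#' synth <- generate_phantom_profiles(noise = c(0.01, 0.005), seed = 1)
#' fit <- fit_saturation(synth$data)
#' summary(fit)
#' }
#' @export
fit_saturation <- function(observations,
                           start = c(s0 = 0.1, ks = 1e-5),
                           fit_D = FALSE,
                           lower = NULL, upper = NULL,
                           sol = default_solutes()$srb,
                           materials = default_materials(),
                           domain = phantom_domain(),
                           dx_max = 50, membrane_cells = 5, rtol = 1e-7,
                           multistart = 1, seed = 1,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-10, ptol = 1e-8, maxiter = 100,
                             epsfcn = 1e-6)) {
  stopifnot(all(c("time", "x", "value") %in% names(observations)))
  if (length(unique(observations$time[observations$time > 0])) < 2)
    stop("need >= 2 observation times spanning the transient", call. = FALSE)
  p_names <- c("s0", "ks", if (fit_D) "D")
  lo <- c(s0 = 0, ks = 0, D = 10)[p_names]
  hi <- c(s0 = 1, ks = 0.01, D = 5000)[p_names]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (fit_D && !("D" %in% names(start))) start <- c(start, D = sol$diffusivity)
  start <- start[p_names]
  if (any(start < lo | start > hi))
    stop("start outside bounds", call. = FALSE)
  sc <- .fit_scales(fit_D)
  n_fail <- 0L
  resid_scaled <- function(ps) {
    par <- ps * sc
    names(par) <- p_names
    out <- tryCatch(
      profile_residuals(par, observations, sol = sol, materials = materials,
                        domain = domain, dx_max = dx_max,
                        membrane_cells = membrane_cells, rtol = rtol),
      error = function(e) {
        n_fail <<- n_fail + 1L
        rep(1e6 * (1 + sum(abs(ps))), nrow(observations))
      })
    out
  }
  starts <- list(start / sc)
  if (multistart > 1) {
    set.seed(seed)
    # draw starts inside the physically plausible regime: an initial
    # saturation below one half and rates for which the membrane still
    # wets over the observation window (outside it the residual surface
    # is flat in both parameters and any optimizer stalls)
    hi_draw <- pmin(hi, c(s0 = 0.5, ks = 1e-4, D = 2000)[p_names])
    for (i in seq_len(multistart - 1)) {
      s <- lo + stats::runif(length(lo)) * (hi_draw - lo)
      names(s) <- p_names
      starts[[i + 1]] <- s / sc
    }
  }
  fits <- lapply(starts, function(s0v) {
    minpack.lm::nls.lm(par = s0v, lower = lo / sc, upper = hi / sc,
                       fn = resid_scaled, control = control)
  })
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  fit <- fits[[which.min(dev)]]
  est <- fit$par * sc
  names(est) <- p_names
  n <- nrow(observations)
  p <- length(est)
  sigma2 <- fit$deviance / max(n - p, 1)
  vc <- matrix(NA_real_, p, p, dimnames = list(p_names, p_names))
  singular <- FALSE
  vc_s <- tryCatch(solve(fit$hessian), error = function(e) NULL)
  if (is.null(vc_s) || any(!is.finite(vc_s))) {
    singular <- TRUE
  } else {
    vc <- sigma2 * (vc_s * outer(sc, sc))
    dimnames(vc) <- list(p_names, p_names)
    if (any(diag(vc) < 0)) singular <- TRUE
  }
  res_final <- resid_scaled(fit$par)
  structure(
    list(coefficients = est, vcov = vc, sigma = sqrt(sigma2),
         loss = fit$deviance, df = n - p,
         convergence = list(info = fit$info, message = fit$message,
                            niter = fit$niter, forward_failures = n_fail,
                            singular_jacobian = singular),
         trace = fit$rsstrace,
         multistart_deviances = dev,
         start = start, lower = lo, upper = hi,
         observations = observations,
         fitted = observations$value - res_final,
         residuals = res_final,
         forward = list(sol = sol, materials = materials, domain = domain,
                        dx_max = dx_max, membrane_cells = membrane_cells,
                        rtol = rtol),
         call = match.call()),
    class = "saturation_fit"
  )
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("Membrane saturation fit (Levenberg-Marquardt, phantom forward model)\n")
  cat("  coefficients:\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("  residual sum of squares: %.6g on %d degrees of freedom\n",
              x$loss, x$df))
  cat(sprintf("  %s (%d iterations)\n", x$convergence$message,
              x$convergence$niter))
  invisible(x)
}

#' @export
coef.saturation_fit <- function(object, ...) object$coefficients

#' @export
vcov.saturation_fit <- function(object, ...) object$vcov

#' @export
fitted.saturation_fit <- function(object, ...) object$fitted

#' @export
residuals.saturation_fit <- function(object, ...) object$residuals

#' @export
summary.saturation_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  out <- list(coefficients = tab, sigma = object$sigma, loss = object$loss,
              df = object$df, convergence = object$convergence)
  class(out) <- "summary.saturation_fit"
  out
}

#' @export
print.summary.saturation_fit <- function(x, ...) {
  cat("Membrane saturation fit\n\nCoefficients:\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("\nResidual standard error: %.4g on %d degrees of freedom\n",
              x$sigma, x$df))
  if (x$convergence$singular_jacobian)
    cat("Warning: near-singular Jacobian; parameters weakly identified\n")
  if (x$convergence$forward_failures > 0)
    cat(sprintf("Note: %d forward-model failures were penalised during fitting\n",
                x$convergence$forward_failures))
  invisible(x)
}

#' Predict concentration profiles from a saturation fit
#'
#' Runs the forward model at the fitted parameters.
#'
#' @param object a `saturation_fit`.
#' @param times output times, s; default the observed times.
#' @param x positions, um; default the observed positions.
#' @param ... unused.
#' @return data.frame of `time`, `x`, `value`.
#' @export
predict.saturation_fit <- function(object, times = NULL, x = NULL, ...) {
  if (is.null(times)) times <- sort(unique(object$observations$time))
  if (is.null(x)) x <- sort(unique(object$observations$x))
  newobs <- expand.grid(x = x, time = times)[, c("time", "x")]
  newobs$value <- 0
  pred <- .forward_predict(object$coefficients, newobs, object$forward$sol,
                           NULL, object$forward$materials,
                           object$forward$domain, object$forward$dx_max,
                           object$forward$membrane_cells,
                           object$forward$rtol)
  data.frame(time = newobs$time, x = newobs$x, value = pred)
}

#' @export
plot.saturation_fit <- function(x, ...) {
  obs <- x$observations
  times <- sort(unique(obs$time))
  pal <- grDevices::hcl.colors(length(times), "viridis")
  graphics::plot(range(obs$x), range(c(obs$value, x$fitted)), type = "n",
                 xlab = "position (um)", ylab = "concentration (uM)", ...)
  for (i in seq_along(times)) {
    sel <- obs$time == times[i]
    o <- order(obs$x[sel])
    graphics::points(obs$x[sel][o], obs$value[sel][o], col = pal[i], pch = 1,
                     cex = 0.5)
    graphics::lines(obs$x[sel][o], x$fitted[sel][o], col = pal[i])
  }
  invisible(x)
}

#' Simulate synthetic datasets from a saturation fit
#'
#' Draws seeded noisy replicates of the phantom profiles at the fitted
#' parameters, using the same noise model as
#' [generate_phantom_profiles()].
#'
#' @param object a `saturation_fit`.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param noise `c(multiplicative, additive)` noise fractions.
#' @param ... unused.
#' @return list of `synthetic_profiles` objects.
#' @export
simulate.saturation_fit <- function(object, nsim = 1, seed = 1,
                                    noise = c(0.01, 0.005), ...) {
  cf <- object$coefficients
  sl <- object$forward$sol
  if ("D" %in% names(cf))
    sl <- solute(sl$name, diffusivity = cf[["D"]], c_source = sl$c_source)
  lapply(seq_len(nsim), function(i) {
    generate_phantom_profiles(
      s0 = cf[["s0"]], ks = cf[["ks"]], sol = sl,
      materials = object$forward$materials, domain = object$forward$domain,
      times = sort(unique(object$observations$time)),
      x_step = NULL, x = sort(unique(object$observations$x)),
      noise = noise, seed = seed + i - 1L,
      dx_max = object$forward$dx_max,
      membrane_cells = object$forward$membrane_cells)
  })
}
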