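# Derived transport quantities: time to steady state, interface flux,
# penetration depth, profile normalisation.

#' Time to steady state
#'
#' Earliest output time at which the profile is within `rel_tol` (relative
#' L-infinity, scaled by the peak of the converged profile) of the
#' converged long-horizon profile. The converged profile defaults to the
#' final output of the solve; the result is flagged as a lower bound when
#' the run has not visibly settled by its horizon.
#'
#' @param result a `transport_result` with at least 3 output times.
#' @param rel_tol relative tolerance of the criterion, in (0, 1);
#'   default 0.05.
#' @param reference optional converged profile (numeric, one value per
#'   cell) to compare against instead of the final output.
#' @return an object of class `steady_state_report` with `time_s`,
#'   `time_h`, `converged` (FALSE when only a lower bound), the criterion
#'   and the reference profile.
#' @export
steady_state_time <- function(result, rel_tol = 0.05, reference = NULL) {
  stopifnot(inherits(result, "transport_result"),
            length(result$times) >= 3, rel_tol > 0, rel_tol < 1)
  nt <- length(result$times)
  cinf <- if (is.null(reference)) result$conc[nt, ] else reference
  stopifnot(length(cinf) == ncol(result$conc))
  scale <- max(abs(cinf))
  if (scale == 0) scale <- max(abs(result$conc), 1e-300)
  dev <- apply(abs(sweep(result$conc, 2, cinf)), 1, max) / scale
  # settled iff the criterion holds at this and every later output time
  ok <- rev(cumprod(rev(dev <= rel_tol))) > 0
  converged <- TRUE
  if (is.null(reference)) {
    # the last profile trivially matches itself; require the tail to be flat
    if (nt >= 2 && dev[nt - 1] > rel_tol / 5) converged <- FALSE
  }
  t_ss <- if (any(ok)) result$times[which(ok)[1]] else result$times[nt]
  if (!any(ok)) converged <- FALSE
  structure(
    list(time_s = t_ss, time_h = t_ss / 3600, rel_tol = rel_tol,
         converged = converged, deviation = dev, c_inf = cinf),
    class = "steady_state_report"
  )
}

#' @export
print.steady_state_report <- function(x, ...) {
  cat(sprintf("Steady state (%.3g%% L-inf criterion) at t = %.4g s (%.3g h)%s\n",
              100 * x$rel_tol, x$time_s, x$time_h,
              if (x$converged) "" else "  [lower bound: run not settled]"))
  invisible(x)
}

#' Average solute flux across the membrane interface
#'
#' Flux `J = -D_eff dc/dn` evaluated at the membrane/tissue interface face
#' (per unit interface area, uM.um/s), spatially uniform in the 1D model.
#' Because the averaging convention behind a reported mean flux is often
#' unstated, three conventions are returned: the time average from 0 to
#' the steady-state time (computed exactly from the integrated cumulative
#' interface flux when available), the steady (final) value, and the
#' whole-run time average.
#'
#' @param result a `transport_result` of a phantom solve (must contain a
#'   membrane interface).
#' @param window optional `c(t0, t1)` averaging window, s, within the
#'   output times; default 0 to the steady-state time.
#' @param rel_tol steady-state criterion forwarded to
#'   [steady_state_time()].
#' @return an object of class `flux_report` with the instantaneous series
#'   and the three averages.
#' @export
interface_flux <- function(result, window = NULL, rel_tol = 0.05) {
  stopifnot(inherits(result, "transport_result"))
  if (is.na(result$interface_face) || is.null(result$interface_flux))
    stop("result has no membrane interface", call. = FALSE)
  times <- result$times
  J <- result$interface_flux
  t_ss <- steady_state_time(result, rel_tol = rel_tol)$time_s
  if (is.null(window)) window <- c(0, t_ss)
  if (window[1] < times[1] || window[2] > times[length(times)])
    stop("averaging window outside the output times", call. = FALSE)
  avg_over <- function(t0, t1) {
    if (t1 <= t0) return(J[which.min(abs(times - t0))])
    if (!is.null(result$cumulative)) {
      Qi <- result$cumulative[, "interface"]
      q <- stats::approx(times, Qi, xout = c(t0, t1))$y
      (q[2] - q[1]) / (t1 - t0)
    } else {
      sel <- times >= t0 & times <= t1
      ts <- times[sel]; js <- J[sel]
      sum(diff(ts) * (js[-1] + js[-length(js)]) / 2) / (ts[length(ts)] - ts[1])
    }
  }
  structure(
    list(times = times, flux = J,
         window = window,
         average = avg_over(window[1], window[2]),
         average_to_steady = avg_over(0, t_ss),
         steady_value = J[length(J)],
         whole_run_average = avg_over(times[1], times[length(times)]),
         steady_state_time_s = t_ss),
    class = "flux_report"
  )
}

#' @export
print.flux_report <- function(x, ...) {
  cat("Interface flux (uM.um/s per unit area):\n")
  cat(sprintf("  time average 0 -> steady state (%.3g h): %.4g\n",
              x$steady_state_time_s / 3600, x$average_to_steady))
  cat(sprintf("  steady value: %.4g\n", x$steady_value))
  cat(sprintf("  whole-run average: %.4g\n", x$whole_run_average))
  invisible(x)
}

#' Penetration depth of a decaying profile
#'
#' Distance from the source face at which the concentration falls below
#' `threshold` times its value at the face, with linear sub-cell
#' interpolation.
#'
#' @param x positions, um, increasing away from the source face.
#' @param c concentrations at `x`.
#' @param threshold fraction of the face value, in (0, 1); default 0.1.
#' @return depth in um; 0 (with a warning) when the profile is already
#'   below the threshold at the face.
#' @export
penetration_depth <- function(x, c, threshold = 0.1) {
  stopifnot(length(x) == length(c), threshold > 0, threshold < 1)
  if (all(c == 0)) return(0)
  c_face <- c[1]
  cut <- threshold * c_face
  if (c_face <= 0 || c[1] < cut) {
    warning("profile below threshold at the source face")
    return(0)
  }
  below <- which(c < cut)
  if (!length(below)) return(x[length(x)] - x[1])
  i <- below[1]
  if (i == 1) return(0)
  # linear interpolation between the straddling samples
  x0 <- x[i - 1]; x1 <- x[i]; c0 <- c[i - 1]; c1 <- c[i]
  (x0 + (cut - c0) * (x1 - x0) / (c1 - c0)) - x[1]
}

#' Penetration depth from a transport result
#'
#' @param result a `transport_result`.
#' @param time output time, s.
#' @param threshold fraction of the interface value; default 0.1.
#' @param from position of the source face, um; defaults to the
#'   membrane/tissue interface (0 for the phantom) or the source shell.
#' @return depth in um.
#' @export
penetration_depth_at <- function(result, time, threshold = 0.1, from = NULL) {
  stopifnot(inherits(result, "transport_result"))
  if (is.null(from)) {
    from <- if (!is.na(result$interface_face))
      result$grid$faces[result$interface_face]
    else if (!is.null(attr(result$grid, "source_face")))
      result$grid$faces[attr(result$grid, "source_face")]
    else result$grid$faces[1]
  }
  sel <- result$x >= from
  prof <- profile_at(result, result$x[sel], time)[1, ]
  penetration_depth(result$x[sel], prof, threshold)
}

#' Normalise a concentration profile
#'
#' @param profile numeric profile, uM.
#' @param reference reference concentration (the source concentration), uM;
#'   must be positive.
#' @return dimensionless profile `profile / reference`.
#' @export
normalize_profile <- function(profile, reference) {
  if (!is.numeric(reference) || length(reference) != 1 || reference <= 0)
    stop("reference concentration must be a positive scalar", call. = FALSE)
  profile / reference
}
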