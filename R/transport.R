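# Transient advection-diffusion in layered porous media: conservative
# cell-centred finite volumes in Cartesian or spherical geometry, harmonic
# interface diffusivities, upwind advection, stiff BDF time integration.
#
# The governing balance per cell is  eps * dc/dt = div(D_eff grad c - u c),
# with D_eff = s(t) * eps * D / tau in membrane cells and the porosity eps
# entering storage only. Cumulative boundary/interface fluxes are integrated
# as extra ODE states so the mass balance can be audited to solver accuracy.

#' Assemble a transport problem
#'
#' @param grid a `grid1d` from [build_phantom_grid()] or
#'   [build_spheroid_radial_grid()].
#' @param materials named list of [porous_material()] keyed by the grid's
#'   material labels.
#' @param sol a [solute()].
#' @param saturation optional [saturation_model()] applied to cells whose
#'   material label is `"membrane"`.
#' @param bc_left,bc_right boundary conditions: `list(type = "dirichlet",
#'   value = )` or `list(type = "closed")`. A sink is a Dirichlet condition
#'   at 0.
#' @param advection optional face velocity vector (um/s, length
#'   `length(grid$faces)`) or a `darcy_field` (mapped via
#'   [darcy_face_velocities()]).
#' @param clamp_cells integer indices of cells held at `clamp_value`
#'   (an internal source shell); empty by default.
#' @param clamp_value concentration of clamped cells, uM.
#' @param init initial concentration, scalar or per cell, uM.
#' @param times output times, s; must start at 0.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param track_fluxes integrate cumulative boundary/interface fluxes as
#'   extra states (needed for the mass-balance audit and exact flux
#'   averages; adds a full-Jacobian solve).
#' @return an object of class `transport_config`.
#' @export
transport_config <- function(grid, materials, sol, saturation = NULL,
                             bc_left = list(type = "closed"),
                             bc_right = list(type = "dirichlet", value = 0),
                             advection = NULL,
                             clamp_cells = integer(0), clamp_value = 0,
                             init = 0, times = seq(0, 24000, by = 2400),
                             rtol = 1e-9, atol = NULL,
                             track_fluxes = TRUE) {
  stopifnot(inherits(grid, "grid1d"), inherits(sol, "solute"))
  labs <- grid$material_labels
  used <- unique(labs[grid$material])
  if (!all(used %in% names(materials)))
    stop("materials must provide: ", paste(used, collapse = ", "), call. = FALSE)
  for (m in materials) stopifnot(inherits(m, "porous_material"))
  if (!is.null(saturation)) stopifnot(inherits(saturation, "saturation_model"))
  ok_bc <- function(b) is.list(b) && b$type %in% c("dirichlet", "closed") &&
    (b$type == "closed" || is.numeric(b$value))
  if (!ok_bc(bc_left) || !ok_bc(bc_right))
    stop("boundary conditions must be dirichlet(value) or closed", call. = FALSE)
  if (inherits(advection, "darcy_field"))
    advection <- darcy_face_velocities(advection, grid)
  if (!is.null(advection) && length(advection) != length(grid$faces))
    stop("advection field grid mismatch: need one velocity per face", call. = FALSE)
  if (times[1] != 0 || any(diff(times) <= 0))
    stop("times must start at 0 and increase", call. = FALSE)
  if (length(clamp_cells) > 0)
    stopifnot(all(clamp_cells >= 1), all(clamp_cells <= grid$n))
  n <- grid$n
  init <- rep_len(init, n)
  init[clamp_cells] <- clamp_value
  c_ref <- max(init, clamp_value,
               if (bc_left$type == "dirichlet") bc_left$value else 0,
               if (bc_right$type == "dirichlet") bc_right$value else 0, 1)
  if (is.null(atol)) atol <- 1e-12 * c_ref
  structure(
    list(grid = grid, materials = materials, solute = sol,
         saturation = saturation, bc_left = bc_left, bc_right = bc_right,
         advection = advection, clamp_cells = as.integer(clamp_cells),
         clamp_value = clamp_value, init = init, times = times,
         rtol = rtol, atol = atol, track_fluxes = isTRUE(track_fluxes)),
    class = "transport_config"
  )
}

# Precompute the discretisation arrays shared by every RHS evaluation.
.transport_ops <- function(config) {
  g <- config$grid
  n <- g$n
  labs <- g$material_labels[g$material]
  eps <- vapply(labs, function(l) config$materials[[l]]$porosity, numeric(1))
  tau <- vapply(labs, function(l) config$materials[[l]]$tortuosity, numeric(1))
  D1 <- eps * config$solute$diffusivity / tau   # per-cell D_eff at s = 1
  mem <- which(labs == "membrane")
  if (is.null(config$saturation)) mem <- integer(0)
  faces <- g$faces; centers <- g$centers
  # interior faces 2..n (face i sits between cells i-1 and i)
  d1 <- faces[2:n] - centers[1:(n - 1)]
  d2 <- centers[2:n] - faces[2:n]
  dcent <- d1 + d2
  ifm <- which(diff(g$material) != 0)       # cells left of a material change
  interface_face <- if (length(ifm)) ifm[1] + 1L else NA_integer_
  u <- config$advection
  if (!is.null(u) && max(abs(u)) > 0) {
    # cell Peclet guard: upwinding is only accurate when advection is weak
    Dmin <- pmin(D1[1:(n - 1)], D1[2:n])
    pe_cell <- max(abs(u[2:n]) * dcent / Dmin)
    if (pe_cell > 2)
      warning(sprintf("cell Peclet number %.2f > 2; refine the grid", pe_cell))
  }
  list(n = n, eps = eps, D1 = D1, mem = mem, faces = faces,
       centers = centers, d1 = d1, d2 = d2, dcent = dcent,
       A = g$face_areas, V = g$volumes,
       dbl = centers[1] - faces[1], dbr = faces[n + 1] - centers[n],
       interface_face = interface_face, u = u,
       free = setdiff(seq_len(n), config$clamp_cells))
}

# Face fluxes (positive along +x / +r), length n + 1.
.face_fluxes <- function(c, t, config, ops) {
  n <- ops$n
  Dc <- ops$D1
  if (length(ops$mem)) {
    s <- saturation_at(config$saturation, t)
    Dc[ops$mem] <- s * Dc[ops$mem]
  }
  DL <- Dc[1:(n - 1)]; DR <- Dc[2:n]
  Df <- (ops$d1 + ops$d2) / (ops$d1 / DL + ops$d2 / DR)
  Fi <- -ops$A[2:n] * Df * (c[2:n] - c[1:(n - 1)]) / ops$dcent
  if (!is.null(ops$u)) {
    ui <- ops$u[2:n]
    cup <- ifelse(ui > 0, c[1:(n - 1)], c[2:n])
    Fi <- Fi + ops$A[2:n] * ui * cup
  }
  bl <- config$bc_left
  if (bl$type == "dirichlet") {
    F0 <- -ops$A[1] * Dc[1] * (c[1] - bl$value) / ops$dbl
    if (!is.null(ops$u)) {
      u0 <- ops$u[1]
      F0 <- F0 + ops$A[1] * u0 * if (u0 > 0) bl$value else c[1]
    }
  } else F0 <- 0
  br <- config$bc_right
  if (br$type == "dirichlet") {
    Fn <- -ops$A[n + 1] * Dc[n] * (br$value - c[n]) / ops$dbr
    if (!is.null(ops$u)) {
      un <- ops$u[n + 1]
      Fn <- Fn + ops$A[n + 1] * un * if (un > 0) c[n] else br$value
    }
  } else Fn <- 0
  c(F0, Fi, Fn)
}

#' Solve a transport problem
#'
#' Method-of-lines integration of the finite-volume semi-discretisation
#' with a stiff backward-differentiation (BDF) integrator and adaptive
#' step control. Cumulative boundary, interface and source-shell fluxes are
#' integrated alongside the concentrations, so the porosity-weighted mass
#' balance can be audited at every output step.
#'
#' @param config a [transport_config()].
#' @return an object of class `transport_result`: output times (s), cell
#'   centres (um), concentration matrix (times x cells, uM), instantaneous
#'   interface flux series (uM.um/s per unit area, membrane/tissue face),
#'   cumulative fluxes, porosity-weighted mass, delivered mass and per-step
#'   mass-balance residuals (relative to delivered mass).
#' @export
solve_transport <- function(config) {
  stopifnot(inherits(config, "transport_config"))
  ops <- .transport_ops(config)
  n <- ops$n
  track <- config$track_fluxes
  epsV <- ops$eps * ops$V
  clamp <- config$clamp_cells
  iface <- ops$interface_face
  rhs <- function(t, y, p) {
    c <- y[1:n]
    FF <- .face_fluxes(c, t, config, ops)
    dc <- (FF[1:n] - FF[2:(n + 1)]) / epsV
    if (length(clamp)) dc[clamp] <- 0
    if (!track) return(list(dc))
    dQin <- FF[1]
    dQout <- FF[n + 1]
    dQif <- if (is.na(iface)) 0 else FF[iface]
    dQsrc <- if (length(clamp)) sum(FF[clamp + 1L] - FF[clamp]) else 0
    list(c(dc, dQin, dQout, dQif, dQsrc))
  }
  y0 <- if (track) c(config$init, 0, 0, 0, 0) else config$init
  sol <- if (track) {
    deSolve::ode(y0, config$times, rhs, parms = NULL, method = "lsode",
                 rtol = config$rtol, atol = config$atol,
                 maxsteps = 100000)
  } else {
    deSolve::ode(y0, config$times, rhs, parms = NULL, method = "lsode",
                 jactype = "bandint", bandup = 1, banddown = 1,
                 rtol = config$rtol, atol = config$atol,
                 maxsteps = 100000)
  }
  if (attr(sol, "istate")[1] < 0)
    stop("transport solve failed to converge; see deSolve diagnostics",
         call. = FALSE)
  times <- sol[, 1]
  conc <- sol[, 1 + seq_len(n), drop = FALSE]
  cum <- NULL; residual <- NULL; delivered <- NA_real_
  if (track) {
    cum <- sol[, n + 2:5, drop = FALSE]
    colnames(cum) <- c("influx", "outflux", "interface", "source_shell")
    mass_free <- as.numeric(conc[, ops$free, drop = FALSE] %*% epsV[ops$free])
    net <- cum[, "influx"] - cum[, "outflux"] + cum[, "source_shell"]
    delivered <- max(abs(cum[nrow(cum), "influx"]) +
                       abs(cum[nrow(cum), "source_shell"]),
                     .Machine$double.eps)
    residual <- diff(mass_free) - diff(net)
  }
  # instantaneous interface flux per unit face area at output times
  if_flux <- NULL
  if (!is.na(iface)) {
    if_flux <- vapply(seq_along(times), function(i) {
      FF <- .face_fluxes(conc[i, ], times[i], config, ops)
      FF[iface] / ops$A[iface]
    }, numeric(1))
  }
  structure(
    list(times = times, x = ops$centers, conc = unname(conc),
         grid = config$grid, config = config,
         interface_face = iface, interface_flux = if_flux,
         cumulative = cum, delivered = delivered,
         mass = as.numeric(conc %*% epsV),
         mass_residual = if (is.null(residual)) NULL else residual / delivered),
    class = "transport_result"
  )
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("Transport solve: %d cells (%s), %d output times to %g s\n",
              ncol(x$conc), x$grid$geometry, length(x$times), max(x$times)))
  cat(sprintf("  final concentration range [%.4g, %.4g] uM\n",
              min(x$conc[nrow(x$conc), ]), max(x$conc[nrow(x$conc), ])))
  if (!is.null(x$mass_residual))
    cat(sprintf("  max |mass-balance residual| = %.3g (relative to delivered mass)\n",
                max(abs(x$mass_residual))))
  invisible(x)
}

#' @export
plot.transport_result <- function(x, times = NULL, normalize = FALSE, ...) {
  idx <- if (is.null(times)) seq_along(x$times)
         else vapply(times, function(t) which.min(abs(x$times - t)), integer(1))
  y <- t(x$conc[idx, , drop = FALSE])
  ylab <- "concentration (uM)"
  if (normalize) {
    y <- y / max(y)
    ylab <- "c / c_max"
  }
  graphics::matplot(x$x, y, type = "l", lty = 1,
                    xlab = sprintf("position (um, %s)", x$grid$geometry),
                    ylab = ylab, ...)
  invisible(x)
}

#' Interpolate a solved concentration field
#'
#' Linear interpolation of the cell-centred field at arbitrary positions
#' and output times present in the solve.
#'
#' @param result a `transport_result`.
#' @param x positions, um.
#' @param times times, s; each must match an output time.
#' @return matrix `length(times) x length(x)`.
#' @export
profile_at <- function(result, x, times) {
  stopifnot(inherits(result, "transport_result"))
  it <- vapply(times, function(t) {
    i <- which(abs(result$times - t) <= 1e-6 * max(t, 1))
    if (!length(i)) stop("time ", t, " is not an output time", call. = FALSE)
    i[1]
  }, integer(1))
  out <- vapply(it, function(i) {
    stats::approx(result$x, result$conc[i, ], xout = x, rule = 2)$y
  }, numeric(length(x)))
  t(matrix(out, nrow = length(x)))
}

# -- configuration wrappers for the three delivery experiments ----------

#' Simulate dye delivery into the agarose phantom
#'
#' Transient diffusion of the fluorescent dye from the channel reservoir
#' through the time-saturating nanoporous membrane into the 5 mm agarose
#' phantom, with the far end held at zero concentration (sink) and the
#' channel face held at the source concentration.
#'
#' @param sol a [solute()]; defaults to sulforhodamine B at 10 uM.
#' @param saturation a [saturation_model()] for the membrane.
#' @param materials named list with `membrane` and `agarose`
#'   [porous_material()] entries.
#' @param domain a [phantom_domain()].
#' @param times output times, s; default every 40 min to 400 min.
#' @param dx_max,membrane_cells grid resolution (see
#'   [build_phantom_grid()]).
#' @param ... further arguments passed to [transport_config()] (e.g.
#'   `rtol`, `track_fluxes`).
#' @return a `transport_result`.
#' @examples
#' \donttest{
#' res <- solve_phantom(times = seq(0, 24000, by = 2400))
#' plot(res)
#' }
#' @export
solve_phantom <- function(sol = default_solutes()$srb,
                          saturation = default_saturation(),
                          materials = default_materials(),
                          domain = phantom_domain(),
                          times = seq(0, 400 * 60, by = 40 * 60),
                          dx_max = 50, membrane_cells = 5, ...) {
  grid <- build_phantom_grid(domain, dx_max = dx_max,
                             membrane_cells = membrane_cells)
  cfg <- transport_config(
    grid, materials, sol, saturation = saturation,
    bc_left = list(type = "dirichlet", value = sol$c_source),
    bc_right = list(type = "dirichlet", value = 0),
    times = times, ...
  )
  solve_transport(cfg)
}

#' Simulate radial delivery into the embedded organoid
#'
#' Spherically symmetric reduction of intra-organoid delivery: the source
#' shell (the radius where the nanoporous membrane interfaces the tissue)
#' is held at the channel concentration, the centre is regular (zero flux)
#' and the outer surface sees the culture well (sink by default). Darcy
#' leakage advection can be coupled in.
#'
#' @param sol a [solute()]; defaults to the MRI contrast agent at 5.6 mM.
#' @param domain a [spheroid_domain()].
#' @param material the tissue [porous_material()].
#' @param times output times, s; default 0 and 1 h.
#' @param dr radial grid spacing, um.
#' @param advection optional `darcy_field` from [darcy_radial_flow()].
#' @param ... further arguments passed to [transport_config()].
#' @return a `transport_result`.
#' @export
solve_organoid_radial <- function(sol = default_solutes()$magnevist,
                                  domain = spheroid_domain(),
                                  material = default_materials()$organoid,
                                  times = c(0, 3600), dr = 10,
                                  advection = NULL, ...) {
  grid <- build_spheroid_radial_grid(domain, dr = dr,
                                     material_label = material$name)
  mats <- setNames(list(material), material$name)
  bc_outer <- if (domain$outer_bc == "sink")
    list(type = "dirichlet", value = 0) else list(type = "closed")
  cfg <- transport_config(
    grid, mats, sol,
    bc_left = list(type = "closed"), bc_right = bc_outer,
    advection = advection,
    clamp_cells = attr(grid, "source_cell"), clamp_value = sol$c_source,
    times = times, ...
  )
  solve_transport(cfg)
}

#' Simulate contrast delivery into an agarose-embedded device
#'
#' The same radial solver as [solve_organoid_radial()] with the sphere
#' filled with agarose and the CT contrast agent (iohexol) as solute;
#' default snapshots at 0, 1, 4 and 24 h of delivery.
#'
#' @inheritParams solve_organoid_radial
#' @export
solve_agarose_3d_embedding <- function(sol = default_solutes()$iohexol,
                                       domain = spheroid_domain(),
                                       material = default_materials()$agarose,
                                       times = c(0, 1, 4, 24) * 3600,
                                       dr = 10, advection = NULL, ...) {
  solve_organoid_radial(sol = sol, domain = domain, material = material,
                        times = times, dr = dr, advection = advection, ...)
}
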