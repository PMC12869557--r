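# Pressure-driven laminar flow in the rectangular microchannels, Darcy
# leakage flow in porous domains, and dimensionless diagnostics.

#' Laminar flow in a rectangular microchannel
#'
#' Classical Fourier-series solution of fully developed pressure-driven
#' laminar flow in a rectangular duct (no-slip on all four walls):
#' \deqn{u(y,z) = \frac{4 h^2 \Delta p}{\pi^3 \eta L} \sum_{n\ odd}
#'   \frac{1}{n^3}\left[1 - \frac{\cosh(n\pi y/h)}{\cosh(n\pi w/2h)}\right]
#'   \sin(n\pi z/h)}
#' with the matching series for the volumetric flow. Creeping flow: all
#' quantities are strictly linear in the applied pressure drop.
#'
#' @param width,depth duct cross-section, um (width w along y, depth h
#'   along z).
#' @param length_mm duct length, mm.
#' @param dp applied pressure drop, Pa.
#' @param fl a [fluid()].
#' @param n_terms number of odd series terms (>= 10).
#' @param ny,nz evaluation grid for the velocity field.
#' @return an object of class `duct_flow` with the velocity field (um/s),
#'   `u_max`, `u_mean`, volumetric flow `Q` (um^3/s) and hydraulic
#'   resistance `R = dp/Q` (Pa.s/um^3).
#' @examples
#' rectangular_duct_flow(200, 10, 11.7, dp = 690)
#' @export
rectangular_duct_flow <- function(width, depth, length_mm, dp,
                                  fl = default_fluid(), n_terms = 51,
                                  ny = 41, nz = 41) {
  if (width <= 0 || depth <= 0 || length_mm <= 0)
    stop("duct geometry must be positive", call. = FALSE)
  stopifnot(dp >= 0, n_terms >= 10)
  w <- width * 1e-6; h <- depth * 1e-6; L <- length_mm * 1e-3
  eta <- fl$viscosity
  n <- seq(1, by = 2, length.out = n_terms)
  y <- seq(-w / 2, w / 2, length.out = ny)
  z <- seq(0, h, length.out = nz)
  pref <- 4 * h^2 * dp / (pi^3 * eta * L)
  u <- matrix(0, ny, nz)
  for (k in seq_along(n)) {
    nk <- n[k]
    # guard cosh overflow for wide ducts: cosh(a)/cosh(b) = exp(|a|-b) * ...
    a <- nk * pi * y / h
    b <- nk * pi * w / (2 * h)
    ratio <- exp(abs(a) - b) * (1 + exp(-2 * abs(a))) / (1 + exp(-2 * b))
    u <- u + pref / nk^3 * outer(1 - ratio, sin(nk * pi * z / h))
  }
  Q_si <- duct_flow_rate(width, depth, length_mm, dp, fl, n_terms) * 1e-18
  u_um <- u * 1e6
  structure(
    list(width = width, depth = depth, length_mm = length_mm, dp = dp,
         y_um = y * 1e6, z_um = z * 1e6, u = u_um,
         u_max = max(u_um), u_mean = Q_si / (w * h) * 1e6,
         Q = Q_si * 1e18, R = if (Q_si > 0) dp / (Q_si * 1e18) else Inf),
    class = "duct_flow"
  )
}

#' @export
print.duct_flow <- function(x, ...) {
  cat(sprintf("Rectangular duct %g x %g um, L = %g mm, dp = %g Pa\n",
              x$width, x$depth, x$length_mm, x$dp))
  cat(sprintf("  u_max = %.4g um/s, u_mean = %.4g um/s, Q = %.4g um^3/s\n",
              x$u_max, x$u_mean, x$Q))
  invisible(x)
}

#' Volumetric flow rate of a rectangular duct
#'
#' Series expression
#' \deqn{Q = \frac{h^3 w \Delta p}{12 \eta L}\left[1 - \sum_{n\ odd}
#'   \frac{192 h}{\pi^5 n^5 w} \tanh\left(\frac{n\pi w}{2h}\right)\right]}
#'
#' @inheritParams rectangular_duct_flow
#' @return flow rate in um^3/s.
#' @export
duct_flow_rate <- function(width, depth, length_mm, dp,
                           fl = default_fluid(), n_terms = 51) {
  if (width <= 0 || depth <= 0 || length_mm <= 0)
    stop("duct geometry must be positive", call. = FALSE)
  w <- width * 1e-6; h <- depth * 1e-6; L <- length_mm * 1e-3
  n <- seq(1, by = 2, length.out = n_terms)
  corr <- sum(192 * h / (pi^5 * n^5 * w) * tanh(n * pi * w / (2 * h)))
  Q <- h^3 * w * dp / (12 * fl$viscosity * L) * (1 - corr)
  Q * 1e18
}

#' Hydraulic resistance of a rectangular duct
#'
#' @inheritParams rectangular_duct_flow
#' @return resistance `dp/Q` in Pa.s/um^3 (independent of `dp`).
#' @export
duct_resistance <- function(width, depth, length_mm,
                            fl = default_fluid(), n_terms = 51) {
  1 / duct_flow_rate(width, depth, length_mm, dp = 1, fl = fl,
                     n_terms = n_terms)
}

#' Flow through a tapered wing channel
#'
#' Lubrication approximation: the taper is discretised into `n_segments`
#' uniform rectangular ducts in series; the flow rate follows from the
#' summed resistances and is strictly linear in the applied pressure.
#'
#' @param profile a [channel_profile()].
#' @param dp applied pressure drop over the full wing, Pa.
#' @param fl a [fluid()].
#' @param n_segments number of series segments (>= 10; default 200).
#' @return an object of class `network_flow` with total resistance, flow
#'   rate (um^3/s) and per-segment mean velocities (um/s).
#' @export
network_flow <- function(profile, dp, fl = default_fluid(), n_segments = 200) {
  stopifnot(inherits(profile, "channel_profile"), n_segments >= 10, dp >= 0)
  r_edges <- seq(0, profile$r_max_mm, length.out = n_segments + 1L)
  r_mid <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  seg_len <- diff(r_edges)
  w <- channel_width_at(profile, r_mid, "inner")
  h <- profile$depth_um
  R <- vapply(seq_len(n_segments), function(i)
    duct_resistance(w[i], h, seg_len[i], fl = fl), numeric(1))
  R_tot <- sum(R)
  Q <- dp / R_tot
  structure(
    list(r_mid_mm = r_mid, width_um = w, depth_um = h,
         segment_R = R, R_total = R_tot, dp = dp, Q = Q,
         u_mean = Q / (w * h)),
    class = "network_flow"
  )
}

#' @export
print.network_flow <- function(x, ...) {
  cat(sprintf("Tapered channel, %d segments: R = %.4g Pa.s/um^3\n",
              length(x$segment_R), x$R_total))
  cat(sprintf("  dp = %g Pa -> Q = %.4g um^3/s, mean velocity %.4g (inlet) to %.4g (outlet) um/s\n",
              x$dp, x$Q, x$u_mean[1], x$u_mean[length(x$u_mean)]))
  invisible(x)
}

#' Hydraulic diameter of a rectangular duct
#'
#' @param width,depth cross-section, um.
#' @return `2*w*h/(w+h)` in um.
#' @export
hydraulic_diameter <- function(width, depth) {
  stopifnot(width > 0, depth > 0)
  2 * width * depth / (width + depth)
}

#' Reynolds number
#'
#' `Re = rho * u * D_h / eta` with the velocity in um/s and the hydraulic
#' diameter in um (converted to SI internally).
#'
#' @param u_um_s mean velocity, um/s.
#' @param d_h_um hydraulic diameter, um.
#' @param fl a [fluid()].
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(u_um_s, d_h_um, fl = default_fluid()) {
  stopifnot(u_um_s >= 0, d_h_um > 0)
  fl$density * (u_um_s * 1e-6) * (d_h_um * 1e-6) / fl$viscosity
}

#' Peclet number
#'
#' `Pe = u * L / D`, the ratio of advective to diffusive transport rates.
#'
#' @param u_um_s velocity, um/s.
#' @param length_um characteristic length, um (membrane thickness by
#'   convention here; the appropriate choice depends on the question asked).
#' @param diffusivity_um2_s diffusivity, um^2/s.
#' @return dimensionless Peclet number.
#' @export
peclet_number <- function(u_um_s, length_um, diffusivity_um2_s) {
  stopifnot(length_um > 0, diffusivity_um2_s > 0)
  u_um_s * length_um / diffusivity_um2_s
}

#' Steady Darcy leakage flow into the spherical organoid
#'
#' Reduced spherically symmetric model of pressure-driven leakage: the
#' channel pressure drives flow through the membrane (conductance
#' `k_membrane / thickness` per unit area, in series) across the source
#' shell at `r_s`, then outward through the organoid to the outer boundary
#' held at 0 Pa. Steady incompressible Darcy flow gives a superficial
#' velocity `u(r) = Q / (4 pi r^2)` between the shell and the surface and
#' zero inside the shell, so `r^2 u(r)` is constant in every source-free
#' shell.
#'
#' @param domain a [spheroid_domain()].
#' @param material organoid [porous_material()].
#' @param membrane membrane [porous_material()] (permeability used for the
#'   series conductance).
#' @param dp driving pressure, Pa (>= 0).
#' @param fl a [fluid()].
#' @param membrane_thickness_um membrane thickness, um.
#' @param exposed_area_um2 wetted membrane area; defaults to the full
#'   source-shell sphere `4 pi r_s^2`.
#' @param n number of radial sample points.
#' @return an object of class `darcy_field` with radii, radial velocity
#'   (um/s), total flow `Q` (um^3/s), `u_max` and the radius at which it
#'   occurs.
#' @export
darcy_radial_flow <- function(domain, material, membrane, dp,
                              fl = default_fluid(),
                              membrane_thickness_um = 10,
                              exposed_area_um2 = NULL, n = 200) {
  stopifnot(inherits(domain, "spheroid_domain"),
            inherits(material, "porous_material"),
            inherits(membrane, "porous_material"), dp >= 0)
  if (material$permeability <= 0 || membrane$permeability <= 0)
    stop("permeability must be positive", call. = FALSE)
  rs <- domain$r_source_um
  re <- equivalent_radius(domain)
  eta <- fl$viscosity
  A_s <- if (is.null(exposed_area_um2)) 4 * pi * rs^2 else exposed_area_um2
  R_mem <- eta * membrane_thickness_um / (membrane$permeability * A_s)
  R_org <- eta / (4 * pi * material$permeability) * (1 / rs - 1 / re)
  Q <- dp / (R_mem + R_org)
  r <- seq(rs, re, length.out = n)
  u <- Q / (4 * pi * r^2)
  structure(
    list(r_um = r, u_um_s = u, Q = Q, dp = dp,
         r_source_um = rs, r_outer_um = re,
         R_membrane = R_mem, R_tissue = R_org,
         u_max = if (Q > 0) max(u) else 0,
         r_at_max = r[which.max(u)]),
    class = "darcy_field"
  )
}

#' @export
print.darcy_field <- function(x, ...) {
  cat(sprintf("Darcy leakage flow: dp = %g Pa -> Q = %.4g um^3/s\n", x$dp, x$Q))
  cat(sprintf("  max |u_r| = %.4g um/s at r = %.4g um (source shell %g um, surface %.4g um)\n",
              x$u_max, x$r_at_max, x$r_source_um, x$r_outer_um))
  invisible(x)
}

#' Face velocities of a Darcy field on a transport grid
#'
#' Maps the radial Darcy velocity onto the faces of a spherical `grid1d`
#' for use as the advection field of the transport solver.
#'
#' @param field a `darcy_field`.
#' @param grid a spherical `grid1d`.
#' @return numeric vector of face velocities (um/s), zero inside the source
#'   shell.
#' @export
darcy_face_velocities <- function(field, grid) {
  stopifnot(inherits(field, "darcy_field"), inherits(grid, "grid1d"))
  if (grid$geometry != "spherical")
    stop("Darcy field applies to spherical grids", call. = FALSE)
  if (max(grid$faces) > field$r_outer_um * (1 + 1e-9))
    stop("advection field does not cover the grid", call. = FALSE)
  u <- numeric(length(grid$faces))
  out <- grid$faces >= field$r_source_um - 1e-9 & grid$faces > 0
  u[out] <- field$Q / (4 * pi * grid$faces[out]^2)
  u
}

#' Pressure sweep summary of channel hydraulics
#'
#' @param pressures_Pa vector of applied pressures; defaults to the three
#'   delivery presets (690, 510, 196 Pa).
#' @param profile a [channel_profile()].
#' @param fl a [fluid()].
#' @return data.frame of pressure, flow rate, mean and max velocity at the
#'   widest cross-section, and Reynolds number there.
#' @export
hydraulics_sweep <- function(pressures_Pa = c(690, 510, 196),
                             profile = channel_profile(),
                             fl = default_fluid()) {
  w_out <- channel_width_at(profile, profile$r_max_mm, "inner")
  h <- profile$depth_um
  do.call(rbind, lapply(pressures_Pa, function(p) {
    nf <- network_flow(profile, p, fl)
    duct <- rectangular_duct_flow(w_out, h, profile$r_max_mm, p, fl)
    u_mean <- nf$Q / (w_out * h)
    data.frame(
      pressure_Pa = p,
      Q_um3_s = nf$Q,
      u_mean_um_s = u_mean,
      u_max_um_s = duct$u_max,
      Re = reynolds_number(u_mean, hydraulic_diameter(w_out, h), fl)
    )
  }))
}
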