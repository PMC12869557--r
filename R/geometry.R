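# Parametric device geometry (tapered channels, nanoporous membrane, buckled
# cage) and the 1D simulation domains with their finite-volume grids.

#' Tapered microchannel profile
#'
#' The device consists of radially distributed wing microchannels whose inner
#' (fluid-carrying) width tapers from the centre outwards while the depth
#' stays constant.
#'
#' @param inner_width_r0,inner_width_rmax inner width at `r = 0` and at
#'   `r = r_max`, um.
#' @param outer_width_r0,outer_width_rmax outer (structural) width, um.
#' @param r_max_mm radial extent of a wing, mm.
#' @param depth_um channel depth, um (constant along the wing).
#' @param n_wings number of wings.
#' @return an object of class `channel_profile`.
#' @export
channel_profile <- function(inner_width_r0 = 20, inner_width_rmax = 200,
                            outer_width_r0 = 60, outer_width_rmax = 2000,
                            r_max_mm = 11.7, depth_um = 10, n_wings = 8) {
  stopifnot(inner_width_r0 > 0, inner_width_rmax >= inner_width_r0,
            outer_width_r0 > 0, outer_width_rmax >= outer_width_r0,
            r_max_mm > 0, depth_um > 0, n_wings >= 1)
  structure(
    list(inner_width_r0 = inner_width_r0, inner_width_rmax = inner_width_rmax,
         outer_width_r0 = outer_width_r0, outer_width_rmax = outer_width_rmax,
         r_max_mm = r_max_mm, depth_um = depth_um, n_wings = n_wings),
    class = "channel_profile"
  )
}

#' Channel width at a radial position
#'
#' Monotone interpolation between the endpoint widths; linear by default
#' (the taper is only described as gradual, so linear is the minimal
#' assumption).
#'
#' @param profile a [channel_profile()].
#' @param r_mm radial position in mm, in `[0, r_max]`; vectorised.
#' @param which `"inner"` (fluid-carrying) or `"outer"` (structural) width.
#' @return width in um.
#' @export
channel_width_at <- function(profile, r_mm, which = c("inner", "outer")) {
  stopifnot(inherits(profile, "channel_profile"))
  which <- match.arg(which)
  if (any(r_mm < 0 | r_mm > profile$r_max_mm))
    stop("r_mm outside [0, r_max]", call. = FALSE)
  w0 <- profile[[paste0(which, "_width_r0")]]
  w1 <- profile[[paste0(which, "_width_rmax")]]
  w0 + (w1 - w0) * r_mm / profile$r_max_mm
}

#' Nanoporous membrane specification
#'
#' @param thickness_um membrane thickness, um.
#' @param pore_diameter_nm nominal pore diameter, nm.
#' @param pore_density_cm2 areal pore density, pores/cm^2.
#' @param barrier_thickness_um thickness of the conformal barrier coating
#'   that seals non-exposed regions, um.
#' @return an object of class `membrane_spec`. Pore-level quantities are
#'   retained for documentation; hydraulic conductance is computed from the
#'   Darcy permeability through the thickness.
#' @export
membrane_spec <- function(thickness_um = 10, pore_diameter_nm = 200,
                          pore_density_cm2 = 3e8, barrier_thickness_um = 1) {
  stopifnot(thickness_um > 0, pore_density_cm2 > 0)
  structure(
    list(thickness_um = thickness_um, pore_diameter_nm = pore_diameter_nm,
         pore_density_cm2 = pore_density_cm2,
         barrier_thickness_um = barrier_thickness_um),
    class = "membrane_spec"
  )
}

#' Buckled cage geometry
#'
#' The buckled wings form a cage whose x-y diameter varies with height:
#' it widens from the central bonding site to a maximum, narrows to the
#' insertion aperture, then flares to the highest point. The default
#' anchors are `(z, diameter)` = (0, 110), (398, 771), (1480, 339),
#' (2130, 1580) um; the base entry is the central bonding region.
#'
#' @param anchors two-column matrix or data.frame of `(z_um, diameter_um)`
#'   with strictly increasing heights and positive diameters.
#' @return an object of class `cage_spec`.
#' @export
cage_spec <- function(anchors = NULL) {
  if (is.null(anchors)) {
    a <- of_constants()$cage$anchors
    anchors <- do.call(rbind, a)
  }
  anchors <- as.matrix(anchors)
  stopifnot(ncol(anchors) == 2)
  z <- anchors[, 1]; d <- anchors[, 2]
  if (any(diff(z) <= 0)) stop("anchor heights must be strictly increasing", call. = FALSE)
  if (any(d <= 0)) stop("anchor diameters must be positive", call. = FALSE)
  structure(list(z = z, diameter = d), class = "cage_spec")
}

#' Cage diameter at a height
#'
#' Piecewise-linear interpolation through the anchors; exact at anchors and
#' monotone between consecutive anchors.
#'
#' @param cage a [cage_spec()].
#' @param z_um height above the substrate, um, within the anchor range;
#'   vectorised.
#' @return diameter in um.
#' @export
cage_diameter_at <- function(cage, z_um) {
  stopifnot(inherits(cage, "cage_spec"))
  if (any(z_um < min(cage$z) | z_um > max(cage$z)))
    stop("z_um outside the anchor range", call. = FALSE)
  stats::approx(cage$z, cage$diameter, xout = z_um, method = "linear")$y
}

#' Oblate-spheroid organoid domain
#'
#' For radial transport the oblate spheroid (equatorial semi-axis `r0`,
#' polar semi-axis `r0z`) is reduced to its volume-equivalent sphere, with
#' a source shell at the radius where the nanoporous membrane interfaces
#' the tissue (half the maximum cage diameter by default).
#'
#' @param r0_mm,r0z_mm equatorial and polar semi-axes, mm.
#' @param r_source_um radius of the membrane source shell, um; must lie
#'   strictly inside the equivalent radius.
#' @param outer_bc outer boundary condition: `"sink"` (culture well at zero
#'   concentration) or `"closed"`.
#' @return an object of class `spheroid_domain`.
#' @export
spheroid_domain <- function(r0_mm = 1.0, r0z_mm = 0.98, r_source_um = 385.5,
                            outer_bc = c("sink", "closed")) {
  stopifnot(r0_mm > 0, r0z_mm > 0, r_source_um > 0)
  outer_bc <- match.arg(outer_bc)
  dom <- structure(
    list(r0_mm = r0_mm, r0z_mm = r0z_mm, r_source_um = r_source_um,
         outer_bc = outer_bc),
    class = "spheroid_domain"
  )
  if (r_source_um >= equivalent_radius(dom))
    stop("r_source_um must lie strictly inside the equivalent radius", call. = FALSE)
  dom
}

#' Volume-equivalent sphere radius of the oblate spheroid
#'
#' @param domain a [spheroid_domain()].
#' @return radius in um, `(r0^2 * r0z)^(1/3) * 1000`.
#' @export
equivalent_radius <- function(domain) {
  stopifnot(inherits(domain, "spheroid_domain"))
  (domain$r0_mm^2 * domain$r0z_mm)^(1 / 3) * 1000
}

#' Agarose phantom domain
#'
#' A rectangular agarose phantom with the membrane-contact face at `x = 0`
#' (membrane occupying `[-thickness, 0]` when present), a sink held at zero
#' concentration at `x = L`, and closed boundaries elsewhere.
#'
#' @param length_mm phantom length along x, mm.
#' @param height_um phantom height along y, um (geometry bookkeeping; the
#'   default transport model is 1D along x).
#' @param membrane a [membrane_spec()] forming the source interface, or
#'   `NULL` for a bare agarose slab.
#' @return an object of class `phantom_domain`.
#' @export
phantom_domain <- function(length_mm = 5, height_um = 500,
                           membrane = membrane_spec()) {
  if (length_mm <= 0) stop("length_mm must be positive", call. = FALSE)
  stopifnot(height_um > 0)
  if (!is.null(membrane)) stopifnot(inherits(membrane, "membrane_spec"))
  structure(
    list(length_mm = length_mm, height_um = height_um, membrane = membrane),
    class = "phantom_domain"
  )
}

# -- grids --------------------------------------------------------------

.make_grid1d <- function(faces, material, labels, geometry = c("cartesian", "spherical")) {
  geometry <- match.arg(geometry)
  if (any(diff(faces) <= 0)) stop("face coordinates must be strictly increasing", call. = FALSE)
  n <- length(faces) - 1L
  stopifnot(length(material) == n, all(material >= 1L))
  centers <- (faces[-1] + faces[-length(faces)]) / 2
  if (geometry == "cartesian") {
    areas <- rep(1, length(faces))         # per unit cross-section
    volumes <- diff(faces)
  } else {
    areas <- 4 * pi * faces^2
    volumes <- 4 / 3 * pi * diff(faces^3)
  }
  structure(
    list(faces = faces, centers = centers, volumes = volumes,
         face_areas = areas, material = as.integer(material),
         material_labels = labels, geometry = geometry, n = n),
    class = "grid1d"
  )
}

#' @export
print.grid1d <- function(x, ...) {
  cat(sprintf("1D %s finite-volume grid: %d cells over [%g, %g] um\n",
              x$geometry, x$n, min(x$faces), max(x$faces)))
  tb <- table(factor(x$material_labels[x$material], levels = x$material_labels))
  cat("  cells per material:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Build the phantom finite-volume grid
#'
#' Cell-centred 1D grid covering the membrane (`[-thickness, 0]`, resolved
#' by at least `membrane_cells` uniform cells) and the agarose slab
#' (`[0, L]`, geometrically graded from the membrane cell size up to
#' `dx_max`, then uniform). With `membrane = NULL` the grid is a uniform
#' slab of spacing `dx_max`.
#'
#' @param domain a [phantom_domain()].
#' @param dx_max coarsest agarose spacing, um.
#' @param membrane_cells number of cells across the membrane (>= 5 advised).
#' @param grow geometric growth factor for the graded region.
#' @return a `grid1d` with materials `membrane` (1) and `agarose` (2).
#' @export
build_phantom_grid <- function(domain, dx_max = 50, membrane_cells = 5,
                               grow = 1.2) {
  stopifnot(inherits(domain, "phantom_domain"))
  if (dx_max <= 0 || membrane_cells < 1 || grow <= 1)
    stop("degenerate grid resolution", call. = FALSE)
  L <- domain$length_mm * 1000
  if (is.null(domain$membrane)) {
    faces <- seq(0, L, by = dx_max)
    if (abs(faces[length(faces)] - L) > 1e-9) faces <- c(faces, L)
    return(.make_grid1d(faces, rep(2L, length(faces) - 1L),
                        c("membrane", "agarose")))
  }
  tm <- domain$membrane$thickness_um
  mem_faces <- seq(-tm, 0, length.out = membrane_cells + 1L)
  dx <- tm / membrane_cells
  # graded agarose: geometric growth until dx_max, then uniform
  ag_faces <- 0
  x <- 0
  while (x < L) {
    dx <- min(dx * grow, dx_max, L - x)
    x <- x + dx
    ag_faces <- c(ag_faces, x)
  }
  # merge a possibly tiny last cell into its neighbour
  nf <- length(ag_faces)
  if (nf > 2 && (ag_faces[nf] - ag_faces[nf - 1]) < 0.25 * (ag_faces[nf - 1] - ag_faces[nf - 2])) {
    ag_faces <- ag_faces[-(nf - 1)]
  }
  faces <- c(mem_faces, ag_faces[-1])
  material <- c(rep(1L, membrane_cells), rep(2L, length(ag_faces) - 1L))
  .make_grid1d(faces, material, c("membrane", "agarose"))
}

#' Build the spherical organoid grid
#'
#' Uniform 1D spherical grid from the centre to the volume-equivalent
#' radius, with a face snapped exactly to the source-shell radius. The
#' source shell is the single cell immediately outside that face.
#'
#' @param domain a [spheroid_domain()].
#' @param dr target radial spacing, um.
#' @param material_label material filling the sphere (`"organoid"` or
#'   `"agarose"` for phantom-embedding runs).
#' @return a `grid1d` (spherical) with attribute `source_cell` (index of the
#'   source-shell cell) and `source_face` (index of the snapped face).
#' @export
build_spheroid_radial_grid <- function(domain, dr = 10,
                                       material_label = "organoid") {
  stopifnot(inherits(domain, "spheroid_domain"), dr > 0)
  r_eq <- equivalent_radius(domain)
  rs <- domain$r_source_um
  if (rs >= r_eq) stop("source shell outside the domain", call. = FALSE)
  inner <- seq(0, rs, length.out = max(2L, round(rs / dr) + 1L))
  outer <- seq(rs, r_eq, length.out = max(2L, round((r_eq - rs) / dr) + 1L))
  faces <- c(inner, outer[-1])
  n <- length(faces) - 1L
  g <- .make_grid1d(faces, rep(1L, n), material_label, geometry = "spherical")
  attr(g, "source_face") <- length(inner)      # face index at r = rs
  attr(g, "source_cell") <- length(inner)      # cell just outside that face
  g
}

#' Export a grid as a data frame
#'
#' @param grid a `grid1d`.
#' @return data.frame of cell centre coordinate (um), cell measure and
#'   material label, suitable for writing as CSV.
#' @export
grid_as_data_frame <- function(grid) {
  stopifnot(inherits(grid, "grid1d"))
  data.frame(
    center_um = grid$centers,
    volume = grid$volumes,
    material = grid$material_labels[grid$material],
    stringsAsFactors = FALSE
  )
}
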