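# Seeded generators of synthetic measurements with the statistical
# structure of the platform's data: fluorescence line profiles along the
# phantom and a normalized radial MRI-intensity profile of a
# contrast-loaded organoid. Noise is fluorescence-like heteroscedastic:
# multiplicative plus additive relative to the peak signal.

.apply_noise <- function(clean, noise, seed) {
  noise <- rep_len(noise, 2)
  if (any(noise < 0)) stop("noise fractions must be >= 0", call. = FALSE)
  set.seed(seed)
  n <- length(clean)
  clean * (1 + noise[1] * stats::rnorm(n)) +
    noise[2] * max(abs(clean)) * stats::rnorm(n)
}

.make_synth <- function(data, clean, manifest, seed) {
  manifest$seed <- seed
  manifest$package_version <- as.character(utils::packageVersion("organoflux"))
  structure(list(data = data, clean = clean, manifest = manifest, seed = seed),
            class = "synthetic_profiles")
}

#' @export
print.synthetic_profiles <- function(x, ...) {
  cat(sprintf("Synthetic %s: %d observations, seed %d\n",
              x$manifest$generator, nrow(x$data), x$seed))
  cat(sprintf("  noise: %.3g multiplicative + %.3g of peak additive\n",
              x$manifest$noise[1], x$manifest$noise[2]))
  invisible(x)
}

#' Generate synthetic phantom fluorescence line profiles
#'
#' Forward phantom diffusion solve sampled on a line along the phantom,
#' emulating time-lapse fluorescence line profiles: 11 times from 0 to
#' 400 min every 40 min and positions every 50 um along the 5 mm phantom
#' by default, corrupted by multiplicative plus additive Gaussian noise.
#' The noiseless channel is stored alongside the noisy values, and the
#' dataset regenerates bit-identically from its manifest and seed
#' (see [synthetic_regenerate()]).
#'
#' @param s0,ks generating (truth) saturation parameters.
#' @param sol a [solute()]; defaults to sulforhodamine B at 10 uM.
#' @param materials,domain forward-model setup.
#' @param times sampling times, s.
#' @param x sampling positions, um; overrides `x_step`.
#' @param x_step position spacing, um (default 50, from 0 to the phantom
#'   length).
#' @param noise `c(multiplicative, additive)` noise fractions; the additive
#'   term is scaled by the peak clean signal.
#' @param seed integer seed governing all draws.
#' @param dx_max,membrane_cells,rtol forward-model resolution.
#' @return an object of class `synthetic_profiles` with `data`
#'   (data.frame `time`, `x`, `value`), the noiseless `clean` channel and
#'   a provenance `manifest`.
#' @export
generate_phantom_profiles <- function(s0 = 0.075, ks = 3.7e-5,
                                      sol = default_solutes()$srb,
                                      materials = default_materials(),
                                      domain = phantom_domain(),
                                      times = seq(0, 400 * 60, by = 40 * 60),
                                      x = NULL, x_step = 50,
                                      noise = c(0.01, 0.005), seed = 1,
                                      dx_max = 50, membrane_cells = 5,
                                      rtol = 1e-7) {
  if (is.null(x)) x <- seq(0, domain$length_mm * 1000, by = x_step)
  obs <- expand.grid(x = x, time = times)[, c("time", "x")]
  s0 <- unname(s0); ks <- unname(ks)
  clean <- .forward_predict(c(s0 = s0, ks = ks), obs, sol, NULL, materials,
                            domain, dx_max, membrane_cells, rtol)
  value <- .apply_noise(clean, noise, seed)
  data <- data.frame(time = obs$time, x = obs$x, value = value)
  manifest <- list(
    generator = "phantom_profiles",
    truth = list(s0 = s0, ks = ks),
    solute = list(name = sol$name, diffusivity = sol$diffusivity,
                  c_source = sol$c_source),
    domain = list(length_mm = domain$length_mm,
                  membrane_thickness_um =
                    if (is.null(domain$membrane)) NULL
                    else domain$membrane$thickness_um),
    times = times, x = x, noise = rep_len(noise, 2),
    dx_max = dx_max, membrane_cells = membrane_cells, rtol = rtol
  )
  .make_synth(data, clean, manifest, seed)
}

#' Generate a synthetic radial MRI-intensity profile
#'
#' Radial organoid delivery solve at the requested time, normalized by the
#' source concentration, mapped through a monotone (affine by default)
#' intensity mapping and corrupted with noise, emulating a gray-scale
#' MRI line profile of a contrast-loaded organoid.
#'
#' @param sol a [solute()]; defaults to the MRI contrast agent.
#' @param domain a [spheroid_domain()].
#' @param material tissue [porous_material()].
#' @param time acquisition time, s (default 1 h of delivery).
#' @param dr radial grid spacing, um.
#' @param mapping `c(gain, offset)` of the affine intensity mapping applied
#'   to the normalized concentration; the gain must be non-negative
#'   (monotone mapping).
#' @param noise `c(multiplicative, additive)` noise fractions.
#' @param seed integer seed.
#' @param advection optional `darcy_field`.
#' @param ... passed to [solve_organoid_radial()].
#' @return a `synthetic_profiles` object with `data` columns `r`
#'   (radius, um) and `value` (intensity).
#' @export
generate_radial_mri_profile <- function(sol = default_solutes()$magnevist,
                                        domain = spheroid_domain(),
                                        material = default_materials()$organoid,
                                        time = 3600, dr = 10,
                                        mapping = c(gain = 1, offset = 0),
                                        noise = c(0.01, 0.005), seed = 1,
                                        advection = NULL, ...) {
  if (mapping[1] < 0)
    stop("intensity mapping must be monotone (non-negative gain)", call. = FALSE)
  res <- solve_organoid_radial(sol = sol, domain = domain, material = material,
                               times = sort(unique(c(0, time))), dr = dr,
                               advection = advection, track_fluxes = FALSE,
                               ...)
  prof <- profile_at(res, res$x, time)[1, ]
  cnorm <- normalize_profile(prof, sol$c_source)
  clean <- mapping[2] + mapping[1] * cnorm
  value <- .apply_noise(clean, noise, seed)
  data <- data.frame(r = res$x, value = value)
  manifest <- list(
    generator = "radial_mri_profile",
    solute = list(name = sol$name, diffusivity = sol$diffusivity,
                  c_source = sol$c_source),
    domain = list(r0_mm = domain$r0_mm, r0z_mm = domain$r0z_mm,
                  r_source_um = domain$r_source_um,
                  outer_bc = domain$outer_bc),
    material = material$name, time = time, dr = dr,
    mapping = unname(mapping), noise = rep_len(noise, 2)
  )
  .make_synth(data, clean, manifest, seed)
}

#' Regenerate a synthetic dataset from its manifest
#'
#' Reconstructs a [generate_phantom_profiles()] dataset bit-identically
#' from the provenance manifest and seed stored in the object.
#'
#' @param x a `synthetic_profiles` object (or its manifest plus a seed).
#' @param seed seed override; default the recorded seed.
#' @return a new `synthetic_profiles` object.
#' @export
synthetic_regenerate <- function(x, seed = NULL) {
  m <- if (inherits(x, "synthetic_profiles")) x$manifest else x
  if (is.null(seed)) seed <- m$seed
  if (m$generator == "phantom_profiles") {
    sol <- solute(m$solute$name, m$solute$diffusivity, m$solute$c_source)
    generate_phantom_profiles(
      s0 = m$truth$s0, ks = m$truth$ks, sol = sol,
      domain = phantom_domain(length_mm = m$domain$length_mm),
      times = m$times, x = m$x, noise = m$noise, seed = seed,
      dx_max = m$dx_max, membrane_cells = m$membrane_cells, rtol = m$rtol)
  } else if (m$generator == "radial_mri_profile") {
    sol <- solute(m$solute$name, m$solute$diffusivity, m$solute$c_source)
    generate_radial_mri_profile(
      sol = sol,
      domain = spheroid_domain(m$domain$r0_mm, m$domain$r0z_mm,
                               m$domain$r_source_um, m$domain$outer_bc),
      time = m$time, dr = m$dr, mapping = m$mapping, noise = m$noise,
      seed = seed)
  } else stop("unknown generator: ", m$generator, call. = FALSE)
}
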