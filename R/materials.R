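# Physical constants and constitutive laws shared by all solvers:
# porous materials, working fluid, solutes, and the membrane saturation law.

#' Define a porous material
#'
#' @param name label, e.g. `"membrane"`, `"organoid"`, `"agarose"`.
#' @param porosity volume fraction of connected pore space, in (0, 1].
#' @param permeability Darcy permeability, by default in m^2 (the unit in
#'   which such values are usually tabulated); stored internally in um^2.
#' @param tortuosity dimensionless path-length factor, >= 1. The transport
#'   model uses a tortuosity of 1 throughout by default.
#' @param permeability_unit unit of `permeability` (`"m^2"` or `"um^2"`).
#' @return an object of class `porous_material`.
#' @examples
#' porous_material("membrane", porosity = 0.094, permeability = 1.2e-16)
#' @export
porous_material <- function(name, porosity, permeability,
                            tortuosity = 1, permeability_unit = "m^2") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(porosity) || porosity <= 0 || porosity > 1)
    stop("porosity must lie in (0, 1]", call. = FALSE)
  k <- convert_units(permeability, permeability_unit, "um^2")
  if (!is.numeric(k) || k <= 0)
    stop("permeability must be positive", call. = FALSE)
  if (!is.numeric(tortuosity) || tortuosity < 1)
    stop("tortuosity must be >= 1", call. = FALSE)
  structure(
    list(name = name, porosity = porosity, permeability = k,
         tortuosity = tortuosity),
    class = "porous_material"
  )
}

#' @export
print.porous_material <- function(x, ...) {
  cat(sprintf("Porous material '%s': porosity %.3g, permeability %.3g um^2, tortuosity %.3g\n",
              x$name, x$porosity, x$permeability, x$tortuosity))
  invisible(x)
}

#' Define a Newtonian working fluid
#'
#' Defaults are liquid water at room temperature.
#'
#' @param density mass density in kg/m^3.
#' @param viscosity dynamic viscosity in Pa.s.
#' @return an object of class `fluid`.
#' @export
fluid <- function(density = 997, viscosity = 0.0010016) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity), class = "fluid")
}

#' @export
print.fluid <- function(x, ...) {
  cat(sprintf("Fluid: density %g kg/m^3, viscosity %g Pa.s\n",
              x$density, x$viscosity))
  invisible(x)
}

#' Define a solute
#'
#' @param name label, e.g. `"magnevist"`, `"srb"`, `"iohexol"`.
#' @param diffusivity free diffusivity in water, um^2/s.
#' @param c_source source (channel reservoir) concentration.
#' @param c_unit unit of `c_source`; stored internally in uM.
#' @return an object of class `solute`.
#' @examples
#' solute("srb", diffusivity = 470, c_source = 10, c_unit = "uM")
#' @export
solute <- function(name, diffusivity, c_source = 0, c_unit = "uM") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(diffusivity) || diffusivity <= 0)
    stop("diffusivity must be positive", call. = FALSE)
  cs <- convert_units(c_source, c_unit, "uM")
  if (cs < 0) stop("source concentration must be non-negative", call. = FALSE)
  structure(
    list(name = name, diffusivity = diffusivity, c_source = cs),
    class = "solute"
  )
}

#' @export
print.solute <- function(x, ...) {
  cat(sprintf("Solute '%s': D = %g um^2/s, source concentration %g uM\n",
              x$name, x$diffusivity, x$c_source))
  invisible(x)
}

#' Membrane saturation law
#'
#' The nanoporous membrane wets gradually after flow starts; its liquid
#' saturation is modelled as linear in time, `s(t) = s0 + ks * t`, capped at
#' full saturation 1 (the linear form is unbounded; physical saturation
#' cannot exceed 1). Effective diffusivity through the membrane scales with
#' `s(t)`, so solute exchange ramps up until the pores are fully wetted.
#'
#' @param s0 initial saturation, in [0, 1].
#' @param ks rate of saturation increase, 1/s, >= 0.
#' @return an object of class `saturation_model`.
#' @examples
#' m <- saturation_model(s0 = 0.075, ks = 3.7e-5)
#' saturation_at(m, c(0, 12500, 25000, 40000))
#' @export
saturation_model <- function(s0 = 0.075, ks = 3.7e-5) {
  if (!is.numeric(s0) || s0 < 0 || s0 > 1)
    stop("s0 must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(ks) || ks < 0)
    stop("ks must be >= 0", call. = FALSE)
  structure(list(s0 = s0, ks = ks, cap = 1), class = "saturation_model")
}

#' @export
print.saturation_model <- function(x, ...) {
  cat(sprintf("Saturation law s(t) = min(%g + %g t, 1)", x$s0, x$ks))
  if (x$ks > 0)
    cat(sprintf("  [fully saturated at t = %.5g s]", saturation_crossover(x)))
  cat("\n")
  invisible(x)
}

#' Evaluate the saturation law
#'
#' @param model a [saturation_model()].
#' @param t time in seconds, vectorised; must be non-negative.
#' @return saturation in [s0, 1], non-decreasing in `t`.
#' @export
saturation_at <- function(model, t) {
  stopifnot(inherits(model, "saturation_model"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  pmin(model$s0 + model$ks * t, model$cap)
}

#' Time at which the membrane becomes fully saturated
#'
#' @param model a [saturation_model()].
#' @return crossover time `(1 - s0) / ks` in seconds (`Inf` when `ks = 0`
#'   and `s0 < 1`; 0 when `s0 = 1`).
#' @export
saturation_crossover <- function(model) {
  stopifnot(inherits(model, "saturation_model"))
  if (model$s0 >= 1) return(0)
  if (model$ks == 0) return(Inf)
  (1 - model$s0) / model$ks
}

#' Effective diffusivity in a porous medium
#'
#' `D_eff = s * porosity * D / tortuosity`. Fully saturated domains use
#' `s = 1`; the nanoporous membrane uses the time-dependent saturation from
#' [saturation_at()]. The effective diffusivity never exceeds the free
#' diffusivity.
#'
#' @param solute a [solute()] or a bare free diffusivity in um^2/s.
#' @param material a [porous_material()].
#' @param s saturation in [0, 1]; vectorised.
#' @return effective diffusivity in um^2/s.
#' @examples
#' pete <- porous_material("membrane", 0.094, 1.2e-16)
#' effective_diffusivity(450, pete)  # contrast agent through wetted membrane
#' @export
effective_diffusivity <- function(solute, material, s = 1) {
  D <- if (inherits(solute, "solute")) solute$diffusivity else solute
  stopifnot(is.numeric(D), all(D > 0), inherits(material, "porous_material"))
  if (any(s < 0 | s > 1)) stop("saturation must lie in [0, 1]", call. = FALSE)
  s * material$porosity * D / material$tortuosity
}

.constants_cache <- new.env(parent = emptyenv())

#' Built-in physical constants
#'
#' Reads the packaged constants table (a YAML file under `extdata`) holding
#' the material porosities and permeabilities, fluid properties, solute
#' diffusivities and source concentrations, device geometry and pressure
#' presets used throughout. Any entry can be overridden per run.
#'
#' @param overrides optional named list merged over the built-in table
#'   (nested lists merge recursively), or a path to a YAML file of overrides.
#' @return nested list of constants.
#' @export
of_constants <- function(overrides = NULL) {
  if (is.null(.constants_cache$base)) {
    path <- system.file("extdata", "constants.yaml", package = "organoflux")
    .constants_cache$base <- yaml::read_yaml(path)
  }
  out <- .constants_cache$base
  if (!is.null(overrides)) {
    if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
    out <- .merge_lists(out, overrides)
  }
  out
}

.merge_lists <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_lists(base[[nm]], over[[nm]])
    else
      base[[nm]] <- over[[nm]]
  }
  base
}

#' Default materials, fluid and solutes
#'
#' Convenience constructors around [of_constants()].
#'
#' @param constants constants list from [of_constants()].
#' @return `default_materials()`: named list of [porous_material()] for the
#'   nanoporous membrane, organoid tissue and agarose; `default_fluid()`: the
#'   water [fluid()]; `default_solutes()`: named list of [solute()] for the
#'   MRI contrast agent (Magnevist), the fluorescent dye (sulforhodamine B)
#'   and the CT contrast agent (iohexol).
#' @export
default_materials <- function(constants = of_constants()) {
  m <- constants$materials
  lapply(setNames(names(m), names(m)), function(nm) {
    porous_material(nm, porosity = m[[nm]]$porosity,
                    permeability = m[[nm]]$permeability_m2,
                    tortuosity = if (is.null(m[[nm]]$tortuosity)) 1 else m[[nm]]$tortuosity,
                    permeability_unit = "m^2")
  })
}

#' @rdname default_materials
#' @export
default_fluid <- function(constants = of_constants()) {
  fluid(density = constants$fluid$density_kg_m3,
        viscosity = constants$fluid$viscosity_Pa_s)
}

#' @rdname default_materials
#' @export
default_solutes <- function(constants = of_constants()) {
  s <- constants$solutes
  lapply(setNames(names(s), names(s)), function(nm) {
    solute(nm, diffusivity = s[[nm]]$diffusivity_um2_s,
           c_source = s[[nm]]$c_source_uM, c_unit = "uM")
  })
}

#' Default membrane saturation law
#'
#' @param constants constants list from [of_constants()].
#' @return a [saturation_model()] with the packaged defaults.
#' @export
default_saturation <- function(constants = of_constants()) {
  saturation_model(s0 = constants$saturation$s0, ks = constants$saturation$ks)
}
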