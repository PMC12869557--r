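# Internal unit system: micrometre, second, micromolar, pascal.
# Constants are converted on load so solver matrices avoid 1e-15-scale entries.

.unit_table <- local({
  # scale factor to the base unit of each dimension
  tab <- list(
    length        = c("m" = 1e6, "mm" = 1e3, "um" = 1, "nm" = 1e-3),
    area          = c("m^2" = 1e12, "mm^2" = 1e6, "um^2" = 1),
    pressure      = c("Pa" = 1, "kPa" = 1e3),
    density       = c("kg/m^3" = 1),
    viscosity     = c("Pa*s" = 1),
    concentration = c("M" = 1e6, "mM" = 1e3, "uM" = 1, "nM" = 1e-3),
    time          = c("s" = 1, "min" = 60, "h" = 3600)
  )
  tab
})

.unit_aliases <- c(
  "μm" = "um", "µm" = "um",
  "μm^2" = "um^2", "µm^2" = "um^2",
  "m2" = "m^2", "um2" = "um^2", "mm2" = "mm^2",
  "μM" = "uM", "µM" = "uM",
  "Pa.s" = "Pa*s", "Pa s" = "Pa*s"
)

.canon_unit <- function(u) {
  u <- as.character(u)
  if (u %in% names(.unit_aliases)) .unit_aliases[[u]] else u
}

.unit_dim <- function(u) {
  for (d in names(.unit_table)) if (u %in% names(.unit_table[[d]])) return(d)
  stop("unsupported unit: '", u, "'", call. = FALSE)
}

#' Convert a value between supported physical units
#'
#' Exact scale-factor conversion within one physical dimension (length, area,
#' pressure, density, dynamic viscosity, molar concentration, time). The
#' package works internally in micrometres, seconds, micromolar and pascals;
#' this helper converts printed constants (for example permeabilities in m^2)
#' into that system and back.
#'
#' @param x numeric vector of values.
#' @param from,to unit names, e.g. `"m^2"`, `"um^2"`, `"mM"`, `"uM"`, `"h"`.
#'   Micro-prefixed spellings with a Greek mu are accepted.
#' @return `x` rescaled; round trips are exact to machine precision.
#' @examples
#' convert_units(3.75e-15, "m^2", "um^2")  # 3.75e-3
#' convert_units(5.6, "mM", "uM")          # 5600
#' @export
convert_units <- function(x, from, to) {
  from <- .canon_unit(from)
  to <- .canon_unit(to)
  if (identical(from, to)) return(x)
  df <- .unit_dim(from)
  dt <- .unit_dim(to)
  if (!identical(df, dt)) {
    stop("cannot convert '", from, "' (", df, ") to '", to, "' (", dt, ")",
         call. = FALSE)
  }
  tab <- .unit_table[[df]]
  x * (tab[[from]] / tab[[to]])
}
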