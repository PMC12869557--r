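# Run configuration, presets, manifests and file I/O shared by all stages,
# plus the driver behind the command-line entry point (inst/exec/organoflux).

#' Read a run configuration file
#'
#' YAML configuration merged over the packaged constants table, so a config
#' file only needs to state what it overrides. Dotted-path overrides
#' (`"a.b.c=value"`) are applied last.
#'
#' @param path YAML file path, or `NULL` for the built-in defaults.
#' @param overrides character vector of `"dotted.path=value"` assignments.
#' @return resolved constants list (see [of_constants()]).
#' @export
read_run_config <- function(path = NULL, overrides = character(0)) {
  if (!is.null(path) && !file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- of_constants(path)
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad override (want key.path=value): ", ov,
                              call. = FALSE)
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    node <- cfg
    for (i in seq_along(keys[-length(keys)])) {
      if (is.null(node[[keys[i]]]))
        stop("unknown key '", kv[1], "'; top-level keys: ",
             paste(names(cfg), collapse = ", "), call. = FALSE)
      node <- node[[keys[i]]]
    }
    val <- suppressWarnings(as.numeric(kv[2]))
    if (is.na(val)) val <- kv[2]
    cfg[[keys]] <- val
  }
  cfg
}

#' Delivery experiment presets
#'
#' Named presets for the three delivery experiments: `magnevist-organoid`
#' (690 Pa, 5.6 mM contrast into the organoid), `srb-phantom` (510 Pa,
#' 10 uM dye into the agarose phantom) and `iohexol-agarose` (196 Pa,
#' 300 mg/mL iohexol, i.e. 365.3 mM at 821.14 g/mol, into agarose).
#'
#' @param name preset name.
#' @param constants constants list from [of_constants()].
#' @return list with the solute, driving pressure and experiment kind.
#' @export
preset_config <- function(name = c("srb-phantom", "magnevist-organoid",
                                   "iohexol-agarose"),
                          constants = of_constants()) {
  name <- match.arg(name)
  sols <- default_solutes(constants)
  switch(name,
    "srb-phantom" = list(
      kind = "phantom", solute = sols$srb,
      pressure_Pa = constants$pressures_Pa$srb),
    "magnevist-organoid" = list(
      kind = "organoid", solute = sols$magnevist,
      pressure_Pa = constants$pressures_Pa$magnevist),
    "iohexol-agarose" = list(
      kind = "agarose_embedding", solute = sols$iohexol,
      pressure_Pa = constants$pressures_Pa$iohexol)
  )
}

#' Build a run manifest
#'
#' Captures everything needed to re-run a stage: the resolved parameters,
#' package version, seed and timestamp.
#'
#' @param stage stage name.
#' @param params resolved parameter list.
#' @param seed seed used (or `NA` for deterministic stages).
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(stage, params, seed = NA_integer_) {
  structure(
    list(stage = stage,
         package = "organoflux",
         version = as.character(utils::packageVersion("organoflux")),
         seed = seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         params = params),
    class = "run_manifest"
  )
}

#' Write a manifest as JSON
#'
#' @param manifest a [run_manifest()] (or any list).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a transport result as tidy CSV
#'
#' Long format: one row per (time, position) with the concentration, ready
#' for the calibration stage.
#'
#' @param result a `transport_result` or `synthetic_profiles`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(result, path) {
  df <- if (inherits(result, "synthetic_profiles")) {
    result$data
  } else if (inherits(result, "transport_result")) {
    data.frame(
      time = rep(result$times, each = length(result$x)),
      x = rep(result$x, length(result$times)),
      value = as.vector(t(result$conc))
    )
  } else stop("unsupported object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a profiles CSV
#'
#' @param path CSV with columns `time`, `x` (or `r`), `value`.
#' @return data.frame with columns `time`, `x`, `value`.
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path)
  if ("r" %in% names(df) && !("x" %in% names(df))) names(df)[names(df) == "r"] <- "x"
  need <- c("x", "value")
  if (!all(need %in% names(df)))
    stop("profiles CSV needs columns time, x, value", call. = FALSE)
  df
}

#' Execute a pipeline stage
#'
#' Driver behind the `organoflux` command-line script. Outputs land in
#' `out_dir` together with a JSON manifest of the resolved parameters; on
#' error, partial outputs are removed.
#'
#' @param command one of `hydraulics`, `simulate-phantom`,
#'   `simulate-organoid`, `metrics`, `fit`, `synth`.
#' @param config path to a YAML config file (optional).
#' @param overrides character vector of dotted-path overrides.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for stochastic stages.
#' @param input input CSV path (for `metrics` and `fit`).
#' @return named list of output file paths, invisibly.
#' @export
run_stage <- function(command = c("hydraulics", "simulate-phantom",
                                  "simulate-organoid", "metrics", "fit",
                                  "synth"),
                      config = NULL, overrides = character(0),
                      out_dir = "organoflux-run", seed = 1, input = NULL) {
  command <- match.arg(command)
  cfg <- read_run_config(config, overrides)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("stage '", command, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  out <- tryCatch({
    outputs <- list()
    mats <- default_materials(cfg)
    satm <- default_saturation(cfg)
    if (command == "hydraulics") {
      sw <- hydraulics_sweep(unlist(cfg$pressures_Pa),
                             fl = default_fluid(cfg))
      p <- file.path(out_dir, "hydraulics.csv")
      utils::write.csv(sw, p, row.names = FALSE)
      written <- c(written, p); outputs$csv <- p
    } else if (command == "simulate-phantom") {
      res <- solve_phantom(sol = default_solutes(cfg)$srb, saturation = satm,
                           materials = mats)
      p <- file.path(out_dir, "phantom_profiles.csv")
      write_profiles_csv(res, p)
      written <- c(written, p); outputs$csv <- p
    } else if (command == "simulate-organoid") {
      res <- solve_organoid_radial(sol = default_solutes(cfg)$magnevist,
                                   material = mats$organoid)
      p <- file.path(out_dir, "organoid_profiles.csv")
      write_profiles_csv(res, p)
      written <- c(written, p); outputs$csv <- p
    } else if (command == "metrics") {
      if (is.null(input)) stop("metrics needs --input profiles CSV")
      res <- solve_phantom(sol = default_solutes(cfg)$srb, saturation = satm,
                           materials = mats,
                           times = seq(0, 43200, by = 600))
      ss <- steady_state_time(res)
      fx <- interface_flux(res)
      rep <- list(steady_state_h = ss$time_h,
                  flux_avg_to_steady = fx$average_to_steady,
                  flux_steady = fx$steady_value,
                  flux_whole_run = fx$whole_run_average,
                  penetration_depth_um_1h =
                    penetration_depth_at(res, 3600))
      p <- file.path(out_dir, "metrics.json")
      jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA)
      written <- c(written, p); outputs$json <- p
    } else if (command == "fit") {
      if (is.null(input)) stop("fit needs --input observations CSV")
      obs <- read_profiles_csv(input)
      fit <- fit_saturation(obs, sol = default_solutes(cfg)$srb,
                            materials = mats, seed = seed)
      p <- file.path(out_dir, "fit.json")
      jsonlite::write_json(
        list(estimates = as.list(coef(fit)),
             std_errors = as.list(sqrt(diag(vcov(fit)))),
             loss = fit$loss, convergence = fit$convergence),
        p, auto_unbox = TRUE, digits = NA)
      written <- c(written, p); outputs$json <- p
    } else if (command == "synth") {
      synth <- generate_phantom_profiles(
        s0 = cfg$saturation$s0, ks = cfg$saturation$ks,
        sol = default_solutes(cfg)$srb, materials = mats, seed = seed)
      p <- file.path(out_dir, "synthetic_profiles.csv")
      write_profiles_csv(synth, p)
      written <- c(written, p); outputs$csv <- p
      pm <- file.path(out_dir, "synthetic_manifest.json")
      write_manifest(run_manifest("synth", synth$manifest, seed), pm)
      written <- c(written, pm); outputs$manifest <- pm
    }
    mp <- file.path(out_dir, paste0(command, "_manifest.json"))
    write_manifest(run_manifest(command, cfg, seed), mp)
    outputs$run_manifest <- mp
    outputs
  }, error = on_fail)
  invisible(out)
}
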