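#' Configuration files and time-series serialization
#'
#' One structured YAML config dialect; all physical quantities carry unit
#' suffixes in their key names (`diameter_nm`, `k_c_um_h`, ...) so unit
#' mistakes are visible at the key level. Trajectories and datasets are
#' exchanged as tidy CSV at full double precision.
#'
#' @name io
NULL

known_keys <- list(
  top = c("geometry", "cell", "enzymes", "permeabilities", "initial",
          "growth", "solver", "scenarios", "seed"),
  geometry = c("shape", "diameter_nm", "length_um", "count", "match_mode",
               "include_end_area"),
  cell = c("capsule_radius_um", "cell_length_um"),
  enzyme = c("vmax_fwd", "km_fwd", "vmax_rev", "km_rev"),
  permeabilities = c("k_c_um_h", "k_m_um_h", "end_permeability_multiplier"),
  initial = c("external_PDO_mM"),
  growth = c("file", "n0_cells_ml", "lag_h", "td_early_h", "t_switch_h",
             "td_late_h"),
  solver = c("rtol", "atol", "output_dt", "t_end_h"))

reject_unknown <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra)) {
    stop(sprintf("config error at '%s': unknown key(s) %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML config, validates it against the documented schema
#' (unknown keys are rejected with the offending location), fills defaults
#' for everything omitted, and returns resolved model objects. The base-case
#' defaults are 15 spheres of 140 nm diameter, 55 mM initial external
#' 1,2-propanediol, and the calibrated kinetic defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list: `params` (a `pdu_params`), `growth` (a
#'   `growth_curve`), `solver` options, `scenarios`, `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  reject_unknown(cfg, known_keys$top, "top level")

  geom_cfg <- cfg$geometry %||% list()
  reject_unknown(geom_cfg, known_keys$geometry, "geometry")
  shape <- geom_cfg$shape %||% "sphere"
  if (!shape %in% c("sphere", "cylinder")) {
    stop("config error at 'geometry.shape': must be sphere or cylinder",
         call. = FALSE)
  }
  cell_cfg <- cfg$cell %||% list()
  reject_unknown(cell_cfg, known_keys$cell, "cell")
  cell <- cell_geometry(cell_cfg$capsule_radius_um %||% 0.5,
                        cell_cfg$cell_length_um %||% 2.5)
  geom <- if (shape == "sphere") {
    make_sphere(geom_cfg$diameter_nm %||% 140)
  } else {
    make_cylinder(geom_cfg$diameter_nm %||% 50,
                  (geom_cfg$length_um %||% cell$cell_length_um) * NM_PER_UM,
                  isTRUE(geom_cfg$include_end_area))
  }
  base_ens <- compartment_ensemble(make_sphere(140), 15)
  ens <- if (!is.null(geom_cfg$match_mode)) {
    match_ensemble(base_ens, geom, geom_cfg$match_mode,
                   count = geom_cfg$count)
  } else {
    compartment_ensemble(geom, geom_cfg$count %||% 15)
  }

  enz <- default_enzymes()
  enz_cfg <- cfg$enzymes %||% list()
  reject_unknown(enz_cfg, names(enz), "enzymes")
  for (e in names(enz_cfg)) {
    reject_unknown(enz_cfg[[e]], known_keys$enzyme, paste0("enzymes.", e))
    cur <- enz[[e]]
    enz[[e]] <- enzyme_kinetics(
      e,
      enz_cfg[[e]]$vmax_fwd %||% cur$vmax_fwd,
      enz_cfg[[e]]$km_fwd %||% cur$km_fwd,
      enz_cfg[[e]]$vmax_rev %||% cur$vmax_rev,
      enz_cfg[[e]]$km_rev %||% cur$km_rev)
  }

  perm <- cfg$permeabilities %||% list()
  reject_unknown(perm, known_keys$permeabilities, "permeabilities")
  for (k in names(perm)) {
    if (!is.numeric(perm[[k]]) || perm[[k]] < 0) {
      stop("config error at 'permeabilities.", k, "': must be >= 0",
           call. = FALSE)
    }
  }
  init <- cfg$initial %||% list()
  reject_unknown(init, known_keys$initial, "initial")

  params <- pdu_model_parameters(
    compartments = ens, cell = cell, enzymes = enz,
    k_c_um_h = perm$k_c_um_h %||% 5000,
    end_permeability_multiplier = perm$end_permeability_multiplier %||% 0,
    k_m_um_h = perm$k_m_um_h %||% 3600,
    initial_external_PDO_mM = init$external_PDO_mM %||% 55)

  gr_cfg <- cfg$growth %||% list()
  reject_unknown(gr_cfg, known_keys$growth, "growth")
  growth <- if (!is.null(gr_cfg$file)) {
    d <- utils::read.csv(gr_cfg$file)
    if (!all(c("time_h", "density_cells_ml") %in% names(d))) {
      stop("growth file needs columns time_h, density_cells_ml",
           call. = FALSE)
    }
    growth_curve(d$time_h, d$density_cells_ml)
  } else {
    generate_growth_curve(growth_model(
      n0_cells_ml = gr_cfg$n0_cells_ml %||% 5e7,
      lag_h = gr_cfg$lag_h %||% 1,
      td_early_h = gr_cfg$td_early_h %||% 3.17,
      t_switch_h = gr_cfg$t_switch_h %||% 12,
      td_late_h = gr_cfg$td_late_h %||% 9.2))
  }

  solver <- cfg$solver %||% list()
  reject_unknown(solver, known_keys$solver, "solver")
  scen <- cfg$scenarios %||% "base"
  allowed_scen <- c("base", "equal_volume", "equal_area", "wellmixed",
                    "open_ends")
  if (!all(scen %in% allowed_scen)) {
    stop("config error at 'scenarios': allowed values are ",
         paste(allowed_scen, collapse = ", "), call. = FALSE)
  }
  structure(list(params = params, growth = growth,
                 solver = list(rtol = solver$rtol %||% 1e-8,
                               atol = solver$atol %||% 1e-10,
                               output_dt = solver$output_dt %||% 0.1,
                               t_end_h = solver$t_end_h %||% 30),
                 scenarios = scen, seed = cfg$seed %||% 1L),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tidy time-series table to CSV at full precision
#'
#' Accepts a `pdu_sim`, a `synthetic_dataset` (its measurement table), or a
#' tidy data frame. Numeric columns are written with 17 significant digits
#' so that `read_timeseries(write_timeseries(x))` is the identity on values.
#'
#' @param x Object to serialize.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  d <- if (inherits(x, "pdu_sim")) as.data.frame(x)
       else if (inherits(x, "synthetic_dataset")) x$measurements
       else as.data.frame(x)
  out <- d
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy time-series CSV
#'
#' @param path CSV path written by [write_timeseries()] (or any CSV with a
#'   `time_h` column and a numeric `concentration_mM` column).
#' @return Data frame with numeric columns restored.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_h" %in% names(d)) {
    stop("malformed time-series file (no time_h column): ", path,
         call. = FALSE)
  }
  for (j in names(d)) {
    if (j %in% c("time_h", "concentration_mM", "replicate",
                 "density_cells_ml")) {
      v <- suppressWarnings(as.numeric(d[[j]]))
      bad <- which(is.na(v) & !is.na(d[[j]]) & nzchar(d[[j]]))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at data line %d of %s",
                     j, bad[1], path), call. = FALSE)
      }
      d[[j]] <- v
    }
  }
  d
}

#' Resolved default-parameter manifest
#'
#' Reads the machine-readable manifest shipped with the package listing
#' every model symbol with its default value, unit, and provenance
#' (printed model dimension, literature-informed magnitude, calibrated
#' value, or design default).
#'
#' @return Data frame with columns `symbol`, `value`, `unit`, `provenance`,
#'   `description`.
#' @export
default_parameter_manifest <- function() {
  path <- system.file("extdata", "default_parameters.yaml",
                      package = "pdukinetics")
  m <- yaml::read_yaml(path)
  do.call(rbind, lapply(m, function(r) {
    data.frame(symbol = r$symbol, value = as.numeric(r$value), unit = r$unit,
               provenance = r$provenance, description = r$description,
               stringsAsFactors = FALSE)
  }))
}
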