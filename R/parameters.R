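#' Model parameters
#'
#' The full parameter set for the three-region Pdu pathway model: compartment
#' ensemble, cell geometry, Michaelis-Menten kinetics for the four enzymatic
#' steps, shell and membrane permeabilities, and the initial condition.
#'
#' Units throughout: concentrations mM, time h, lengths um, permeabilities
#' um/h. Maximal rates are referred to the volume of the region in which the
#' enzyme acts (compartment lumen for PduCDE/PduP/PduQ, cytosol for the
#' lumped PduL/PduW step).
#'
#' @name parameters
NULL

SPECIES <- c("PDO", "PALD", "PCOA", "POH", "PROP")
REGIONS <- c("lumen", "cytosol", "external")

#' Michaelis-Menten kinetics of one enzymatic step
#'
#' @param name Enzyme label, one of `"PduCDE"`, `"PduP"`, `"PduQ"`, `"PduLW"`.
#' @param vmax_fwd Forward maximal rate, mM/h referred to the acting region's
#'   volume; nonnegative (0 switches the step off, e.g. for transport-only
#'   limits).
#' @param km_fwd Forward Michaelis constant, mM; must be positive.
#' @param vmax_rev Reverse maximal rate, mM/h; 0 for an irreversible step.
#'   PduCDE and the lumped PduL/PduW step are irreversible.
#' @param km_rev Reverse Michaelis constant, mM; required positive when
#'   `vmax_rev > 0`.
#' @return An `enzyme_kinetics` object.
#' @export
enzyme_kinetics <- function(name, vmax_fwd, km_fwd, vmax_rev = 0, km_rev = 1) {
  name <- match.arg(name, c("PduCDE", "PduP", "PduQ", "PduLW"))
  stopifnot(is.numeric(vmax_fwd), is.numeric(km_fwd),
            is.numeric(vmax_rev), is.numeric(km_rev))
  if (vmax_fwd < 0 || km_fwd <= 0) {
    stop(name, ": vmax_fwd must be >= 0 and km_fwd > 0", call. = FALSE)
  }
  if (vmax_rev < 0) stop(name, ": vmax_rev must be >= 0", call. = FALSE)
  if (vmax_rev > 0 && km_rev <= 0) {
    stop(name, ": km_rev must be positive when the step is reversible",
         call. = FALSE)
  }
  if (name %in% c("PduCDE", "PduLW") && vmax_rev > 0) {
    stop(name, " is irreversible in this model (vmax_rev must be 0)",
         call. = FALSE)
  }
  structure(list(name = name, vmax_fwd = vmax_fwd, km_fwd = km_fwd,
                 vmax_rev = vmax_rev, km_rev = km_rev),
            class = "enzyme_kinetics")
}

#' Default enzyme kinetics
#'
#' Effective lumped kinetics for the four modeled steps. PduCDE magnitude
#' follows diol-dehydratase turnover at lumen-scale enzyme concentrations;
#' PduP/PduQ maximal rates are the calibrated values that reproduce the
#' observed propionaldehyde timescales and peak (see the methods vignette);
#' the cytosolic PduL/PduW step is strongly capacity-limited, which sets the
#' delayed appearance of external propionate.
#'
#' @return Named list of `enzyme_kinetics` objects.
#' @export
default_enzymes <- function() {
  list(
    PduCDE = enzyme_kinetics("PduCDE", vmax_fwd = 4e5, km_fwd = 0.5),
    PduP = enzyme_kinetics("PduP", vmax_fwd = 8e5, km_fwd = 25,
                           vmax_rev = 8e3, km_rev = 50),
    PduQ = enzyme_kinetics("PduQ", vmax_fwd = 2e5, km_fwd = 25,
                           vmax_rev = 2e4, km_rev = 50),
    PduLW = enzyme_kinetics("PduLW", vmax_fwd = 500, km_fwd = 0.5)
  )
}

#' Full model parameter set
#'
#' @param compartments A `compartment_ensemble`; default 15 spheres of 140 nm
#'   diameter (the MCP base case).
#' @param cell A `cell_geometry`; default 0.5 um capsule radius, 2.5 um length.
#' @param enzymes Named list of `enzyme_kinetics` with entries PduCDE, PduP,
#'   PduQ, PduLW.
#' @param k_c_um_h Shell permeability, um/h, one value for all species;
#'   default 5000 (calibrated).
#' @param end_permeability_multiplier Scale on the shell permeability applied
#'   to cylinder end caps (0 = closed ends, 1 = fully open ends at shell
#'   permeability). Ignored for spheres.
#' @param k_m_um_h Cell-membrane permeability, um/h; default 3600.
#' @param membrane_permeable Logical vector over species (PDO, PALD, PCOA,
#'   POH, PROP) flagging which cross the cell membrane. Propionyl-CoA is
#'   membrane-impermeant by default (CoA thioesters stay inside the cell).
#' @param initial_external_PDO_mM Initial external 1,2-propanediol, mM
#'   (default 55).
#' @param enzyme_scaling_mode `"fixed_total_enzyme"` rescales lumen maximal
#'   rates inversely with total compartment volume relative to
#'   `reference_lumen_volume_um3`, holding the total enzyme amount per cell
#'   fixed across geometries; `"fixed_concentration"` uses the vmax values
#'   as given.
#' @param reference_lumen_volume_um3 Total compartment volume to which the
#'   lumen vmax values are referred (default: 15 spheres of 140 nm).
#' @return A `pdu_params` object.
#' @export
pdu_model_parameters <- function(compartments = compartment_ensemble(make_sphere(140), 15),
                                 cell = cell_geometry(),
                                 enzymes = default_enzymes(),
                                 k_c_um_h = 5000,
                                 end_permeability_multiplier = 0,
                                 k_m_um_h = 3600,
                                 membrane_permeable = c(PDO = TRUE, PALD = TRUE,
                                                        PCOA = FALSE, POH = TRUE,
                                                        PROP = TRUE),
                                 initial_external_PDO_mM = 55,
                                 enzyme_scaling_mode = c("fixed_total_enzyme",
                                                         "fixed_concentration"),
                                 reference_lumen_volume_um3 = NULL) {
  stopifnot(inherits(compartments, "compartment_ensemble"),
            inherits(cell, "cell_geometry"))
  enzyme_scaling_mode <- match.arg(enzyme_scaling_mode)
  need <- c("PduCDE", "PduP", "PduQ", "PduLW")
  if (!all(need %in% names(enzymes))) {
    stop("enzymes must contain ", paste(need, collapse = ", "), call. = FALSE)
  }
  for (e in enzymes[need]) stopifnot(inherits(e, "enzyme_kinetics"))
  if (k_c_um_h < 0 || k_m_um_h < 0 || end_permeability_multiplier < 0) {
    stop("permeabilities and the end multiplier must be >= 0", call. = FALSE)
  }
  if (initial_external_PDO_mM < 0) {
    stop("initial external 1,2-propanediol must be >= 0", call. = FALSE)
  }
  mp <- rep(TRUE, 5L)
  names(mp) <- SPECIES
  mp[names(membrane_permeable)] <- as.logical(membrane_permeable)
  if (is.null(reference_lumen_volume_um3)) {
    reference_lumen_volume_um3 <- 15 * make_sphere(140)$volume_per_compartment_um3
  }
  p <- structure(
    list(compartments = compartments, cell = cell, enzymes = enzymes[need],
         k_c_um_h = k_c_um_h,
         end_permeability_multiplier = end_permeability_multiplier,
         k_m_um_h = k_m_um_h, membrane_permeable = mp,
         initial_external_PDO_mM = initial_external_PDO_mM,
         enzyme_scaling_mode = enzyme_scaling_mode,
         reference_lumen_volume_um3 = reference_lumen_volume_um3),
    class = "pdu_params"
  )
  if (cytosol_volume(p) <= 0) {
    stop("total compartment volume exceeds the cell volume", call. = FALSE)
  }
  p
}

#' Cytosol volume implied by a parameter set
#'
#' Cell volume minus total compartment volume, um^3.
#' @param params A `pdu_params`.
#' @export
cytosol_volume <- function(params) {
  params$cell$cell_volume_um3 - params$compartments$total_volume_um3
}

#' Scale factor applied to lumen maximal rates
#'
#' Under `fixed_total_enzyme`, lumen vmax values are multiplied by the ratio
#' of the reference lumen volume to the current total compartment volume, so
#' the enzyme amount per cell is invariant under geometry changes (the
#' equal-area microtube case concentrates the same enzymes into less volume).
#'
#' @param params A `pdu_params`.
#' @return Dimensionless multiplier.
#' @export
lumen_vmax_scale <- function(params) {
  if (params$enzyme_scaling_mode == "fixed_total_enzyme") {
    params$reference_lumen_volume_um3 / params$compartments$total_volume_um3
  } else {
    1
  }
}

#' @export
print.pdu_params <- function(x, ...) {
  g <- x$compartments$geometry
  cat(sprintf("<pdu_params: %.4g x %s (r=%g um), k_c=%g um/h, k_m=%g um/h>\n",
              x$compartments$count, g$shape, g$radius_um, x$k_c_um_h, x$k_m_um_h))
  cat(sprintf("  lumen vmax scale %.4g, initial external PDO %g mM\n",
              lumen_vmax_scale(x), x$initial_external_PDO_mM))
  invisible(x)
}

## ---- named scalar parameter access (calibration & sensitivity) -----------

enzyme_param_table <- function() {
  out <- expand.grid(enz = c("PduCDE", "PduP", "PduQ", "PduLW"),
                     fld = c("vmax_fwd", "km_fwd", "vmax_rev", "km_rev"),
                     stringsAsFactors = FALSE)
  suffix <- c(PduCDE = "CDE", PduP = "P", PduQ = "Q", PduLW = "LW")
  pre <- c(vmax_fwd = "vmax_", km_fwd = "km_", vmax_rev = "vmax_rev_",
           km_rev = "km_rev_")
  out$name <- paste0(pre[out$fld], suffix[out$enz])
  out
}

#' Names of perturbable scalar parameters
#'
#' Kinetic and transport scalars address fields of the parameter object
#' directly (`k_c`, `k_m`, `vmax_P`, `km_CDE`, ...). Morphological names are
#' defined by how the geometry is rebuilt when they are scaled:
#' \describe{
#'   \item{total_surface_area}{compartment count at fixed per-compartment
#'     geometry, holding the total enzyme amount fixed (pure transport-area
#'     perturbation).}
#'   \item{total_lumen_volume}{per-compartment volume at fixed area and
#'     count, holding total enzyme fixed.}
#'   \item{compartment_count}{count at fixed geometry and fixed enzyme
#'     concentration (total enzyme scales with count).}
#'   \item{compartment_radius}{per-compartment radius at fixed count and
#'     fixed total enzyme (a composite knob: area scales as r^2 and volume
#'     as r^3).}
#'   \item{cell_length, capsule_radius}{cell dimensions (membrane area and
#'     cytosol volume move together).}
#' }
#' @return Character vector of parameter names.
#' @export
perturbable_parameters <- function() {
  c("k_c", "k_m", enzyme_param_table()$name,
    "total_surface_area", "total_lumen_volume", "compartment_count",
    "compartment_radius", "cell_length", "capsule_radius")
}

#' Morphological feature parameters used for the dominance ranking
#'
#' The aggregate geometric quantities the model equations contain: total
#' shell surface area, total lumen volume, compartment count, and the two
#' cell dimensions. The composite `compartment_radius` knob is excluded from
#' the feature ranking because it rescales surface area at twice the
#' logarithmic rate of a direct area perturbation (see the methods vignette).
#' @return Character vector of parameter names.
#' @export
morphological_parameters <- function() {
  c("total_surface_area", "total_lumen_volume", "compartment_count",
    "cell_length", "capsule_radius")
}

scale_geometry <- function(geom, radius_factor = 1, volume_factor = 1) {
  ## volume_factor adjusts per-compartment volume without touching areas
  ## (an aggregate perturbation, not a realizable shape change)
  g <- geom
  if (radius_factor != 1) {
    r <- geom$radius_um * radius_factor
    if (geom$shape == "sphere") {
      g <- make_sphere(2 * r * NM_PER_UM)
    } else {
      g <- make_cylinder(2 * r * NM_PER_UM, geom$length_um * NM_PER_UM,
                         geom$include_end_area)
    }
  }
  if (volume_factor != 1) {
    g$volume_per_compartment_um3 <- g$volume_per_compartment_um3 * volume_factor
  }
  g
}

#' Scale a named parameter by a factor
#'
#' Returns a new parameter object in which the named scalar (see
#' [perturbable_parameters()]) is multiplied by `factor`, rebuilding the
#' geometry for morphological names.
#'
#' @param params A `pdu_params`.
#' @param name Parameter name.
#' @param factor Positive multiplicative factor.
#' @return A modified `pdu_params`.
#' @export
scale_param <- function(params, name, factor) {
  stopifnot(inherits(params, "pdu_params"), is.numeric(factor), factor > 0)
  p <- params
  et <- enzyme_param_table()
  if (name == "k_c") {
    p$k_c_um_h <- p$k_c_um_h * factor
  } else if (name == "k_m") {
    p$k_m_um_h <- p$k_m_um_h * factor
  } else if (name %in% et$name) {
    row <- et[et$name == name, ]
    p$enzymes[[row$enz]][[row$fld]] <- p$enzymes[[row$enz]][[row$fld]] * factor
  } else if (name %in% c("total_surface_area", "compartment_count")) {
    p$compartments <- compartment_ensemble(p$compartments$geometry,
                                           p$compartments$count * factor)
    if (name == "compartment_count") {
      ## fixed concentration: total enzyme follows the volume
      p$reference_lumen_volume_um3 <- p$reference_lumen_volume_um3 * factor
    }
  } else if (name == "total_lumen_volume") {
    g <- scale_geometry(p$compartments$geometry, volume_factor = factor)
    p$compartments <- compartment_ensemble(g, p$compartments$count)
  } else if (name == "compartment_radius") {
    g <- scale_geometry(p$compartments$geometry, radius_factor = factor)
    p$compartments <- compartment_ensemble(g, p$compartments$count)
  } else if (name == "cell_length") {
    p$cell <- cell_geometry(p$cell$capsule_radius_um,
                            p$cell$cell_length_um * factor)
  } else if (name == "capsule_radius") {
    p$cell <- cell_geometry(p$cell$capsule_radius_um * factor,
                            p$cell$cell_length_um)
  } else {
    stop("unknown parameter name: ", name, call. = FALSE)
  }
  if (cytosol_volume(p) <= 0) {
    stop("perturbation makes cytosol volume nonpositive", call. = FALSE)
  }
  p
}

#' Read the current value of a named scalar parameter
#'
#' Morphological names report the corresponding aggregate quantity (total
#' area in um^2, total volume in um^3, count, or the cell dimension in um).
#'
#' @inheritParams scale_param
#' @return Numeric scalar.
#' @export
param_value <- function(params, name) {
  et <- enzyme_param_table()
  if (name == "k_c") return(params$k_c_um_h)
  if (name == "k_m") return(params$k_m_um_h)
  if (name %in% et$name) {
    row <- et[et$name == name, ]
    return(params$enzymes[[row$enz]][[row$fld]])
  }
  switch(name,
    total_surface_area = params$compartments$total_area_um2,
    total_lumen_volume = params$compartments$total_volume_um3,
    compartment_count = params$compartments$count,
    compartment_radius = params$compartments$geometry$radius_um,
    cell_length = params$cell$cell_length_um,
    capsule_radius = params$cell$capsule_radius_um,
    stop("unknown parameter name: ", name, call. = FALSE)
  )
}

#' Set a named scalar parameter to an absolute value
#'
#' @inheritParams scale_param
#' @param value New positive value on the same scale as [param_value()].
#' @export
set_param <- function(params, name, value) {
  cur <- param_value(params, name)
  scale_param(params, name, value / cur)
}
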