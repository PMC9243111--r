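#' Compartment and cell geometry
#'
#' The model treats each region (compartment lumen, cytosol, external medium)
#' as well mixed, so the only geometric quantities that matter are surface
#' areas, volumes, and the number of compartments per cell. Lengths are
#' supplied in nm for compartments (matching how microcompartment dimensions
#' are reported) and converted to an internal canonical unit of micrometres;
#' all areas and volumes are stored in um^2 / um^3 so that flux terms stay
#' O(1)-O(100) in magnitude.
#'
#' @name geometry
NULL

NM_PER_UM <- 1e3

#' Spherical compartment geometry
#'
#' @param diameter_nm Sphere diameter in nm (microcompartments are idealized
#'   as 140 nm spheres).
#' @return A `compartment_geometry` object with per-compartment lateral area,
#'   end-cap area (zero for spheres), total area, and volume in um^2 / um^3.
#' @examples
#' make_sphere(140)
#' @export
make_sphere <- function(diameter_nm) {
  stopifnot(is.numeric(diameter_nm), length(diameter_nm) == 1L)
  if (!is.finite(diameter_nm) || diameter_nm <= 0) {
    stop("sphere diameter must be a positive finite length (nm)", call. = FALSE)
  }
  r <- diameter_nm / NM_PER_UM / 2
  structure(
    list(
      shape = "sphere",
      radius_um = r,
      length_um = NA_real_,
      include_end_area = FALSE,
      lateral_area_um2 = 4 * pi * r^2,
      end_area_um2 = 0,
      area_per_compartment_um2 = 4 * pi * r^2,
      volume_per_compartment_um3 = 4 / 3 * pi * r^3
    ),
    class = "compartment_geometry"
  )
}

#' Cylindrical compartment geometry
#'
#' Microtubes are idealized as cylinders spanning the cell; metabolites cross
#' the lateral (long-axis) surface, and the end caps are closed unless an end
#' permeability is switched on in the model parameters.
#'
#' @param diameter_nm Cylinder diameter in nm.
#' @param length_nm Cylinder length in nm (typically the cell length).
#' @param include_end_area Count both end caps (2 pi r^2) in
#'   `area_per_compartment_um2`. The default `FALSE` gives the lateral-only
#'   area used for surface-area matching.
#' @return A `compartment_geometry` object.
#' @examples
#' make_cylinder(50, 2500)
#' @export
make_cylinder <- function(diameter_nm, length_nm, include_end_area = FALSE) {
  stopifnot(is.numeric(diameter_nm), is.numeric(length_nm),
            is.logical(include_end_area), length(include_end_area) == 1L)
  if (!is.finite(diameter_nm) || diameter_nm <= 0) {
    stop("cylinder diameter must be a positive finite length (nm)", call. = FALSE)
  }
  if (!is.finite(length_nm) || length_nm <= 0) {
    stop("cylinder length must be a positive finite length (nm)", call. = FALSE)
  }
  r <- diameter_nm / NM_PER_UM / 2
  L <- length_nm / NM_PER_UM
  lateral <- 2 * pi * r * L
  ends <- 2 * pi * r^2
  structure(
    list(
      shape = "cylinder",
      radius_um = r,
      length_um = L,
      include_end_area = include_end_area,
      lateral_area_um2 = lateral,
      end_area_um2 = ends,
      area_per_compartment_um2 = lateral + if (include_end_area) ends else 0,
      volume_per_compartment_um3 = pi * r^2 * L
    ),
    class = "compartment_geometry"
  )
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat(sprintf("<compartment_geometry: %s, r = %g um%s>\n", x$shape, x$radius_um,
              if (x$shape == "cylinder") sprintf(", L = %g um", x$length_um) else ""))
  cat(sprintf("  area/compartment   %.6g um^2\n", x$area_per_compartment_um2))
  cat(sprintf("  volume/compartment %.6g um^3\n", x$volume_per_compartment_um3))
  invisible(x)
}

#' Capsule-shaped cell geometry
#'
#' Cells are modeled as spherocylinders (capsules): a cylinder of radius `r`
#' and total length `L` with hemispherical caps. The cytosol volume is the
#' cell volume minus the total compartment volume and must remain positive.
#'
#' @param capsule_radius_um Cell radius in um (default 0.5, a typical rod
#'   half-width; not a printed model dimension).
#' @param cell_length_um Total cell length in um (default 2.5).
#' @return A `cell_geometry` object with membrane area and cell volume.
#' @export
cell_geometry <- function(capsule_radius_um = 0.5, cell_length_um = 2.5) {
  stopifnot(is.numeric(capsule_radius_um), is.numeric(cell_length_um))
  if (capsule_radius_um <= 0 || cell_length_um <= 2 * capsule_radius_um) {
    stop("capsule requires 0 < radius and length > 2*radius", call. = FALSE)
  }
  r <- capsule_radius_um
  L <- cell_length_um
  structure(
    list(
      capsule_radius_um = r,
      cell_length_um = L,
      membrane_area_um2 = 2 * pi * r * (L - 2 * r) + 4 * pi * r^2,
      cell_volume_um3 = pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3
    ),
    class = "cell_geometry"
  )
}

#' Ensemble of identical compartments in one cell
#'
#' @param geometry A `compartment_geometry`.
#' @param count Compartments per cell. Fractional counts are permitted: the
#'   model is a continuum description and the area/volume matching modes do
#'   not generally yield integers.
#' @return A `compartment_ensemble` with total area and volume.
#' @export
compartment_ensemble <- function(geometry, count) {
  stopifnot(inherits(geometry, "compartment_geometry"), is.numeric(count))
  if (!is.finite(count) || count < 0) {
    stop("compartment count must be a nonnegative real number", call. = FALSE)
  }
  structure(
    list(
      geometry = geometry,
      count = count,
      total_area_um2 = count * geometry$area_per_compartment_um2,
      total_volume_um3 = count * geometry$volume_per_compartment_um3
    ),
    class = "compartment_ensemble"
  )
}

#' @export
print.compartment_ensemble <- function(x, ...) {
  cat(sprintf("<compartment_ensemble: %.4g x %s>\n", x$count, x$geometry$shape))
  cat(sprintf("  total area   %.6g um^2\n  total volume %.6g um^3\n",
              x$total_area_um2, x$total_volume_um3))
  invisible(x)
}

#' Match an ensemble of a new geometry to a base ensemble
#'
#' Implements the two limiting comparisons between compartment shapes: keep
#' the total encapsulated volume equal (`equal_volume`, enzyme concentration
#' unchanged) or keep the total shell surface area equal (`equal_area`,
#' enzyme concentration rises as the encapsulated volume shrinks). A
#' `fixed_count` mode simply places `count` compartments of the target
#' geometry.
#'
#' @param base A `compartment_ensemble` providing the matching totals.
#' @param target_geom `compartment_geometry` of the new shape.
#' @param mode One of `"equal_volume"`, `"equal_area"`, `"fixed_count"`.
#' @param count Compartments per cell, required for `mode = "fixed_count"`.
#' @return A `compartment_ensemble` of the target geometry.
#' @export
match_ensemble <- function(base, target_geom,
                           mode = c("equal_volume", "equal_area", "fixed_count"),
                           count = NULL) {
  stopifnot(inherits(base, "compartment_ensemble"),
            inherits(target_geom, "compartment_geometry"))
  mode <- match.arg(mode)
  if (base$total_area_um2 <= 0 || base$total_volume_um3 <= 0) {
    stop("base ensemble must have positive total area and volume", call. = FALSE)
  }
  n <- switch(mode,
    equal_volume = base$total_volume_um3 / target_geom$volume_per_compartment_um3,
    equal_area = base$total_area_um2 / target_geom$area_per_compartment_um2,
    fixed_count = {
      if (is.null(count)) {
        stop("mode 'fixed_count' requires a count", call. = FALSE)
      }
      count
    }
  )
  compartment_ensemble(target_geom, n)
}

#' Closed-form surface-area fold factor between a sphere and a lateral cylinder
#'
#' For equal total volume, the ratio of total lateral cylinder area to total
#' sphere area equals the ratio of volume-to-area quotients,
#' (r_s/3)/(r_c/2) = 2 r_s / (3 r_c). This is the analytic oracle for the
#' `match_ensemble` fold changes; with a 140 nm sphere and 50 nm cylinder it
#' gives 1.87 (1.9 at two significant figures).
#'
#' @param sphere_radius Sphere radius (any length unit).
#' @param cylinder_radius Cylinder radius (same unit).
#' @return Dimensionless fold factor.
#' @export
sa_v_fold_factor <- function(sphere_radius, cylinder_radius) {
  if (!is.numeric(sphere_radius) || !is.numeric(cylinder_radius) ||
      any(sphere_radius <= 0) || any(cylinder_radius <= 0)) {
    stop("radii must be positive", call. = FALSE)
  }
  2 * sphere_radius / (3 * cylinder_radius)
}
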