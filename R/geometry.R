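#' Cell geometry
#'
#' All simulation lengths are measured in units of the cell radius, so the
#' simulated cell is always the unit disc. Physical lengths are carried
#' only for derived reporting (area fraction occupied by mitochondria,
#' inter-nucleoid spacing in micrometres); they never enter the
#' simulation itself.
#'
#' @param physical_radius_um cell radius in micrometres (reporting only).
#' @param tubule_width_um mitochondrial tubule width in micrometres
#'   (reporting only).
#' @return an object of class `cell_geometry`.
#' @examples
#' g <- cell_geometry()
#' mito_area_fraction(g, mass_target = 50)
#' @export
cell_geometry <- function(physical_radius_um = 40, tubule_width_um = 0.4) {
  stopifnot(physical_radius_um > 0, tubule_width_um > 0)
  structure(
    list(radius = 1,
         physical_radius_um = physical_radius_um,
         tubule_width_um = tubule_width_um),
    class = "cell_geometry")
}

#' Mitochondrial area fraction implied by a network mass target
#'
#' A network of total length `mass_target` (in cell radii) and tubule width
#' `tubule_width_um` occupies area `mass_target * R * width` in a cell of
#' area `pi * R^2`. With the defaults (total length 50 radii, radius 40 um,
#' width 0.4 um) the mitochondrial area is 800 um^2 out of ~5000 um^2,
#' i.e. about 16% of the cell.
#'
#' @param geom a [cell_geometry()].
#' @param mass_target total network length in units of the cell radius.
#' @return area fraction in percent.
#' @export
mito_area_fraction <- function(geom = cell_geometry(), mass_target = 50) {
  stopifnot(inherits(geom, "cell_geometry"), mass_target > 0)
  mito_area <- mass_target * geom$physical_radius_um * geom$tubule_width_um
  cell_area <- pi * geom$physical_radius_um^2
  100 * mito_area / cell_area
}

#' Physical nucleoid spacing implied by a repulsion radius
#'
#' Converts the dimensionless exclusion radius `l` (units of cell radius)
#' into micrometres; e.g. l = 0.05 in a 40 um cell is a 2 um minimum
#' spacing, within the observed range of inter-nucleoid distances.
#'
#' @param l exclusion radius in units of the cell radius.
#' @param geom a [cell_geometry()].
#' @return spacing in micrometres.
#' @export
nucleoid_spacing_um <- function(l, geom = cell_geometry()) {
  stopifnot(l >= 0, inherits(geom, "cell_geometry"))
  l * geom$physical_radius_um
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat("Circular cell, radius 1 (simulation units)\n")
  cat(sprintf("  physical radius: %g um, tubule width: %g um\n",
              x$physical_radius_um, x$tubule_width_um))
  invisible(x)
}
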