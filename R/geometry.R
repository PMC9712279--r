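# Microsampling geometry: the deterministic calculus linking linear and
# volumetric expansion factors, biopsy-punch sizes, pre-expansion lateral
# resolution, punched tissue volume and cell-count estimates.

#' Volumetric expansion factor from a linear expansion factor
#'
#' Under isotropic expansion a tissue that expands by a linear expansion
#' factor (LEF) grows in volume by the cube of that factor.  A gel that
#' expands 5.5--8-fold linearly therefore expands 166--512-fold in volume.
#'
#' @param lef linear expansion factor (dimensionless, >= 1).
#' @param rounded if `TRUE`, round to the nearest integer as done when the
#'   factor is reported; the default returns the raw cube.
#' @return volumetric expansion factor, `lef^3`.
#' @examples
#' volumetric_expansion_factor(5.5, rounded = TRUE)  # 166
#' volumetric_expansion_factor(8)                    # 512
#' @export
volumetric_expansion_factor <- function(lef, rounded = FALSE) {
  check_number(lef, "lef", lower = 1)
  vef <- lef^3
  if (rounded) round(vef) else vef
}

#' Pre-expansion diameter of a punched gel cylinder
#'
#' A biopsy punch of given diameter taken from the expanded tissue--hydrogel
#' composite samples a disc of tissue whose original (pre-expansion)
#' diameter is the punch diameter divided by the linear expansion factor.
#' This quotient is the lateral sampling resolution of the experiment.
#'
#' @param punch_diameter punch diameter in the expanded gel, um.
#' @param lef linear expansion factor (>= 1).
#' @return pre-expansion diameter in um.
#' @examples
#' pre_expansion_diameter(1000, 8)  # 125 um
#' @export
pre_expansion_diameter <- function(punch_diameter, lef) {
  check_number(punch_diameter, "punch_diameter", lower = 0, strict_lower = TRUE)
  check_number(lef, "lef", lower = 1)
  punch_diameter / lef
}

#' Cylindrical tissue volume in nanolitres
#'
#' Volume of the tissue cylinder sampled by a punch: a disc of the given
#' diameter through the full section thickness,
#' \eqn{V = \pi (d/2)^2 h}, converted from um^3 to nL
#' (1 nL = 1e6 um^3).
#'
#' @param diameter cylinder diameter, um (pre-expansion for tissue volume).
#' @param thickness section thickness, um; default 30 um (vibratome
#'   sections).
#' @return volume in nL.
#' @examples
#' cylinder_volume_nL(500, 30)  # ~5.9 nL
#' @export
cylinder_volume_nL <- function(diameter, thickness = 30) {
  check_number(diameter, "diameter", lower = 0)
  check_number(thickness, "thickness", lower = 0, strict_lower = TRUE)
  pi * (diameter / 2)^2 * thickness / 1e6
}

#' Cell-count estimate for a tissue volume
#'
#' Multiplies a tissue volume by a volumetric cell density and rounds to
#' the nearest whole cell.  The default density is a configuration
#' constant, [default_cell_density()], not a hard-coded value.
#'
#' @param volume_nL tissue volume in nL (>= 0).
#' @param density_cells_per_nL cells per nL of tissue (> 0).
#' @return estimated cell count (integer-valued numeric).
#' @examples
#' estimate_cells(0.37)  # ~160 cells
#' @export
estimate_cells <- function(volume_nL,
                           density_cells_per_nL = default_cell_density()) {
  check_number(volume_nL, "volume_nL", lower = 0)
  check_number(density_cells_per_nL, "density_cells_per_nL",
               lower = 0, strict_lower = TRUE)
  round(volume_nL * density_cells_per_nL)
}

#' Default volumetric cell density
#'
#' Cells per nL of (mouse brain) tissue used by [estimate_cells()].  The
#' value 432.4 cells/nL is back-computed from the literature pairing of
#' roughly 160 cells in 0.37 nL of cortex (BioNumbers entry BNID 100434
#' gives the underlying cellular density); it can be overridden in any
#' call that takes a density.
#'
#' @return numeric scalar, cells per nL.
#' @export
default_cell_density <- function() 432.4

#' Full punch geometry summary
#'
#' Combines the geometry operations for one punch: pre-expansion diameter,
#' pre-expansion tissue volume for a given section thickness, cell-count
#' estimate, and the volumetric expansion factor.
#'
#' @inheritParams pre_expansion_diameter
#' @inheritParams cylinder_volume_nL
#' @inheritParams estimate_cells
#' @return `data.frame` with one row per punch: `punch_diameter_um`, `lef`,
#'   `thickness_um`, `pre_diameter_um`, `pre_volume_nL`, `cell_estimate`,
#'   `vef`.
#' @examples
#' punch_geometry(2000, lef = 6)   # the 2-mm punch at ~6x expansion
#' @export
punch_geometry <- function(punch_diameter, lef, thickness = 30,
                           density_cells_per_nL = default_cell_density()) {
  pre_d <- pre_expansion_diameter(punch_diameter, lef)
  vol <- cylinder_volume_nL(pre_d, thickness)
  data.frame(
    punch_diameter_um = punch_diameter,
    lef = lef,
    thickness_um = thickness,
    pre_diameter_um = pre_d,
    pre_volume_nL = vol,
    cell_estimate = estimate_cells(vol, density_cells_per_nL),
    vef = volumetric_expansion_factor(lef)
  )
}
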