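#' Spherocylinder geometry of a rod-shaped cell
#'
#' Rod-shaped bacteria are modelled as a cylinder of width `w` and total
#' length `l` capped by two hemispheres (a spherocylinder), the standard
#' geometric model for *E. coli*. Projected (2D) area and perimeter describe
#' the cell outline seen in phase contrast; volume and surface area are the
#' 3D quantities derived from the same outline.
#'
#' At the sphere limit `l == w` these reduce to the circle/sphere formulas,
#' so circularity `4 * pi * A / P^2` equals 1 there.
#'
#' @param length_um Cell length in µm (tip to tip), `length_um >= width_um`.
#' @param width_um Cell width (diameter) in µm.
#'
#' @return A tibble with columns `area_um2`, `perimeter_um`, `volume_um3`,
#'   `surface_um2`, `sv_ratio`, `aspect_ratio`, `circularity`, one row per
#'   input cell.
#' @examples
#' spherocylinder_geometry(4, 1)
#' spherocylinder_geometry(1, 1)$circularity # sphere limit -> 1
#' @export
spherocylinder_geometry <- function(length_um, width_um) {
  if (any(!is.finite(length_um)) || any(!is.finite(width_um))) {
    abort("lengths and widths must be finite.")
  }
  l <- pmax(length_um, width_um) # guard against mis-detected w > l rows
  w <- pmin(length_um, width_um)
  body <- l - w
  area <- w * body + pi * w^2 / 4
  perim <- 2 * body + pi * w
  vol <- pi * w^2 * body / 4 + pi * w^3 / 6
  surf <- pi * w * body + pi * w^2
  tibble(
    area_um2 = area,
    perimeter_um = perim,
    volume_um3 = vol,
    surface_um2 = surf,
    sv_ratio = surf / vol,
    aspect_ratio = width_um / length_um,
    circularity = 4 * pi * area / perim^2
  )
}
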