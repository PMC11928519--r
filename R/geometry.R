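#' Adjust corneal irradiance to retinal irradiance
#'
#' The irradiance at the retina follows from power conservation: the optical
#' power in the projected pattern is the same at the cornea and at the
#' retina, so irradiance scales with the inverse of the pattern area,
#' `E_retina = E_cornea * A_cornea / A_retina`.
#'
#' @param corneal_irradiance_mw_mm2 Irradiance of the pattern at the cornea,
#'   mW/mm^2.
#' @param corneal_area_mm2 Area of the projected pattern at the cornea, mm^2.
#' @param retinal_area_mm2 Area of the same pattern on the retina, mm^2.
#' @return Retinal irradiance, mW/mm^2.
#' @examples
#' retinal_irradiance(0.5, corneal_area_mm2 = 4, retinal_area_mm2 = 2)  # 1.0
#' @export
retinal_irradiance <- function(corneal_irradiance_mw_mm2,
                               corneal_area_mm2, retinal_area_mm2) {
  if (!is.numeric(corneal_irradiance_mw_mm2) ||
      any(corneal_irradiance_mw_mm2 <= 0)) {
    stop("corneal irradiance must be positive")
  }
  if (!is.numeric(corneal_area_mm2) || corneal_area_mm2 <= 0 ||
      !is.numeric(retinal_area_mm2) || retinal_area_mm2 <= 0) {
    stop("pattern areas must be positive")
  }
  corneal_irradiance_mw_mm2 * corneal_area_mm2 / retinal_area_mm2
}

#' Row pitch of a hexagonal pixel array
#'
#' Centre-to-centre row spacing of a hexagonal lattice of pixels:
#' `pitch = width * cos(30 degrees)`. A 100 um hexagonal pixel has a pitch
#' of 86.6 um, conventionally displayed as 87 um.
#'
#' @param pixel_width_um Pixel width (flat-to-flat lattice constant), um.
#' @param rounded If `TRUE`, round to the nearest integer for display.
#' @return Pitch in um.
#' @examples
#' hex_pitch(100)                  # 86.60254
#' hex_pitch(100, rounded = TRUE)  # 87
#' @export
hex_pitch <- function(pixel_width_um, rounded = FALSE) {
  if (!is.numeric(pixel_width_um) || any(pixel_width_um <= 0)) {
    stop("pixel width must be positive")
  }
  p <- pixel_width_um * cos(pi / 6)
  if (rounded) round(p) else p
}

#' Snellen denominator for a retinal feature size
#'
#' Converts a resolvable feature size on the human retina into Snellen
#' notation (20/X). By the 1-arcminute definition of 20/20 and the standard
#' human retinal magnification of 288 um per degree (4.8 um per arcminute),
#' `X = 20 * feature / (um_per_degree / 60)`,
#' rounded to the nearest `round_to` for display (clinical acuities are
#' conventionally quoted in steps of 10).
#'
#' @param feature_um Feature size on the retina, um.
#' @param um_per_degree Retinal magnification, um per degree of visual angle
#'   (default 288, human retina).
#' @param round_to Rounding granularity for display; `NULL` returns the raw
#'   value.
#' @return The Snellen denominator X (20/X).
#' @examples
#' snellen_denominator(100)              # 420  (raw 416.7)
#' snellen_denominator(4.8)              # 20
#' snellen_denominator(hex_pitch(22))    # 80   (raw 79.4)
#' @export
snellen_denominator <- function(feature_um, um_per_degree = 288,
                                round_to = 10) {
  if (!is.numeric(feature_um) || any(feature_um <= 0)) {
    stop("feature size must be positive")
  }
  stopifnot(um_per_degree > 0)
  raw <- 20 * feature_um / (um_per_degree / 60)
  if (is.null(round_to)) raw else round(raw / round_to) * round_to
}
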