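#' Sector scan-area geometry
#'
#' B-mode images contain echo data only inside a fan-shaped sector; all pixel
#' statistics in this package are restricted to it. The sector has its apex at
#' the top-centre of the raster and a 120 degree aperture opening downwards.
#' Its radius is the largest value for which the fan is fully inscribed in the
#' raster, `min(height - 1, (width - 1) / (2 sin(aperture/2)))`, so the
#' analytic sector area `aperture/2 * radius^2` applies.
#'
#' @param width,height Raster dimensions in pixels.
#' @param aperture_deg Full fan aperture in degrees (default 120).
#' @return For `sector_geometry()`, a list with `apex_row`, `apex_col`
#'   (1-based pixel coordinates), `radius` (pixels), `aperture_rad`, `width`
#'   and `height`. For `sector_mask()`, a `height x width` logical matrix,
#'   `TRUE` inside the sector.
#' @export
sector_geometry <- function(width, height, aperture_deg = 120) {
  stopifnot(width >= 8, height >= 8)
  half <- aperture_deg / 2 * pi / 180
  list(
    apex_row = 1,
    apex_col = (width + 1) / 2,
    radius = min(height - 1, (width - 1) / (2 * sin(half))),
    aperture_rad = 2 * half,
    width = as.integer(width),
    height = as.integer(height)
  )
}

#' @rdname sector_geometry
#' @export
sector_mask <- function(width, height, aperture_deg = 120) {
  g <- sector_geometry(width, height, aperture_deg)
  rr <- matrix(seq_len(height), height, width) - g$apex_row
  cc <- matrix(seq_len(width), height, width, byrow = TRUE) - g$apex_col
  rho <- sqrt(rr^2 + cc^2)
  # angle from the downward axis; apex row itself belongs to the sector tip
  ang <- atan2(abs(cc), rr)
  rho <= g$radius & (rho == 0 | ang <= g$aperture_rad / 2 + 1e-12)
}

# check that a raster's dimensions match a geometry, error naming both shapes
check_sector_dims <- function(dims, geometry) {
  if (dims[1] != geometry$height || dims[2] != geometry$width) {
    stop(sprintf("dimension mismatch: raster is %d x %d but sector geometry is %d x %d",
                 dims[1], dims[2], geometry$height, geometry$width), call. = FALSE)
  }
  invisible(TRUE)
}
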