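#' Extract a colour tracing overlay from an annotated RGB image
#'
#' Recovers the tracing curve as the set of pixels whose colour matches
#' `color_spec` within a per-channel absolute tolerance. Tolerance 0 is
#' appropriate for synthetic renderings; around 30 per channel accommodates
#' compression artefacts in real annotated images.
#'
#' @param rgb_image RGB array `height x width x 3`, intensities 0..255.
#' @param color_spec RGB triple to match (e.g. `c(0, 0, 255)` for the device
#'   tracing in blue, `c(255, 0, 255)` for a reviewer in magenta).
#' @param tolerance Per-channel absolute bound (default 0).
#' @param source_type,source_id,image_ref Attribution recorded on the
#'   returned overlay.
#' @return A [tracing_overlay()].
#' @export
extract_overlay <- function(rgb_image, color_spec, tolerance = 0,
                            source_type = "device", source_id = NA_character_,
                            image_ref = NA_character_) {
  stopifnot(length(dim(rgb_image)) == 3, dim(rgb_image)[3] == 3,
            length(color_spec) == 3)
  hit <- abs(rgb_image[, , 1] - color_spec[1]) <= tolerance &
    abs(rgb_image[, , 2] - color_spec[2]) <= tolerance &
    abs(rgb_image[, , 3] - color_spec[3]) <= tolerance
  if (!any(hit))
    stop(sprintf("no tracing found: no pixel matches colour (%s) within tolerance %g",
                 paste(color_spec, collapse = ","), tolerance), call. = FALSE)
  tracing_overlay(which(hit, arr.ind = TRUE), source_type, source_id,
                  image_ref, color = color_spec, dims = dim(rgb_image)[1:2])
}

#' Obscure a tracing so blinded reviewers cannot see it
#'
#' Replaces every curve pixel by the per-channel median of the non-curve
#' pixels in its 5x5 neighbourhood (the window grows if it contains no
#' non-curve pixel). Because the replacement values are computed from
#' non-curve pixels only, the operation is idempotent and leaves non-curve
#' pixels untouched.
#'
#' @param rgb_image RGB array `height x width x 3`.
#' @param overlay The [tracing_overlay()] registered to `rgb_image`.
#' @return The RGB image with the tracing removed.
#' @export
obscure_tracing <- function(rgb_image, overlay) {
  stopifnot(length(dim(rgb_image)) == 3, inherits(overlay, "tracing_overlay"))
  cp <- overlay$curve_pixels
  if (nrow(cp) == 0) {
    warning("overlay is empty: image returned unchanged")
    return(rgb_image)
  }
  h <- dim(rgb_image)[1]; w <- dim(rgb_image)[2]
  if (max(cp[, 1]) > h || max(cp[, 2]) > w)
    stop("overlay is not registered to this image (coordinates out of range)",
         call. = FALSE)
  is_curve <- matrix(FALSE, h, w)
  is_curve[cp] <- TRUE
  out <- rgb_image
  for (i in seq_len(nrow(cp))) {
    r <- cp[i, 1]; c <- cp[i, 2]
    half <- 2
    repeat {
      rows <- max(1, r - half):min(h, r + half)
      cols <- max(1, c - half):min(w, c + half)
      keep <- !is_curve[rows, cols]
      if (any(keep)) break
      half <- half + 1
    }
    for (ch in 1:3)
      out[r, c, ch] <- stats::median(rgb_image[rows, cols, ch][keep])
  }
  out
}

#' Restrict a mask or image to the sector scan area
#'
#' Pixels outside the fan-shaped scan sector are set to `FALSE` (logical
#' masks) or to the reserved background value 0 (grayscale or RGB rasters);
#' pixels inside are unchanged.
#'
#' @param x Logical mask matrix, grayscale matrix, or RGB array.
#' @param geometry Optional [sector_geometry()]; defaults to the geometry
#'   implied by the raster's own dimensions. A mismatch between `x` and a
#'   supplied geometry is an error naming both shapes.
#' @return Same type as `x`.
#' @export
crop_to_scan_area <- function(x, geometry = NULL) {
  dims <- dim(x)
  if (is.null(geometry)) geometry <- sector_geometry(dims[2], dims[1])
  check_sector_dims(dims, geometry)
  sect <- sector_mask(geometry$width, geometry$height)
  if (is.logical(x) && length(dims) == 2) {
    x[!sect] <- FALSE
  } else if (length(dims) == 2) {
    x[!sect] <- 0
  } else if (length(dims) == 3) {
    for (ch in seq_len(dims[3])) {
      plane <- x[, , ch]; plane[!sect] <- 0; x[, , ch] <- plane
    }
  } else stop("unsupported raster type", call. = FALSE)
  x
}

#' Fill a tracing outline into a binary mask
#'
#' Reproduces the analysis software's outline-filling step. The curve is
#' first morphologically closed with a disc of radius `closing_radius` to
#' bridge small rasterization gaps; the exterior is then identified by
#' 4-connected flood fill from all raster border pixels; the mask is the
#' complement of the exterior — interior plus curve, so boundary pixels count
#' as inside. Gap-sealing pixels introduced by the closing that touch the
#' exterior are not counted as traced area (they only seal; without this the
#' closing would slightly inflate thin curves). If the curve encloses several
#' regions only the largest is kept, with a warning. The result is cropped to
#' the sector scan area.
#'
#' @param overlay A non-empty [tracing_overlay()].
#' @param dims Raster dimensions (height, width).
#' @param closing_radius Disc radius (pixels) for gap closure; default 2.
#' @return Logical mask matrix of dimension `dims`.
#' @export
fill_tracing <- function(overlay, dims, closing_radius = 2) {
  stopifnot(inherits(overlay, "tracing_overlay"), length(dims) == 2)
  cp <- overlay$curve_pixels
  if (nrow(cp) == 0) stop("overlay is empty: nothing to fill", call. = FALSE)
  h <- dims[1]; w <- dims[2]
  curve <- matrix(FALSE, h, w)
  curve[cp] <- TRUE
  closed <- curve
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    closed <- t(EBImage::imageData(
      EBImage::closing(EBImage::Image(t(curve) * 1), brush)) > 0.5)
    closed <- closed | curve
  }
  # flood the exterior from a padded border (4-connectivity; the closed
  # curve is the barrier)
  pad <- matrix(0, w + 2, h + 2)
  pad[2:(w + 1), 2:(h + 1)] <- t(closed) * 1
  ff <- EBImage::imageData(EBImage::floodFill(EBImage::Image(pad), c(1, 1), col = 2))
  exterior <- t(ff[2:(w + 1), 2:(h + 1)] == 2)
  interior <- !exterior & !closed
  if (!any(interior))
    stop(sprintf("open contour: the curve encloses no region after closing with radius %g",
                 closing_radius), call. = FALSE)
  # several enclosed regions (self-intersecting curve): keep the largest
  lab <- EBImage::bwlabel(EBImage::Image(t(interior) * 1))
  labs <- EBImage::imageData(lab)
  if (max(labs) > 1) {
    warning(sprintf("curve encloses %d regions; keeping the largest", max(labs)))
    sizes <- tabulate(labs[labs > 0])
    interior <- t(labs == which.max(sizes))
  }
  touches_ext <- function(m) {
    rbind(m[-1, , drop = FALSE], FALSE) | rbind(FALSE, m[-h, , drop = FALSE]) |
      cbind(m[, -1, drop = FALSE], FALSE) | cbind(FALSE, m[, -w, drop = FALSE])
  }
  sealing <- closed & !curve & touches_ext(exterior)
  mask <- (interior | closed) & !sealing
  crop_to_scan_area(mask)
}
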