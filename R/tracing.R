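DEVICE_COLOR <- c(0, 0, 255)      # pure blue
REVIEWER_COLOR <- c(255, 0, 255)  # magenta

#' Tracing overlay: a closed border curve registered to a scan image
#'
#' @param curve_pixels Two-column integer matrix of (row, col) coordinates.
#' @param source_type `"device"` or `"reviewer"`.
#' @param source_id Identifier of the tracer (device model or reviewer id).
#' @param image_ref Identifier of the underlying image (free-form).
#' @param color RGB triple (0..255) used when the overlay is rendered.
#' @param dims Optional (height, width) to validate coordinates against.
#' @return An object of class `tracing_overlay`.
#' @export
tracing_overlay <- function(curve_pixels, source_type = c("device", "reviewer"),
                            source_id = NA_character_, image_ref = NA_character_,
                            color = NULL, dims = NULL) {
  source_type <- match.arg(source_type)
  curve_pixels <- matrix(as.integer(curve_pixels), ncol = 2,
                         dimnames = list(NULL, c("row", "col")))
  if (is.null(color))
    color <- if (source_type == "device") DEVICE_COLOR else REVIEWER_COLOR
  if (!is.null(dims)) {
    bad <- curve_pixels[, 1] < 1 | curve_pixels[, 1] > dims[1] |
      curve_pixels[, 2] < 1 | curve_pixels[, 2] > dims[2]
    if (any(bad))
      stop(sprintf("curve_pixels: %d coordinate(s) outside the %d x %d raster",
                   sum(bad), dims[1], dims[2]), call. = FALSE)
  }
  structure(list(curve_pixels = curve_pixels,
                 source = list(type = source_type, id = source_id),
                 image_ref = image_ref, color = as.numeric(color)),
            class = "tracing_overlay")
}

#' @export
print.tracing_overlay <- function(x, ...) {
  cat(sprintf("tracing_overlay: %d curve pixels, source %s (%s), colour (%s)\n",
              nrow(x$curve_pixels), x$source$type, x$source$id,
              paste(x$color, collapse = ",")))
  invisible(x)
}

# overlay from the inner boundary of a region mask
overlay_from_mask <- function(mask, source_type, source_id, image_ref, color = NULL) {
  coords <- which(mask_boundary(mask), arr.ind = TRUE)
  tracing_overlay(coords, source_type, source_id, image_ref, color,
                  dims = dim(mask))
}

# echogenic pixels inside the chamber as the device "sees" them: bright
# (> threshold) pixels of the raster within the truth mask
echogenic_within <- function(image, truth, threshold = 100) {
  image$pixels > threshold & truth
}

#' Simulate the automated device's border tracing
#'
#' Produces a closed curve approximating the ground-truth chamber boundary
#' with smooth radial jitter of state-dependent standard deviation
#' (`config$tracer_jitter_sd[state]`). In late arrest the device undertraces:
#' echogenic clot detected inside the chamber is excluded from the traced
#' region, so the tracing omits bright blobs adjacent to the border — the
#' characteristic device-vs-human disagreement mode in prolonged arrest.
#'
#' @param image A [scan_image()].
#' @param truth Ground-truth chamber mask (logical matrix); must be
#'   non-empty.
#' @param config A [phantom_config()].
#' @param seed Master seed (defaults to the config's); the actual draw uses a
#'   device substream keyed by the image identifiers.
#' @return A [tracing_overlay()] with source type `"device"`.
#' @export
simulate_device_tracing <- function(image, truth, config, seed = config$seed) {
  stopifnot(inherits(image, "scan_image"), inherits(config, "phantom_config"))
  if (!any(truth)) stop("truth mask is empty: nothing to trace", call. = FALSE)
  sd <- config$tracer_jitter_sd[[image$state]]
  sub <- substream_seed(seed, image$animal_id, image$ics, image$state,
                        image$scan_index, image$plane_index, "device")
  region <- with_seed(sub, {
    reg <- jittered_region(truth, sd)
    if (image$state == "late_arrest") {
      reg <- reg & !echogenic_within(image, truth)
      reg <- largest_component(reg)
    }
    reg
  })
  overlay_from_mask(region, "device", "device", image_ref(image))
}

#' Simulate an expert reviewer's free tracing
#'
#' Reviewers trace the full chamber outline — including echogenic clot, which
#' they interpret as being within the heart — with radial jitter of standard
#' deviation `config$reviewer_jitter_sd[reviewer_id]`. Different reviewers
#' (and the device) draw from independent substreams of the same seed.
#'
#' @inheritParams simulate_device_tracing
#' @param reviewer_id One of the reviewer ids named in
#'   `config$reviewer_jitter_sd`.
#' @return A [tracing_overlay()] with source type `"reviewer"`.
#' @export
simulate_reviewer_tracing <- function(image, truth, reviewer_id, config,
                                      seed = config$seed) {
  stopifnot(inherits(image, "scan_image"), inherits(config, "phantom_config"))
  if (!any(truth)) stop("truth mask is empty: nothing to trace", call. = FALSE)
  if (!reviewer_id %in% names(config$reviewer_jitter_sd))
    stop(sprintf("reviewer_id: '%s' is not one of the configured reviewers (%s)",
                 reviewer_id, paste(names(config$reviewer_jitter_sd), collapse = ", ")),
         call. = FALSE)
  sd <- config$reviewer_jitter_sd[[reviewer_id]]
  sub <- substream_seed(seed, image$animal_id, image$ics, image$state,
                        image$scan_index, image$plane_index, "reviewer", reviewer_id)
  region <- with_seed(sub, jittered_region(truth, sd))
  overlay_from_mask(region, "reviewer", reviewer_id, image_ref(image))
}

# canonical identifier string for a scan image
image_ref <- function(image) {
  paste(image$animal_id, image$ics, image$state, image$scan_index,
        image$plane_index, sep = "_")
}

#' Render a tracing overlay onto an image
#'
#' @param image A [scan_image()], a grayscale matrix (0..255), or an RGB
#'   array `height x width x 3`.
#' @param overlay A [tracing_overlay()].
#' @return RGB array `height x width x 3` with the curve pixels set to the
#'   overlay colour.
#' @export
render_tracing <- function(image, overlay) {
  rgb <- as_rgb_array(image)
  stopifnot(inherits(overlay, "tracing_overlay"))
  cp <- overlay$curve_pixels
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  if (nrow(cp) && (max(cp[, 1]) > h || max(cp[, 2]) > w))
    stop("overlay is not registered to this image (coordinates out of range)",
         call. = FALSE)
  for (ch in 1:3) rgb[cbind(cp, ch)] <- overlay$color[ch]
  rgb
}

# coerce scan_image / grayscale matrix / RGB array to an RGB array
as_rgb_array <- function(image) {
  if (inherits(image, "scan_image")) image <- image$pixels
  if (is.matrix(image)) {
    rgb <- array(0, c(nrow(image), ncol(image), 3))
    for (ch in 1:3) rgb[, , ch] <- image
    return(rgb)
  }
  if (is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3)
    return(image)
  stop("expected a scan_image, a grayscale matrix, or an RGB array", call. = FALSE)
}
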