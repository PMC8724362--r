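# ---- low-level raster geometry -------------------------------------------

# logical mask of an axis-aligned ellipse, clipped to the sector scan area
ellipse_mask <- function(config, scale = 1) {
  h <- config$image_height; w <- config$image_width
  a <- config$heart_semiaxes[1] * scale   # column semiaxis
  b <- config$heart_semiaxes[2] * scale   # row semiaxis
  rr <- matrix(seq_len(h), h, w) - config$heart_center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - config$heart_center[2]
  ((cc / a)^2 + (rr / b)^2 <= 1) & sector_mask(w, h)
}

# inner 4-boundary of a mask: pixels with at least one 4-neighbour outside
# (or on the raster edge); an 8-connected closed curve for solid regions
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  up    <- rbind(FALSE, mask[-h, , drop = FALSE])
  down  <- rbind(mask[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, mask[, -w, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  mask & !(up & down & left & right)
}

# centroid (row, col) of a mask
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# radial extent of a star-shaped mask around its centroid, evaluated on
# n_bins angle bins; empty bins are filled by periodic linear interpolation
radial_profile <- function(mask, center, n_bins = 720) {
  bidx <- which(mask_boundary(mask), arr.ind = TRUE)
  dr <- bidx[, 1] - center[1]; dc <- bidx[, 2] - center[2]
  th <- atan2(dc, dr)                      # (-pi, pi]
  rho <- sqrt(dr^2 + dc^2)
  bin <- pmin(n_bins, floor((th + pi) / (2 * pi) * n_bins) + 1)
  prof <- rep(NA_real_, n_bins)
  agg <- tapply(rho, bin, max)
  prof[as.integer(names(agg))] <- agg
  if (anyNA(prof)) {
    ok <- which(!is.na(prof))
    # wrap-around interpolation over missing bins
    x <- c(ok - n_bins, ok, ok + n_bins)
    y <- rep(prof[ok], 3)
    prof <- stats::approx(x, y, xout = seq_len(n_bins))$y
  }
  prof
}

# smooth periodic radial jitter: K iid Normal(0, sd) knots joined by a
# periodic spline, evaluated on the same n_bins grid as radial_profile
radial_jitter <- function(sd, n_bins = 720, n_knots = 24) {
  if (sd == 0) return(rep(0, n_bins))
  knots <- stats::rnorm(n_knots, 0, sd)
  x <- seq(0, 2 * pi, length.out = n_knots + 1)
  sp <- stats::spline(x, c(knots, knots[1]), method = "periodic",
                      xout = (seq_len(n_bins) - 0.5) / n_bins * 2 * pi)
  sp$y
}

# region whose boundary is the truth boundary perturbed radially by jitter;
# sd = 0 returns the truth mask itself (exactness contract)
jittered_region <- function(truth, sd, n_bins = 720) {
  if (sd == 0) return(truth)
  center <- mask_centroid(truth)
  prof <- radial_profile(truth, center, n_bins) + radial_jitter(sd, n_bins)
  h <- nrow(truth); w <- ncol(truth)
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  th <- atan2(cc, rr)
  bin <- pmin(n_bins, floor((th + pi) / (2 * pi) * n_bins) + 1)
  reg <- sqrt(rr^2 + cc^2) <= matrix(prof[bin], h, w)
  reg & sector_mask(w, h)
}

# largest 4-connected component of a mask (EBImage labelling)
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  labs <- EBImage::imageData(lab)
  if (max(labs) <= 1) return(mask)
  sizes <- tabulate(labs[labs > 0])
  t(labs == which.max(sizes))
}

# echogenic clot blobs: clot_count discs adjacent to the chamber boundary,
# grown/shrunk so their union covers clot_fraction of the truth area
clot_blobs <- function(truth, config) {
  target <- config$clot_fraction * sum(truth)
  if (target <= 0 || config$clot_count < 1) return(truth & FALSE)
  center <- mask_centroid(truth)
  prof <- radial_profile(truth, center)
  n <- config$clot_count
  phi <- stats::runif(n, -pi, pi)
  u <- stats::runif(n, 0.60, 0.92)
  bin <- pmin(720, floor((phi + pi) / (2 * pi) * 720) + 1)
  ctr_r <- center[1] + u * prof[bin] * cos(phi)
  ctr_c <- center[2] + u * prof[bin] * sin(phi)
  h <- nrow(truth); w <- ncol(truth)
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  r0 <- sqrt(target / (pi * n))
  for (iter in 1:4) {
    blobs <- truth & FALSE
    for (i in seq_len(n))
      blobs <- blobs | ((rr - ctr_r[i])^2 + (cc - ctr_c[i])^2 <= r0^2)
    blobs <- blobs & truth
    got <- sum(blobs)
    if (abs(got - target) / max(target, 1) < 0.02 || got == 0) break
    r0 <- r0 * sqrt(target / max(got, 1))
  }
  blobs
}

# ---- scan image / scan set ------------------------------------------------

#' Construct a single simulated B-mode image record
#'
#' @param pixels `height x width` numeric matrix of intensities in 0..255.
#' @param animal_id,ics,state,scan_index,plane_index Acquisition metadata.
#' @param rib_shadow_flag Whether the image carries a rib-shadow failure.
#' @return An object of class `scan_image`.
#' @export
scan_image <- function(pixels, animal_id, ics, state, scan_index, plane_index,
                       rib_shadow_flag = FALSE) {
  stopifnot(is.matrix(pixels))
  if (!state %in% STATES)
    stop(sprintf("state: '%s' is not one of %s", state,
                 paste(STATES, collapse = "/")), call. = FALSE)
  if (!ics %in% 4:8)
    stop(sprintf("ics: %s is outside the scanned range 4..8", ics), call. = FALSE)
  structure(list(pixels = pixels, animal_id = animal_id, ics = as.integer(ics),
                 state = state, scan_index = as.integer(scan_index),
                 plane_index = as.integer(plane_index),
                 rib_shadow_flag = isTRUE(rib_shadow_flag)),
            class = "scan_image")
}

# per-plane truth mask: pre-arrest scales the semiaxes around the cardiac
# cycle; arrest and late arrest are motionless
plane_truth_mask <- function(config, state, plane_index) {
  scale <- 1
  if (state == "pre_arrest")
    scale <- 1 + config$cycle_amplitude * sin(2 * pi * (plane_index - 1) / 12)
  ellipse_mask(config, scale)
}

# speckled phantom raster for one plane; clots must be given for late arrest
render_plane <- function(config, truth, clots, rib_shadow) {
  h <- config$image_height; w <- config$image_width
  base <- matrix(160, h, w)
  base[truth] <- 40
  if (!is.null(clots)) base[clots] <- 150
  sect <- sector_mask(w, h)
  if (rib_shadow) {
    half_band <- 0.075 * w
    cols <- abs(matrix(seq_len(w), h, w, byrow = TRUE) - config$heart_center[2]) <= half_band
    base[cols & sect] <- 20
  }
  noise <- matrix(stats::rnorm(h * w, 1, config$speckle_noise_sd / 160), h, w)
  img <- base * pmax(noise, 0)
  img[!sect] <- 0           # reserved background outside the scan sector
  matrix(pmin(pmax(round(img), 0), 255), h, w)
}

#' Generate one simulated biplane scan set
#'
#' Produces the 12 B-mode images (6 orthogonal biplane pairs) of one scan
#' plus the 12 ground-truth chamber masks. The physiologic state drives the
#' appearance: `pre_arrest` scales the chamber per image by
#' `1 + cycle_amplitude * sin(phase)` with phases spread over the 12 images;
#' `arrest` has fixed, crisp borders; `late_arrest` adds `clot_count`
#' echogenic blobs covering `clot_fraction` of the chamber. Each image
#' independently receives a rib shadow (vertical dark band over the heart)
#' with probability `rib_shadow_probability`, recorded in its
#' `rib_shadow_flag`. All randomness comes from substreams of `seed` keyed by
#' the identifiers, so outputs are reproducible in any generation order.
#'
#' @param config A [phantom_config()].
#' @param animal_id Animal identifier (e.g. `"a01"`).
#' @param ics Intercostal space, integer in 4..8.
#' @param state One of `"pre_arrest"`, `"arrest"`, `"late_arrest"`.
#' @param scan_index Scan number within the (animal, ICS, state) cell.
#' @param seed Master seed; defaults to the config's.
#' @return An object of class `scan_set`: list with `images` (12
#'   [scan_image()]s), `truth_masks` (12 logical matrices), and the shared
#'   metadata.
#' @examples
#' cfg <- phantom_config(128, 96, rib_shadow_probability = 0)
#' ss <- generate_scan_set(cfg, "a01", 5, "arrest", 1)
#' length(ss$images)
#' @export
generate_scan_set <- function(config, animal_id, ics, state, scan_index = 1L,
                              seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (!state %in% STATES)
    stop(sprintf("state: '%s' is not one of %s", state,
                 paste(STATES, collapse = "/")), call. = FALSE)
  if (!ics %in% 4:8)
    stop(sprintf("ics: %s is outside the scanned range 4..8", ics), call. = FALSE)
  images <- vector("list", 12)
  truths <- vector("list", 12)
  for (k in 1:12) {
    truth <- plane_truth_mask(config, state, k)
    clots <- NULL
    if (state == "late_arrest")
      clots <- with_seed(substream_seed(seed, animal_id, ics, state, scan_index, k, "clot"),
                         clot_blobs(truth, config))
    flag <- with_seed(substream_seed(seed, animal_id, ics, state, scan_index, k, "rib"),
                      stats::runif(1) < config$rib_shadow_probability)
    px <- with_seed(substream_seed(seed, animal_id, ics, state, scan_index, k, "img"),
                    render_plane(config, truth, clots, flag))
    images[[k]] <- scan_image(px, animal_id, ics, state, scan_index, k, flag)
    truths[[k]] <- truth
  }
  structure(list(images = images, truth_masks = truths, animal_id = animal_id,
                 ics = as.integer(ics), state = state,
                 scan_index = as.integer(scan_index)),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("scan_set: animal %s, ICS %d, %s, scan %d — 12 images (%d x %d)\n",
              x$animal_id, x$ics, x$state, x$scan_index,
              nrow(x$images[[1]]$pixels), ncol(x$images[[1]]$pixels)))
  invisible(x)
}

# rib-shadow flag for one image, without rendering its pixels; must match
# what generate_scan_set draws for the same identifiers
rib_flag_for <- function(config, animal_id, ics, state, scan_index, plane_index,
                         seed = config$seed) {
  with_seed(substream_seed(seed, animal_id, ics, state, scan_index, plane_index, "rib"),
            stats::runif(1) < config$rib_shadow_probability)
}
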