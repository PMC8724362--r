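STATES <- c("pre_arrest", "arrest", "late_arrest")

#' Phantom simulator configuration
#'
#' Bundles every tunable of the synthetic biplane scan generator. Geometric
#' defaults are derived from the raster size so the phantom heart (a dark,
#' hypoechoic chamber) sits well inside the sector scan area at any
#' resolution: the chamber centre lies on the sector axis at 55% of the
#' sector radius and the semiaxes are 28% (columns) and 20% (rows) of it.
#' Jitter defaults are fractions of the minor semiaxis, reflecting that
#' tracing error scales with the structure being traced: the simulated device
#' tracer is least noisy at arrest (crisp, motionless borders), noisier
#' pre-arrest (chamber size varies over the cardiac cycle), intermediate in
#' late arrest where the dominant failure mode is instead undertracing of
#' echogenic clot.
#'
#' @param image_width,image_height Raster size in pixels. The full-scale
#'   default (1616 x 1216, about 1.97 M pixels) matches the source device;
#'   tests and examples use small rasters such as 128 x 96.
#' @param heart_center Length-2 numeric, (row, col) of the chamber centre.
#' @param heart_semiaxes Length-2 numeric, (col semiaxis, row semiaxis) in
#'   pixels; both strictly positive and smaller than half the raster.
#' @param cycle_amplitude Pre-arrest per-image fractional scaling of the
#'   semiaxes, in `[0, 0.5]`.
#' @param clot_fraction Fraction of the chamber area rendered echogenic in
#'   late arrest, in `[0, 0.8]`.
#' @param clot_count Number of echogenic blobs (integer >= 0).
#' @param speckle_noise_sd Multiplicative speckle amplitude in intensity
#'   units at the background mean.
#' @param rib_shadow_probability Per-image probability of a rib-shadow
#'   acquisition failure, in `[0, 1]`.
#' @param tracer_jitter_sd Named numeric, radial tracing jitter (pixels) of
#'   the simulated device per physiologic state; names must be the three
#'   states.
#' @param reviewer_jitter_sd Named numeric, radial jitter (pixels) per
#'   reviewer id.
#' @param seed Integer master seed; identical config + seed gives
#'   bit-identical outputs.
#' @return An object of class `phantom_config`.
#' @examples
#' cfg <- phantom_config(128, 96)
#' cfg$heart_semiaxes
#' @export
phantom_config <- function(image_width = 1616, image_height = 1216,
                           heart_center = NULL, heart_semiaxes = NULL,
                           cycle_amplitude = 0.12, clot_fraction = 0.5,
                           clot_count = 4L, speckle_noise_sd = 25,
                           rib_shadow_probability = 0.05,
                           tracer_jitter_sd = NULL, reviewer_jitter_sd = NULL,
                           seed = 1L) {
  g <- sector_geometry(image_width, image_height)
  if (is.null(heart_center))
    heart_center <- c(g$apex_row + 0.55 * g$radius, g$apex_col)
  if (is.null(heart_semiaxes))
    heart_semiaxes <- c(0.28 * g$radius, 0.20 * g$radius)
  b <- min(heart_semiaxes)
  if (is.null(tracer_jitter_sd))
    tracer_jitter_sd <- c(pre_arrest = 0.14, arrest = 0.04, late_arrest = 0.08) * b
  if (is.null(reviewer_jitter_sd))
    reviewer_jitter_sd <- c(r1 = 0.04, r2 = 0.05, r3 = 0.06) * b
  cfg <- structure(list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    heart_center = as.numeric(heart_center),
    heart_semiaxes = as.numeric(heart_semiaxes),
    cycle_amplitude = cycle_amplitude,
    clot_fraction = clot_fraction,
    clot_count = as.integer(clot_count),
    speckle_noise_sd = speckle_noise_sd,
    rib_shadow_probability = rib_shadow_probability,
    tracer_jitter_sd = tracer_jitter_sd,
    reviewer_jitter_sd = reviewer_jitter_sd,
    seed = as.integer(seed)
  ), class = "phantom_config")
  validate_phantom_config(cfg)
}

validate_phantom_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(cfg$image_width >= 16 && cfg$image_height >= 16,
      "image_width/image_height: raster must be at least 16 x 16")
  frac <- function(x) is.numeric(x) && all(x >= 0) && all(x <= 1)
  chk(cfg$cycle_amplitude >= 0 && cfg$cycle_amplitude <= 0.5,
      "cycle_amplitude: must lie in [0, 0.5]")
  chk(cfg$clot_fraction >= 0 && cfg$clot_fraction <= 0.8,
      "clot_fraction: must lie in [0, 0.8]")
  chk(cfg$clot_count >= 0, "clot_count: must be >= 0")
  chk(frac(cfg$rib_shadow_probability),
      "rib_shadow_probability: must lie in [0, 1]")
  chk(length(cfg$heart_semiaxes) == 2 && all(cfg$heart_semiaxes > 0),
      "heart_semiaxes: both semiaxes must be strictly positive")
  chk(cfg$heart_semiaxes[1] < cfg$image_width / 2 &&
        cfg$heart_semiaxes[2] < cfg$image_height / 2,
      "heart_semiaxes: semiaxes must be smaller than half the image dimensions")
  chk(length(cfg$heart_center) == 2, "heart_center: must be (row, col)")
  chk(is.numeric(cfg$tracer_jitter_sd) && all(cfg$tracer_jitter_sd >= 0) &&
        setequal(names(cfg$tracer_jitter_sd), STATES),
      "tracer_jitter_sd: must be a non-negative value per state (pre_arrest, arrest, late_arrest)")
  chk(is.numeric(cfg$reviewer_jitter_sd) && all(cfg$reviewer_jitter_sd >= 0) &&
        length(cfg$reviewer_jitter_sd) >= 1 && !is.null(names(cfg$reviewer_jitter_sd)),
      "reviewer_jitter_sd: must be a named non-negative value per reviewer")
  chk(is.numeric(cfg$speckle_noise_sd) && cfg$speckle_noise_sd >= 0,
      "speckle_noise_sd: must be >= 0")
  cfg
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("phantom_config: %d x %d raster, heart semiaxes (%.1f, %.1f) px\n",
              x$image_width, x$image_height, x$heart_semiaxes[1], x$heart_semiaxes[2]))
  cat(sprintf("  cycle_amplitude %.3f, clot_fraction %.2f (%d blobs), rib shadow p = %.3f\n",
              x$cycle_amplitude, x$clot_fraction, x$clot_count, x$rib_shadow_probability))
  cat("  tracer jitter sd (px):",
      paste(sprintf("%s %.2f", names(x$tracer_jitter_sd), x$tracer_jitter_sd), collapse = ", "), "\n")
  cat("  reviewers:",
      paste(sprintf("%s %.2f", names(x$reviewer_jitter_sd), x$reviewer_jitter_sd), collapse = ", "), "\n")
  invisible(x)
}

#' Read or write a phantom configuration as YAML
#'
#' The YAML document mirrors the `phantom_config` field names exactly;
#' `tracer_jitter_sd` and `reviewer_jitter_sd` are maps. Unknown keys are
#' rejected (typo guard) and omitted optional fields take the documented
#' defaults.
#'
#' @param path File path.
#' @param config A `phantom_config`.
#' @return `read_phantom_config()` returns a validated `phantom_config`;
#'   `write_phantom_config()` returns `path` invisibly.
#' @export
read_phantom_config <- function(path) {
  doc <- yaml::read_yaml(path)
  phantom_config_from_list(doc)
}

phantom_config_from_list <- function(doc) {
  known <- names(formals(phantom_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown phantom_config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  for (f in c("tracer_jitter_sd", "reviewer_jitter_sd"))
    if (!is.null(doc[[f]])) doc[[f]] <- unlist(doc[[f]])
  do.call(phantom_config, doc)
}

#' @rdname read_phantom_config
#' @export
write_phantom_config <- function(config, path) {
  stopifnot(inherits(config, "phantom_config"))
  doc <- unclass(config)
  doc$tracer_jitter_sd <- as.list(doc$tracer_jitter_sd)
  doc$reviewer_jitter_sd <- as.list(doc$reviewer_jitter_sd)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Study run configuration
#'
#' Everything needed to reproduce a full simulated study: the phantom
#' configuration, the acquisition design (animals, states, intercostal
#' spaces, scans per space), the per-state sampling quota, the reviewer
#' panel, and the master seed.
#'
#' @param phantom A [phantom_config()].
#' @param quota_per_state Images retained per physiologic state (>= 1).
#' @param reviewers Named numeric of radial jitter sd (pixels) per reviewer
#'   id; defaults to the phantom config's reviewer panel.
#' @param n_animals Number of animals (>= 1).
#' @param states Character vector of physiologic states to acquire.
#' @param ics Intercostal spaces scanned, each in 4..8.
#' @param scans_per_ics Repeat scans per (animal, ICS, state).
#' @param master_seed Integer seed governing every random stage.
#' @param render_sample_size Number of agreement renderings written by
#'   [run_study()] when an output directory is given.
#' @param output_dir Optional default output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(), quota_per_state = 50L,
                       reviewers = NULL, n_animals = 7L, states = STATES,
                       ics = 4:8, scans_per_ics = 1L, master_seed = 1L,
                       render_sample_size = 3L, output_dir = NULL) {
  if (is.null(reviewers)) reviewers <- phantom$reviewer_jitter_sd
  cfg <- structure(list(
    phantom = phantom, quota_per_state = as.integer(quota_per_state),
    reviewers = reviewers, n_animals = as.integer(n_animals),
    states = states, ics = as.integer(ics),
    scans_per_ics = as.integer(scans_per_ics),
    master_seed = as.integer(master_seed),
    render_sample_size = as.integer(render_sample_size),
    output_dir = output_dir
  ), class = "run_config")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(inherits(cfg$phantom, "phantom_config"), "phantom: must be a phantom_config")
  chk(cfg$quota_per_state >= 1, "quota_per_state: must be >= 1")
  chk(length(cfg$reviewers) >= 1 && !is.null(names(cfg$reviewers)),
      "reviewers: at least one named reviewer is required")
  chk(all(cfg$reviewers >= 0), "reviewers: jitter sd must be >= 0")
  chk(cfg$n_animals >= 1, "n_animals: must be >= 1")
  chk(length(cfg$states) >= 1 && all(cfg$states %in% STATES),
      "states: must be a non-empty subset of pre_arrest/arrest/late_arrest")
  chk(all(cfg$ics %in% 4:8), "ics: intercostal spaces must lie in 4..8")
  chk(cfg$scans_per_ics >= 1, "scans_per_ics: must be >= 1")
  chk(cfg$render_sample_size >= 0, "render_sample_size: must be >= 0")
  cfg
}

#' Validate a study configuration document
#'
#' Parses a YAML document (or an already-parsed list) into a [run_config()],
#' checking every invariant, injecting documented defaults for omitted
#' optional fields, and rejecting unknown keys.
#'
#' @param document Path to a YAML file, or a named list.
#' @return A validated `run_config`.
#' @export
validate_config <- function(document) {
  doc <- if (is.character(document)) yaml::read_yaml(document) else document
  if (!is.list(doc)) stop("config document must be a YAML mapping", call. = FALSE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(doc$phantom)) doc$phantom <- phantom_config_from_list(doc$phantom)
  if (!is.null(doc$reviewers)) doc$reviewers <- unlist(doc$reviewers)
  do.call(run_config, doc)
}

#' @rdname validate_config
#' @param config A `run_config`.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  doc <- unclass(config)
  doc$phantom <- unclass(doc$phantom)
  doc$phantom$tracer_jitter_sd <- as.list(doc$phantom$tracer_jitter_sd)
  doc$phantom$reviewer_jitter_sd <- as.list(doc$phantom$reviewer_jitter_sd)
  doc$reviewers <- as.list(doc$reviewers)
  doc$output_dir <- NULL
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
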