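#' Example acquisition design for the recorded study layout
#'
#' Enumerates a plausible acquisition layout — animals `a01..a07`,
#' intercostal spaces 4..8, the three physiologic states, up to three repeat
#' scans per cell — in a fixed order and truncates it to `n_sets` scan sets.
#' Useful for acquisition arithmetic on set counts that do not factor evenly
#' into a full factorial design.
#'
#' @param n_sets Number of scan sets (rows), at most 315.
#' @return Data frame with columns `animal_id`, `ics`, `state`,
#'   `scan_index`, suitable as the `design` argument of [generate_study()].
#' @examples
#' nrow(example_recorded_design(69))
#' @export
example_recorded_design <- function(n_sets) {
  full <- expand.grid(scan_index = 1:3, state = STATES, ics = 4:8,
                      animal_id = sprintf("a%02d", 1:7),
                      stringsAsFactors = FALSE)
  full <- full[order(full$animal_id, full$ics, full$state, full$scan_index), ]
  if (n_sets < 1 || n_sets > nrow(full))
    stop(sprintf("n_sets must lie in 1..%d", nrow(full)), call. = FALSE)
  out <- full[seq_len(n_sets), c("animal_id", "ics", "state", "scan_index")]
  rownames(out) <- NULL
  out
}

# fixed seed under which the packaged screening fixture reproduces the
# study's screening log
SCREENING_FIXTURE_SEED <- 2201L

#' Packaged screening fixture reproducing the study screening log
#'
#' Builds the eligible-image manifest of the simulated study: 23 eligible
#' (animal, intercostal space) pairs x 3 physiologic states x 12 images =
#' 828 eligible images, with rib-shadow flags placed on ten deterministically
#' chosen images among the first 150 screened under the fixture seed. Running
#' [screen_and_sample()] on it at quota 50 per state with the same seed
#' therefore screens 160 images, excludes the 10 flagged ones, and retains
#' exactly 150 (50 per state).
#'
#' @return List with `manifest` (828-row data frame) and `seed` (the integer
#'   screening seed the fixture is calibrated to).
#' @examples
#' fx <- example_screening_manifest()
#' scr <- screen_and_sample(fx$manifest, 50, fx$seed)
#' scr$n_screened
#' @export
example_screening_manifest <- function() {
  pairs <- expand.grid(ics = 4:8, animal_id = sprintf("a%02d", 1:7),
                       stringsAsFactors = FALSE)
  pairs <- pairs[seq_len(23), ]   # spaces where LV/LVOT was visualized
  design <- merge(pairs, data.frame(state = STATES), by = NULL)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    d <- design[i, ]
    data.frame(animal_id = d$animal_id, ics = d$ics, state = d$state,
               scan_index = 1L, plane_index = 1:12, rib_shadow_flag = FALSE,
               image_path = sprintf("%s_ics%d_%s_scan1_plane%02d.png",
                                    d$animal_id, d$ics, d$state, 1:12),
               truth_path = NA_character_, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  # place the ten rib-shadow failures among the first 150 images screened
  # under the fixture seed, so the seeded pass reproduces the screening log
  clean <- screen_and_sample(manifest, 50, SCREENING_FIXTURE_SEED)
  flagged_paths <- clean$retained$image_path[c(3, 17, 29, 41, 58, 76, 90,
                                               113, 129, 144)]
  manifest$rib_shadow_flag[manifest$image_path %in% flagged_paths] <- TRUE
  list(manifest = manifest, seed = SCREENING_FIXTURE_SEED)
}
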