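#' Eligibility labels from the anatomical survey
#'
#' Each scanned (animal, intercostal space) pair is labelled with the
#' cardiac anatomy visualized there (`aortic_root`, `lvot`, `lv`, `apex`).
#' Analysis is narrowed to spaces where the left ventricle or LV outflow
#' tract was seen.
#'
#' @param animal_id,ics Vectors of equal length identifying the spaces.
#' @param visualized Character vector, anatomy per space as a
#'   semicolon-separated subset of `aortic_root;lvot;lv;apex` (non-empty).
#' @return A data frame of class `eligibility_labels`.
#' @export
eligibility_labels <- function(animal_id, ics, visualized) {
  stopifnot(length(animal_id) == length(ics), length(ics) == length(visualized))
  parts <- strsplit(visualized, ";", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) > 0 &&
                 all(p %in% c("aortic_root", "lvot", "lv", "apex")), logical(1))
  if (!all(ok))
    stop("visualized: each label must be a non-empty subset of aortic_root;lvot;lv;apex",
         call. = FALSE)
  structure(data.frame(animal_id = animal_id, ics = as.integer(ics),
                       visualized = visualized, stringsAsFactors = FALSE),
            class = c("eligibility_labels", "data.frame"))
}

#' Narrow a manifest to anatomically eligible images
#'
#' Retains exactly the images whose (animal, ICS) label includes `lv` or
#' `lvot`, mirroring the narrowing of analysis to spaces where those
#' structures were identified on the echocardiographic survey.
#'
#' @param manifest Data frame with at least `animal_id` and `ics` columns
#'   (one row per image, as emitted by [generate_study()]).
#' @param labels An [eligibility_labels()] covering every (animal, ICS) pair
#'   in the manifest; an unlabelled pair is an error naming it.
#' @return The manifest subset (possibly empty).
#' @export
select_eligible <- function(manifest, labels) {
  key <- paste(manifest$animal_id, manifest$ics)
  lkey <- paste(labels$animal_id, labels$ics)
  missing <- setdiff(unique(key), lkey)
  if (length(missing))
    stop("unlabelled (animal, ICS) pair(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  has_lv <- vapply(strsplit(labels$visualized, ";", fixed = TRUE),
                   function(p) any(p %in% c("lv", "lvot")), logical(1))
  manifest[key %in% lkey[has_lv], , drop = FALSE]
}

#' Randomized screening to a per-state quota with rib-shadow exclusion
#'
#' Images are drawn without replacement in a seeded random order. Each drawn
#' image whose state has not yet reached the quota is screened: images with
#' a rib-shadow flag are excluded and recorded; the rest are retained. The
#' draw stops when every state has reached the quota.
#'
#' @param manifest Eligible-image manifest (must carry `state` and
#'   `rib_shadow_flag` columns).
#' @param quota_per_state Images to retain per physiologic state.
#' @param seed Integer seed for the draw order.
#' @return List with `retained` and `excluded` manifest subsets (in screening
#'   order) and `n_screened = nrow(retained) + nrow(excluded)`.
#' @export
screen_and_sample <- function(manifest, quota_per_state, seed) {
  stopifnot(quota_per_state >= 1)
  ord <- with_seed(seed, sample.int(nrow(manifest)))
  states <- unique(manifest$state)
  got <- stats::setNames(integer(length(states)), states)
  retained <- integer(0); excluded <- integer(0)
  for (i in ord) {
    st <- manifest$state[i]
    if (got[[st]] >= quota_per_state) next
    if (isTRUE(manifest$rib_shadow_flag[i])) {
      excluded <- c(excluded, i)
    } else {
      retained <- c(retained, i)
      got[[st]] <- got[[st]] + 1
    }
    if (all(got >= quota_per_state)) break
  }
  short <- names(got)[got < quota_per_state]
  if (length(short))
    stop("insufficient eligible images for state(s): ",
         paste(short, collapse = ", "), call. = FALSE)
  list(retained = manifest[retained, , drop = FALSE],
       excluded = manifest[excluded, , drop = FALSE],
       n_screened = length(retained) + length(excluded))
}

#' Blind and shuffle the retained images for review
#'
#' Permutes the retained images with a seeded Fisher-Yates shuffle, then
#' assigns opaque zero-padded sequential codes in shuffled order (so code
#' order leaks nothing about acquisition order or state). The reviewer-facing
#' entries carry only the code and a coded path; the blinding key maps codes
#' back to the full metadata.
#'
#' @param retained Non-empty manifest subset from [screen_and_sample()].
#' @param seed Integer seed for the shuffle.
#' @return An object of class `study_manifest`: list with `entries`
#'   (data frame `image_code`, `image_path`), `blinding_key` (code plus
#'   `animal_id`, `state`, `ics`, `scan_index`, `plane_index`, and the source
#'   image path), and `seed`.
#' @export
blind_and_shuffle <- function(retained, seed) {
  if (nrow(retained) == 0) stop("retained list is empty", call. = FALSE)
  if (anyDuplicated(retained$image_path))
    stop("duplicate image paths in retained list", call. = FALSE)
  perm <- with_seed(seed, sample.int(nrow(retained)))
  shuffled <- retained[perm, , drop = FALSE]
  codes <- sprintf("IMG-%04d", seq_len(nrow(shuffled)))
  entries <- data.frame(image_code = codes,
                        image_path = file.path("packet", paste0(codes, ".png")),
                        stringsAsFactors = FALSE)
  key <- data.frame(image_code = codes,
                    animal_id = shuffled$animal_id, state = shuffled$state,
                    ics = shuffled$ics, scan_index = shuffled$scan_index,
                    plane_index = shuffled$plane_index,
                    source_path = shuffled$image_path,
                    stringsAsFactors = FALSE)
  structure(list(entries = entries, blinding_key = key, seed = as.integer(seed)),
            class = "study_manifest")
}

#' @rdname blind_and_shuffle
#' @param study_manifest A `study_manifest`.
#' @param code An image code present in the blinding key.
#' @return `decode_image()` returns the one-row metadata record for `code`.
#' @export
decode_image <- function(study_manifest, code) {
  key <- study_manifest$blinding_key
  hit <- key[key$image_code == code, , drop = FALSE]
  if (nrow(hit) != 1)
    stop(sprintf("image code '%s' is not in the blinding key", code), call. = FALSE)
  hit
}

#' Score every retained image against every reviewer
#'
#' Computes the pixel-wise confusion areas and Sorensen-Dice index of each
#' (image, reviewer) pair, comparing the reviewer's filled mask (reference)
#' against the device's (test). Records carry only blinded image codes.
#'
#' @param study_manifest A [blind_and_shuffle()] result.
#' @param device_masks Named list of logical masks, one per image code.
#' @param reviewer_masks Named list (one element per reviewer id) of named
#'   lists of logical masks by image code.
#' @return Data frame with columns `image_code`, `reviewer_id`, `tp`, `tn`,
#'   `fp`, `fn`, `sdi` — one row per (image, reviewer).
#' @export
score_study <- function(study_manifest, device_masks, reviewer_masks) {
  codes <- study_manifest$entries$image_code
  out <- vector("list", length(codes) * length(reviewer_masks))
  k <- 0
  for (code in codes) {
    dev <- device_masks[[code]]
    if (is.null(dev))
      stop(sprintf("missing device mask for image %s", code), call. = FALSE)
    for (rev in names(reviewer_masks)) {
      ref <- reviewer_masks[[rev]][[code]]
      if (is.null(ref))
        stop(sprintf("missing mask for image %s, reviewer %s", code, rev),
             call. = FALSE)
      ca <- confusion_areas(ref, dev)
      k <- k + 1
      out[[k]] <- data.frame(image_code = code, reviewer_id = rev,
                             tp = ca$tp, tn = ca$tn, fp = ca$fp, fn = ca$fn,
                             sdi = sdi(ca), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Aggregate concordance records into the per-state summary table
#'
#' Unblinds the records and summarises the Sorensen-Dice index per
#' (reviewer, physiologic state): mean and sample standard deviation
#' (n - 1 denominator) over that reviewer's images. A pooled row per state
#' gives the unweighted mean of the reviewer means, with the SD taken over
#' all (image, reviewer) pairs in the state.
#'
#' @param records Data frame from [score_study()].
#' @param blinding_key The blinding key from the [blind_and_shuffle()] step.
#' @return Data frame of class `state_summary` with columns `reviewer_id`
#'   (reviewer ids plus `"pooled"`), `state`, `mean_sdi`, `sd_sdi`,
#'   `n_images`.
#' @export
aggregate_concordance <- function(records, blinding_key) {
  idx <- match(records$image_code, blinding_key$image_code)
  if (anyNA(idx))
    stop("record(s) with image codes not in the blinding key: ",
         paste(unique(records$image_code[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  st <- blinding_key$state[idx]
  reviewers <- sort(unique(records$reviewer_id))
  states <- intersect(STATES, unique(st))
  rows <- list()
  for (s in states) {
    rev_means <- numeric(0)
    for (r in reviewers) {
      x <- records$sdi[records$reviewer_id == r & st == s]
      if (length(x) == 0)
        stop(sprintf("no records for reviewer %s in state %s", r, s), call. = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        reviewer_id = r, state = s, mean_sdi = mean(x),
        sd_sdi = if (length(x) > 1) stats::sd(x) else 0,
        n_images = length(x), stringsAsFactors = FALSE)
      rev_means <- c(rev_means, mean(x))
    }
    all_x <- records$sdi[st == s]
    rows[[length(rows) + 1]] <- data.frame(
      reviewer_id = "pooled", state = s, mean_sdi = mean(rev_means),
      sd_sdi = if (length(all_x) > 1) stats::sd(all_x) else 0,
      n_images = length(all_x) / length(reviewers), stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows), class = c("state_summary", "data.frame"))
}

#' @export
print.state_summary <- function(x, ...) {
  cat("Sorensen-Dice index by reviewer and physiologic state\n")
  wide <- format_state_summary(x)
  print.data.frame(wide, row.names = FALSE)
  invisible(x)
}

#' @rdname aggregate_concordance
#' @param summary A `state_summary`.
#' @return `format_state_summary()` returns a wide data frame, one row per
#'   reviewer (plus pooled), one `mean (SD)` column per state.
#' @export
format_state_summary <- function(summary) {
  reviewers <- unique(summary$reviewer_id)
  states <- unique(summary$state)
  wide <- data.frame(reviewer = reviewers, stringsAsFactors = FALSE)
  for (s in states) {
    cells <- vapply(reviewers, function(r) {
      row <- summary[summary$reviewer_id == r & summary$state == s, ]
      sprintf("%.3f (%.3f)", row$mean_sdi, row$sd_sdi)
    }, character(1))
    wide[[s]] <- cells
  }
  wide
}
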