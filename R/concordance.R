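#' Pixel-wise confusion areas between two binary masks
#'
#' Compares a reference mask (the human reviewer tracing, the known-truth
#' sample) against a test mask (the device tracing, the estimated-truth
#' sample) pixel by pixel over the evaluable region: `tp` pixels traced by
#' both, `fn` traced by the reviewer but missed by the device, `fp` traced
#' only by the device, `tn` the remainder. Counts are restricted to the
#' sector scan area, so `tp + tn + fp + fn` equals the sector pixel count.
#'
#' @param reference,test Logical mask matrices of identical dimensions.
#' @param sector Optional logical matrix delimiting the evaluable region;
#'   defaults to the sector implied by the mask dimensions. Pass
#'   `matrix(TRUE, ...)` to evaluate over the full rectangle instead.
#' @return An object of class `confusion_areas` with fields `tp`, `tn`,
#'   `fp`, `fn`, `total`.
#' @examples
#' a <- matrix(FALSE, 96, 128); a[40:60, 50:80] <- TRUE
#' b <- a; b[40:45, ] <- FALSE
#' confusion_areas(crop_to_scan_area(a), crop_to_scan_area(b))
#' @export
confusion_areas <- function(reference, test, sector = NULL) {
  if (!identical(dim(reference), dim(test)))
    stop(sprintf("shape mismatch: reference is %s but test is %s",
                 paste(dim(reference), collapse = " x "),
                 paste(dim(test), collapse = " x ")), call. = FALSE)
  if (is.null(sector)) sector <- sector_mask(ncol(reference), nrow(reference))
  if (!identical(dim(sector), dim(reference)))
    stop(sprintf("shape mismatch: masks are %s but sector is %s",
                 paste(dim(reference), collapse = " x "),
                 paste(dim(sector), collapse = " x ")), call. = FALSE)
  r <- reference & sector
  t_ <- test & sector
  tp <- sum(r & t_)
  fn <- sum(r & !t_)
  fp <- sum(!r & t_)
  total <- sum(sector)
  as_confusion_areas(tp, total - tp - fn - fp, fp, fn, total)
}

#' @rdname confusion_areas
#' @param tp,tn,fp,fn,total Counts (or area percentages on a common scale)
#'   to wrap directly into a `confusion_areas` object.
#' @export
as_confusion_areas <- function(tp, tn, fp, fn, total = tp + tn + fp + fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  if (abs(tp + tn + fp + fn - total) > 1e-9 * max(total, 1))
    stop("tp + tn + fp + fn must equal total", call. = FALSE)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, total = total),
            class = "confusion_areas")
}

#' @export
print.confusion_areas <- function(x, ...) {
  cat(sprintf("confusion_areas: TP %s, TN %s, FP %s, FN %s (total %s)\n",
              x$tp, x$tn, x$fp, x$fn, x$total))
  invisible(x)
}

#' Sorensen-Dice index of agreement
#'
#' `2 TP / (2 TP + FP + FN)`, equivalently `2|A n B| / (|A| + |B|)`: 1 is
#' perfect agreement (no false positives or negatives), 0 is no overlap.
#' Both masks empty leaves the index undefined and is an error — it flags an
#' upstream fill failure rather than being silently scored.
#'
#' @param areas A [confusion_areas()] object (counts or percentages; the
#'   index is scale-free).
#' @return The index, a dimensionless value in `[0, 1]`.
#' @examples
#' sdi(as_confusion_areas(tp = 11.304, tn = 83.450, fp = 0.172, fn = 5.074))
#' @export
sdi <- function(areas) {
  stopifnot(inherits(areas, "confusion_areas"))
  denom <- 2 * areas$tp + areas$fp + areas$fn
  if (denom == 0)
    stop("undefined SDI: both masks are empty (tp = fp = fn = 0)", call. = FALSE)
  2 * areas$tp / denom
}

#' Confusion areas as percentages of the evaluable region
#'
#' Each count divided by the total sector area, times 100, rounded
#' half-away-from-zero to 3 decimal places (the printing convention of the
#' agreement renderings). The four rounded values sum to 100 within 0.002.
#'
#' @param areas A [confusion_areas()] with `total > 0`.
#' @return Named numeric vector `(tp, tn, fp, fn)` in percent.
#' @export
area_percentages <- function(areas) {
  stopifnot(inherits(areas, "confusion_areas"))
  if (areas$total <= 0) stop("total must be > 0", call. = FALSE)
  raw <- c(tp = areas$tp, tn = areas$tn, fp = areas$fp, fn = areas$fn) /
    areas$total * 100
  round_half_up(raw, 3)
}

# round half away from zero (round() uses round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Four-colour pixel agreement rendering
#'
#' The visual counterpart of [confusion_areas()]: true positive yellow,
#' true negative white, false positive (device only) red, false negative
#' (reviewer only) green; pixels outside the sector scan area black. The
#' per-colour pixel census equals the confusion counts exactly.
#'
#' @inheritParams confusion_areas
#' @return RGB array `height x width x 3` with intensities 0..255.
#' @export
render_agreement <- function(reference, test, sector = NULL) {
  if (!identical(dim(reference), dim(test)))
    stop(sprintf("shape mismatch: reference is %s but test is %s",
                 paste(dim(reference), collapse = " x "),
                 paste(dim(test), collapse = " x ")), call. = FALSE)
  if (is.null(sector)) sector <- sector_mask(ncol(reference), nrow(reference))
  h <- nrow(reference); w <- ncol(reference)
  r <- reference & sector; t_ <- test & sector
  red <- matrix(0, h, w); green <- matrix(0, h, w); blue <- matrix(0, h, w)
  tp <- r & t_; tn <- sector & !r & !t_; fp <- !r & t_; fn <- r & !t_
  red[tp] <- 255; green[tp] <- 255                      # yellow
  red[tn] <- 255; green[tn] <- 255; blue[tn] <- 255     # white
  red[fp] <- 255                                        # red
  green[fn] <- 255                                      # green
  out <- array(0, c(h, w, 3))
  out[, , 1] <- red; out[, , 2] <- green; out[, , 3] <- blue
  out
}
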