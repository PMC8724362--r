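#' Read and write raster images
#'
#' PNG is the canonical lossless interchange format (grayscale, RGB, and
#' binary masks); TIFF is accepted for input when the `tiff` package is
#' available. Grayscale rasters are `height x width` matrices and RGB
#' rasters `height x width x 3` arrays, both with intensities 0..255.
#' Binary masks are written as grayscale PNGs with values {0, 255} and read
#' back exactly.
#'
#' @param path File path; format decided by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param raster Matrix or RGB array with intensities 0..255, or a logical
#'   mask for `write_mask()`.
#' @return `read_raster()` returns a matrix or array of intensities 0..255;
#'   `read_mask()` a logical matrix; the writers return `path` invisibly.
#' @export
read_raster <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read raster: file '%s' does not exist", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  dat <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop(sprintf("cannot read '%s': TIFF support requires the tiff package", path),
             call. = FALSE)
      tiff::readTIFF(path)
    },
    stop(sprintf("cannot read '%s': unsupported format '.%s' (PNG or TIFF expected)",
                 path, ext), call. = FALSE)
  )
  if (length(dim(dat)) == 3 && dim(dat)[3] == 4) dat <- dat[, , 1:3]  # drop alpha
  if (length(dim(dat)) == 3 && dim(dat)[3] == 2) dat <- dat[, , 1]    # gray+alpha
  round(dat * 255)
}

#' @rdname read_raster
#' @export
write_raster <- function(raster, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext != "png")
    stop(sprintf("cannot write '%s': PNG is the only supported output format", path),
         call. = FALSE)
  png::writePNG(pmin(pmax(raster, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname read_raster
#' @export
write_mask <- function(raster, path) {
  stopifnot(is.logical(raster))
  write_raster(raster * 255, path)
}

#' @rdname read_raster
#' @export
read_mask <- function(path) {
  read_raster(path) > 127
}

# deterministic CSV writer: fixed encoding, LF line endings, no quoting of
# numeric fields — identical input gives byte-identical files
write_table_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
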