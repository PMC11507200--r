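## Raster I/O and slide splitting.
##
## Internal representation: integer array h x w x 3, values 0..255.

#' Validate an RGB image array
#'
#' @param image object to check.
#' @return the image, invisibly, after validation.
#' @keywords internal
validate_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an array of dimension height x width x 3", call. = FALSE)
  if (dim(image)[1] < 1L || dim(image)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  rng <- range(image)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
    stop("image channel values must lie in [0, 255] with no NA", call. = FALSE)
  invisible(image)
}

validate_mask <- function(mask, image = NULL) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!is.null(image) && !identical(dim(mask), dim(image)[1:2]))
    stop("mask dimensions do not match image dimensions", call. = FALSE)
  invisible(mask)
}

## Convert a [0,1] double array as returned by png/tiff/jpeg readers to the
## internal 0..255 integer representation; grayscale replicated, alpha dropped.
.from_unit_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  nc <- dim(x)[3]
  if (nc == 1L) x <- x[, , c(1L, 1L, 1L), drop = FALSE]
  if (nc == 2L) x <- x[, , c(1L, 1L, 1L), drop = FALSE]  # gray + alpha
  if (nc >= 4L) x <- x[, , 1:3, drop = FALSE]
  img <- array(as.integer(round(x[, , 1:3, drop = FALSE] * 255)), dim = c(dim(x)[1:2], 3L))
  img
}

#' Read an RGB raster image
#'
#' Reads a PNG, TIFF or JPEG file into an 8-bit RGB array.  Grayscale images
#' are replicated across the three channels; an alpha channel, if present, is
#' dropped.  16-bit TIFF values are rescaled to 0-255 (`round(v * 255 / 65535)`).
#'
#' @param path path to a PNG, TIFF or JPEG file.
#' @return integer array `height x width x 3`, values 0-255.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_image(array(255L, dim = c(2, 2, 3)), f)
#' img <- read_image(f)
#' stopifnot(all(img == 255L))
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '.", ext, "' (expected PNG, TIFF or JPEG): ",
         path, call. = FALSE)
  )
  validate_image(.from_unit_array(x))
}

#' Write an RGB image losslessly
#'
#' Writes the internal 8-bit array to PNG or TIFF.  JPEG output is refused:
#' intermediate and final masks must not pass through a lossy codec.
#'
#' @param image integer array `height x width x 3`, values 0-255.
#' @param path destination path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  validate_image(image)
  ext <- tolower(tools::file_ext(path))
  x <- image / 255
  switch(ext,
    png  = png::writePNG(x, path),
    tif  = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    jpg  = ,
    jpeg = stop("JPEG output is lossy and not allowed; write PNG or TIFF",
                call. = FALSE),
    stop("unsupported output format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

.validate_bounds <- function(bounds, extent) {
  if (is.numeric(bounds) && length(bounds) == 2L) bounds <- list(bounds)
  if (!is.list(bounds) || length(bounds) < 1L)
    stop("bounds must be a non-empty list of c(start, end) pairs", call. = FALSE)
  m <- t(vapply(bounds, function(b) {
    if (length(b) != 2L || any(is.na(b))) stop("each boundary is c(start, end)", call. = FALSE)
    as.integer(b)
  }, integer(2)))
  if (any(m[, 1] < 0L) || any(m[, 2] > extent) || any(m[, 1] >= m[, 2]))
    stop("boundaries must satisfy 0 <= start < end <= ", extent, call. = FALSE)
  o <- order(m[, 1])
  if (nrow(m) > 1L && any(m[o, 2][-nrow(m)] > m[o, 1][-1]))
    stop("boundaries overlap", call. = FALSE)
  m
}

#' Split a multi-section slide image into single-section images
#'
#' Cuts a scanned slide holding several tissue sections into one image per
#' boundary, as verbatim pixel-for-pixel crops: no interpolation, no
#' rescaling, no change in resolution.  Boundaries are 0-based half-open
#' `[start, end)` intervals along the chosen axis, must not overlap, and when
#' they tile the image the sub-images concatenate back to it exactly.
#'
#' @param image RGB array.
#' @param bounds list of `c(start, end)` integer pairs (0-based, half-open);
#'   a single `c(start, end)` vector is accepted.
#' @param axis `"row"` to cut horizontal strips (the usual layout of several
#'   sections stacked vertically on a slide) or `"column"`.
#' @return list of RGB arrays, one per boundary, in the given order.
#' @seealso [auto_split_bounds()] for deriving boundaries from tissue content.
#' @export
split_image <- function(image, bounds, axis = c("row", "column")) {
  validate_image(image)
  axis <- match.arg(axis)
  extent <- if (axis == "row") dim(image)[1] else dim(image)[2]
  m <- .validate_bounds(bounds, extent)
  lapply(seq_len(nrow(m)), function(i) {
    idx <- (m[i, 1] + 1L):m[i, 2]
    if (axis == "row") image[idx, , , drop = FALSE] else image[, idx, , drop = FALSE]
  })
}

#' Derive split boundaries from tissue content
#'
#' Convenience helper beyond plain splitting: projects the tissue mask onto
#' the split axis and cuts at background valleys (runs of tissue-free lines),
#' yielding one boundary per tissue band.  Useful to seed [split_image()]
#' when section positions are unknown.
#'
#' @param image RGB slide scan.
#' @param axis `"row"` or `"column"`.
#' @param params [stain_params()] used for background detection (any stain).
#' @param pad lines of margin added on each side of a band (clamped to the
#'   image and to the neighbouring valley midpoint).
#' @return list of `c(start, end)` boundaries (0-based, half-open).
#' @export
auto_split_bounds <- function(image, axis = c("row", "column"),
                              params = stain_params("mts"), pad = 2L) {
  validate_image(image)
  axis <- match.arg(axis)
  tis <- tissue_mask(image, params, clean = TRUE)
  prof <- if (axis == "row") rowSums(tis) else colSums(tis)
  runs <- rle(prof > 0)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  bands <- which(runs$values)
  if (length(bands) == 0L) stop("no tissue found on the slide", call. = FALSE)
  lapply(bands, function(b) {
    c(max(starts[b] - 1L - pad, 0L), min(ends[b] + pad, length(prof)))
  })
}
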