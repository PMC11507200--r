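## Binary-mask post-processing: labeling, cropping, dilation, artifact
## removal, masked rendering.  Morphology is delegated to EBImage; component
## labeling upgrades EBImage's 4-connectivity to 8-connectivity by merging
## diagonally touching components.

.as_matrix <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

#' Label connected components (8-connectivity)
#'
#' Diagonal neighbours belong to the same component.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels, 0 = background, labels
#'   `1..n` in first-encounter order.
#' @export
label_components <- function(mask) {
  validate_mask(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(.as_matrix(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  k <- max(lab, 0L)
  if (k <= 1L) return(lab)
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nr <- nrow(lab); nc <- ncol(lab)
  merge_pairs <- function(a, b) {
    i <- which(a > 0L & b > 0L & a != b)
    for (j in i) {
      ra <- find(a[j]); rb <- find(b[j])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  if (nr > 1L && nc > 1L) {
    merge_pairs(lab[-nr, -nc], lab[-1, -1])   # down-right diagonal
    merge_pairs(lab[-nr, -1], lab[-1, -nc])   # down-left diagonal
  }
  roots <- vapply(seq_len(k), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Remove connected components below a minimum area
#'
#' @param mask logical matrix.
#' @param min_area minimum component size in pixels; components
#'   (8-connectivity) smaller than this are removed.  0 is the identity.
#' @return logical matrix.
#' @export
filter_small_components <- function(mask, min_area) {
  validate_mask(mask)
  if (min_area <= 0 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- sizes >= min_area
  out <- mask
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Fill enclosed holes in a mask
#'
#' @param mask logical matrix.
#' @return logical matrix with all fully enclosed background holes filled.
#' @export
fill_mask_holes <- function(mask) {
  validate_mask(mask)
  EBImage::imageData(EBImage::fillHull(.as_matrix(mask))) > 0
}

#' Restrict a mask to a rectangular region of interest
#'
#' Pixels outside the ROI are set to `FALSE`; the mask is not resized, so
#' pixel coordinates stay aligned with the source image.
#'
#' @param mask logical matrix.
#' @param roi `c(top, left, bottom, right)`, 0-based half-open rectangle.
#' @return logical matrix of the same dimensions.
#' @export
crop_to_roi <- function(mask, roi) {
  validate_mask(mask)
  roi <- .validate_roi(roi, dim(mask))
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  rows <- (roi[1] + 1L):roi[3]
  cols <- (roi[2] + 1L):roi[4]
  out[rows, cols] <- mask[rows, cols]
  out
}

.validate_roi <- function(roi, dims) {
  roi <- as.integer(roi)
  if (length(roi) != 4L || any(is.na(roi)))
    stop("roi must be c(top, left, bottom, right)", call. = FALSE)
  if (roi[1] < 0L || roi[2] < 0L || roi[3] > dims[1] || roi[4] > dims[2] ||
      roi[1] >= roi[3] || roi[2] >= roi[4])
    stop("roi must be a non-empty rectangle within the image ",
         "(0-based, half-open: 0 <= top < bottom <= ", dims[1],
         ", 0 <= left < right <= ", dims[2], ")", call. = FALSE)
  roi
}

#' Dilate a mask with a disc structuring element
#'
#' Discretization note: the radius-1 "disc" is the full 3x3 square (the
#' EBImage disc brush of size 3); radius 2 and above carve the corners.
#' Radius 0 is the identity.  Dilation is extensive: the input is always a
#' subset of the output.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels, `>= 0`.
#' @return logical matrix.
#' @export
dilate_mask <- function(mask, radius) {
  validate_mask(mask)
  if (length(radius) != 1L || is.na(radius) || radius < 0)
    stop("radius must be a single number >= 0", call. = FALSE)
  radius <- as.integer(radius)
  if (radius == 0L || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  EBImage::imageData(EBImage::dilate(.as_matrix(mask), brush)) > 0
}

## morphological closing with the same disc convention as dilate_mask
close_mask <- function(mask, radius) {
  radius <- as.integer(radius)
  if (radius <= 0L || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  EBImage::imageData(EBImage::closing(.as_matrix(mask), brush)) > 0
}

#' Remove artifacts from a mask
#'
#' Clears user-specified exclusion rectangles (e.g. a bubble trapped over
#' the section) and drops connected components smaller than `min_area`
#' pixels.  With no exclusions and `min_area = 0` this is the identity; the
#' operation is idempotent.
#'
#' @param mask logical matrix.
#' @param exclusion list of ROIs `c(top, left, bottom, right)` (0-based,
#'   half-open) to set `FALSE`; may be empty.
#' @param min_area minimum component size kept (8-connectivity).
#' @return logical matrix.
#' @export
remove_artifacts <- function(mask, exclusion = list(), min_area = 0) {
  validate_mask(mask)
  if (is.numeric(exclusion) && length(exclusion) == 4L) exclusion <- list(exclusion)
  for (roi in exclusion) {
    roi <- .validate_roi(roi, dim(mask))
    mask[(roi[1] + 1L):roi[3], (roi[2] + 1L):roi[4]] <- FALSE
  }
  filter_small_components(mask, min_area)
}

#' Paint masked pixels with a solid color
#'
#' Renders the mask onto the image, painting every masked pixel with the
#' given color (default white, the convention for the quantified infarct).
#'
#' @param image RGB array.
#' @param mask logical matrix matching the image.
#' @param color length-3 RGB triplet in 0-255.
#' @return RGB array with masked pixels painted.
#' @export
render_masked <- function(image, mask, color = c(255L, 255L, 255L)) {
  validate_image(image)
  validate_mask(mask, image)
  color <- as.integer(color)
  if (length(color) != 3L || any(is.na(color)) || any(color < 0L) || any(color > 255L))
    stop("color must be an RGB triplet in 0-255", call. = FALSE)
  out <- image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[mask] <- color[ch]
    out[, , ch] <- plane
  }
  out
}

#' Keep only masked pixels, blanking the rest
#'
#' Isolation rendering: pixels outside the mask are replaced with the
#' background color, pixels inside keep their original values.
#'
#' @inheritParams render_masked
#' @param background RGB triplet for non-masked pixels (default white).
#' @return RGB array.
#' @export
isolate_masked <- function(image, mask, background = c(255L, 255L, 255L)) {
  render_masked(image, !mask, background)
}
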