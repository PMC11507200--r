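#' Analyze one stained section end to end
#'
#' Runs the full single-section pipeline: tissue masking, stain-specific
#' infarct classification, optional ROI crop, artifact removal (exclusion
#' rectangles plus small-component cleanup) and optional dilation, then
#' quantifies the infarct.  The default `min_area = 16` removes speckle-size
#' components from the infarct mask; set it to 0 for the raw per-pixel
#' classification.  Dilation inflates the counted area, so the undilated
#' mask is counted unless `count_dilated = TRUE`; the choice is recorded in
#' the result.
#'
#' @param image RGB array, or a path readable by [read_image()].
#' @param stain `"mts"`, `"he"`, `"ttc"` or `"psr"`; ignored when `params`
#'   is given.
#' @param params a [stain_params()] object; defaults for `stain` if `NULL`.
#' @param crop optional ROI `c(top, left, bottom, right)` (0-based,
#'   half-open) restricting the infarct mask.
#' @param exclude list of exclusion ROIs (artifacts such as bubbles).
#' @param min_area minimum infarct component size in pixels (8-connectivity).
#' @param dilate_radius disc radius of the optional dilation, 0 for none.
#' @param count_dilated count the dilated mask (clipped to tissue) instead
#'   of the undilated one.
#' @param pixel_size optional Px in micrometers per pixel; physical areas
#'   are reported when given.
#' @return object of class `scar_analysis`: image, `tissue` and `infarct`
#'   masks (and `infarct_dilated` when dilation was requested), pixel
#'   counts, `relative_infarct_pct`, the parameters used, and physical
#'   areas when `pixel_size` was supplied.
#' @export
analyze_section <- function(image, stain = c("mts", "he", "ttc", "psr"),
                            params = NULL, crop = NULL, exclude = list(),
                            min_area = 16, dilate_radius = 0,
                            count_dilated = FALSE, pixel_size = NULL) {
  if (is.character(image)) image <- read_image(image)
  validate_image(image)
  if (is.null(params)) params <- stain_params(match.arg(stain))
  tissue <- tissue_mask(image, params)
  infarct <- classify_stain(image, params, tissue = tissue)
  if (!is.null(crop)) infarct <- crop_to_roi(infarct, crop)
  infarct <- remove_artifacts(infarct, exclusion = exclude, min_area = min_area)
  dilated <- NULL
  if (dilate_radius > 0) dilated <- dilate_mask(infarct, dilate_radius) & tissue
  counted <- if (count_dilated && !is.null(dilated)) dilated else infarct
  res <- list(
    stain = params$stain,
    params = params,
    image = image,
    tissue = tissue,
    infarct = infarct,
    infarct_dilated = dilated,
    counted_dilated = isTRUE(count_dilated) && !is.null(dilated),
    infarct_pixels = sum(counted),
    tissue_pixels = sum(tissue),
    relative_infarct_pct =
      if (sum(tissue) > 0) 100 * sum(counted) / sum(tissue) else NA_real_,
    pixel_size = pixel_size
  )
  if (!is.null(pixel_size)) {
    res$infarct_area_mm2 <- physical_area(res$infarct_pixels, pixel_size)
    res$tissue_area_mm2 <- physical_area(res$tissue_pixels, pixel_size)
  }
  class(res) <- "scar_analysis"
  res
}

#' @export
print.scar_analysis <- function(x, ...) {
  cat("Stained-section infarct analysis (", toupper(x$stain), ")\n", sep = "")
  cat(sprintf("  tissue pixels:  %d\n", x$tissue_pixels))
  cat(sprintf("  infarct pixels: %d%s\n", x$infarct_pixels,
              if (x$counted_dilated) " (dilated)" else ""))
  if (!is.na(x$relative_infarct_pct))
    cat(sprintf("  relative infarct size: %.1f%%\n", x$relative_infarct_pct))
  if (!is.null(x$pixel_size))
    cat(sprintf("  infarct area: %.3f mm^2, section area: %.3f mm^2 (Px = %g um)\n",
                x$infarct_area_mm2, x$tissue_area_mm2, x$pixel_size))
  invisible(x)
}

#' @export
summary.scar_analysis <- function(object, ...) print(object, ...)

#' Convert a section analysis to a measurement
#'
#' @param x a `scar_analysis`.
#' @param pixel_size Px in micrometers per pixel; defaults to the one used
#'   in the analysis (or 1).
#' @return a [section_measurement()].
#' @export
as_section_measurement <- function(x, pixel_size = NULL) {
  stopifnot(inherits(x, "scar_analysis"))
  if (is.null(pixel_size)) pixel_size <- if (is.null(x$pixel_size)) 1 else x$pixel_size
  section_measurement(x$infarct_pixels, x$tissue_pixels, pixel_size)
}

.plot_raster <- function(image, main = "") {
  img <- image / 255
  plot(c(0, ncol(img)), c(0, nrow(img)), type = "n", asp = 1,
       xlab = "", ylab = "", axes = FALSE, main = main)
  rasterImage(as.raster(img), 0, 0, ncol(img), nrow(img))
}

#' Plot a section analysis
#'
#' Shows the original section, the infarct masked in white, and the
#' whole-section mask, side by side (the masked-quantification layout).
#'
#' @param x a `scar_analysis`.
#' @param ... unused.
#' @export
plot.scar_analysis <- function(x, ...) {
  op <- par(mfrow = c(1, 3), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(par(op))
  .plot_raster(x$image, "original")
  shown <- if (!is.null(x$infarct_dilated)) x$infarct_dilated else x$infarct
  .plot_raster(render_masked(x$image, shown), "infarct masked")
  tis <- array(0L, dim = dim(x$image))
  .plot_raster(render_masked(tis, x$tissue), "section mask")
  invisible(x)
}

#' @export
plot.fibrosis_analysis <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(par(op))
  .plot_raster(x$isolated, sprintf("isolated fibrosis (%.1f%%)", x$pct))
  tis <- array(0L, dim = dim(x$isolated))
  .plot_raster(render_masked(tis, x$tissue), "section mask")
  invisible(x)
}
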