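## Relative infarct size, physical areas, serial-section volumes and
## diffuse-fibrosis fraction.
##
## Units: pixel size Px in micrometers per pixel, section thicknesses in
## micrometers, areas in mm^2, volumes in mm^3.

#' One section's pixel counts and geometry
#'
#' @param infarct_pixels number of infarct pixels in the section.
#' @param tissue_pixels number of tissue pixels in the entire section
#'   (background excluded; the denominator of the relative infarct size).
#' @param pixel_size pixel edge length Px in micrometers per pixel (pixels
#'   are assumed square).
#' @return object of class `section_measurement`.
#' @export
section_measurement <- function(infarct_pixels, tissue_pixels, pixel_size = 1) {
  infarct_pixels <- as.numeric(infarct_pixels)
  tissue_pixels <- as.numeric(tissue_pixels)
  if (is.na(infarct_pixels) || is.na(tissue_pixels) ||
      infarct_pixels < 0 || infarct_pixels > tissue_pixels)
    stop("need 0 <= infarct_pixels <= tissue_pixels", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0 (micrometers per pixel)", call. = FALSE)
  structure(list(infarct_pixels = infarct_pixels,
                 tissue_pixels = tissue_pixels,
                 pixel_size = pixel_size),
            class = "section_measurement")
}

#' Relative infarct size of one section
#'
#' `100 * infarct_pixels / tissue_pixels`, the percentage of the infarct
#' region relative to the entire section.
#'
#' @param m a [section_measurement()].
#' @return percentage in `[0, 100]`.
#' @export
relative_infarct_pct <- function(m) {
  stopifnot(inherits(m, "section_measurement"))
  if (m$tissue_pixels == 0)
    stop("relative infarct size is undefined: the section has no tissue pixels",
         call. = FALSE)
  100 * m$infarct_pixels / m$tissue_pixels
}

#' Physical area of a pixel count
#'
#' `Px^2 * pixels`, converted from square micrometers to mm^2 (divide by
#' 1e6).
#'
#' @param pixels pixel count.
#' @param pixel_size Px in micrometers per pixel.
#' @return area in mm^2.
#' @export
#' @examples
#' physical_area(1e6, 1)   # 1 mm^2
#' physical_area(4e5, 5)   # 10 mm^2
physical_area <- function(pixels, pixel_size) {
  if (!is.numeric(pixel_size) || any(pixel_size <= 0))
    stop("pixel_size must be > 0", call. = FALSE)
  if (any(pixels < 0)) stop("pixels must be >= 0", call. = FALSE)
  pixel_size^2 * pixels / 1e6
}

#' Serial sections with thickness metadata
#'
#' Orders per-section measurements (apex-to-base or base-to-apex, A1..An)
#' together with the stained-section thickness `h1` and the thickness `h2`
#' of tissue removed between consecutive stained sections.
#'
#' @param sections list of [section_measurement()] objects, in anatomical
#'   order.
#' @param h1 stained-section thickness in micrometers (> 0).
#' @param h2 removed-tissue thickness in micrometers (>= 0).
#' @return object of class `volume_stack`.
#' @export
volume_stack <- function(sections, h1, h2 = 0) {
  if (inherits(sections, "section_measurement")) sections <- list(sections)
  if (!is.list(sections) || length(sections) == 0 ||
      !all(vapply(sections, inherits, logical(1), "section_measurement")))
    stop("sections must be a non-empty list of section_measurement objects",
         call. = FALSE)
  if (!is.numeric(h1) || h1 <= 0) stop("h1 must be > 0 (micrometers)", call. = FALSE)
  if (!is.numeric(h2) || h2 < 0) stop("h2 must be >= 0 (micrometers)", call. = FALSE)
  structure(list(sections = sections, h1 = h1, h2 = h2), class = "volume_stack")
}

#' Infarct and tissue volume over serial sections
#'
#' Per section i with infarct area `A_si` and tissue area `A_ti` (mm^2, from
#' [physical_area()]), the stained-slab volumes are `V_si = A_si * h1` and
#' `V_ti = A_ti * h1`; the removed tissue between sections is assumed to
#' carry the same areas as the adjacent stained section, contributing
#' `V_rsi = A_si * h2` and `V_rti = A_ti * h2`.  Totals are the sums over
#' sections; the relative infarct volume is `100 * V_Ts / V_Tt`.
#'
#' The removed-gap handling is set by `gap_policy`: `"per-section"` (default)
#' lets every section contribute its own gap, so `V_Ts = sum(A_si) * (h1 +
#' h2)`; `"n-1"` attributes removed tissue only to the n - 1 gaps between
#' consecutive sections (the last section contributes `A_sn * h1` only).
#' The difference is exactly one gap's volume.
#'
#' @param stack a [volume_stack()].
#' @param gap_policy `"per-section"` or `"n-1"`.
#' @return object of class `volume_summary`: a list with `infarct_volume`
#'   (V_Ts, mm^3), `tissue_volume` (V_Tt, mm^3), `relative_volume_pct`,
#'   `gap_policy` and a per-section data frame `per_section` (areas in mm^2,
#'   volumes in mm^3, relative infarct size in %).
#' @export
stack_volumes <- function(stack, gap_policy = c("per-section", "n-1")) {
  stopifnot(inherits(stack, "volume_stack"))
  gap_policy <- match.arg(gap_policy)
  n <- length(stack$sections)
  A_s <- vapply(stack$sections, function(m) physical_area(m$infarct_pixels, m$pixel_size),
                numeric(1))
  A_t <- vapply(stack$sections, function(m) physical_area(m$tissue_pixels, m$pixel_size),
                numeric(1))
  h1_mm <- stack$h1 / 1000
  h2_mm <- stack$h2 / 1000
  gap <- if (gap_policy == "per-section") rep(h2_mm, n) else c(rep(h2_mm, n - 1), 0)
  V_s <- A_s * h1_mm
  V_rs <- A_s * gap
  V_t <- A_t * h1_mm
  V_rt <- A_t * gap
  V_Ts <- sum(V_s + V_rs)
  V_Tt <- sum(V_t + V_rt)
  if (V_Tt <= 0) stop("total tissue volume is zero; cannot form a relative volume",
                      call. = FALSE)
  per <- data.frame(
    section = seq_len(n),
    infarct_area_mm2 = A_s,
    tissue_area_mm2 = A_t,
    infarct_volume_mm3 = V_s + V_rs,
    tissue_volume_mm3 = V_t + V_rt,
    relative_infarct_pct = ifelse(A_t > 0, 100 * A_s / A_t, NA_real_)
  )
  structure(list(infarct_volume = V_Ts,
                 tissue_volume = V_Tt,
                 relative_volume_pct = 100 * V_Ts / V_Tt,
                 gap_policy = gap_policy,
                 h1 = stack$h1, h2 = stack$h2,
                 per_section = per),
            class = "volume_summary")
}

#' @export
print.volume_summary <- function(x, ...) {
  cat("Serial-section volume summary (", nrow(x$per_section), " sections, h1 = ",
      x$h1, " um, h2 = ", x$h2, " um, gaps: ", x$gap_policy, ")\n", sep = "")
  cat(sprintf("  infarct volume V_Ts: %.2f mm^3\n", x$infarct_volume))
  cat(sprintf("  tissue  volume V_Tt: %.2f mm^3\n", x$tissue_volume))
  cat(sprintf("  relative infarct volume: %.1f%%\n", x$relative_volume_pct))
  invisible(x)
}

#' Diffuse-fibrosis fraction of an MTS section
#'
#' Diffuse and patchy fibrosis is detected with the same blue-versus-red
#' color rule as the MTS infarct classifier, but with no minimum-component
#' filtering: scattered single-pixel collagen deposits are exactly what is
#' being measured.  Returns the fibrotic fraction of the whole tissue
#' section and an isolation rendering (fibrotic pixels on a blank
#' background) for inspecting the fibrosis distribution.
#'
#' @param image RGB array of an MTS-stained section.
#' @param params [stain_params()] with `stain = "mts"`.
#' @return object of class `fibrosis_analysis`: list with `pct`
#'   (percentage of tissue pixels that are fibrotic), `fibrosis_pixels`,
#'   `tissue_pixels`, `mask`, `tissue` and `isolated` (RGB array).
#' @export
fibrosis_pct <- function(image, params = stain_params("mts")) {
  validate_image(image)
  .needs_stain(params, "mts")
  tissue <- tissue_mask(image, params)
  if (!any(tissue))
    stop("fibrosis fraction is undefined: no tissue detected", call. = FALSE)
  fib <- classify_mts(image, params, tissue = tissue)
  structure(list(pct = 100 * sum(fib) / sum(tissue),
                 fibrosis_pixels = sum(fib),
                 tissue_pixels = sum(tissue),
                 mask = fib,
                 tissue = tissue,
                 isolated = isolate_masked(image, fib)),
            class = "fibrosis_analysis")
}

#' @export
print.fibrosis_analysis <- function(x, ...) {
  cat(sprintf("Diffuse fibrosis: %.1f%% of the tissue section (%d / %d pixels)\n",
              x$pct, x$fibrosis_pixels, x$tissue_pixels))
  invisible(x)
}
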