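#' Per-stain classification thresholds
#'
#' Bundles the thresholds that govern per-pixel infarct classification for
#' one staining technique.  Defaults are pre-set per stain and freely
#' adjustable by the user; they are engineering choices validated on
#' synthetic fixtures, chosen so that the characteristic palettes of each
#' stain fall clearly on the correct side of every rule.
#'
#' Active fields by stain:
#' * **MTS** — `r_limit` (upper limit on R for infarct; scar is blue, so its
#'   R is low) and `br_ratio_min` (lower limit on B/R, excluding faintly
#'   blue normal tissue; R = 0 counts as infinitely blue).
#' * **TTC** — `std_max` (upper limit on the per-pixel sample standard
#'   deviation of R, G, B; the off-white infarct has nearly equal channels,
#'   viable deep-red tissue does not).
#' * **PSR** — `thd` (minimum margin of R above `mean_GB = (G + B) / 2`;
#'   the collagen-rich infarct is saturated red, normal tissue pale).
#' * **H&E** — `r_limit` (channel-removal threshold of the two-step
#'   green-revealing transform), `he_close_radius` and `he_min_area_frac`
#'   (density filter keeping only large, dense green components).
#'
#' Fields used by every stain: `background_white_min` (a pixel whose three
#' channels all reach this value is slide background, not tissue),
#' `background_black_max` (channels all at or below this value are treated
#' as scanner void, not tissue), `background_saturation` (chroma
#' `max - min` at or above which a bright pixel is still considered
#' stained tissue), `tissue_min_area` and `tissue_fill_holes` (tissue-mask
#' cleanup, see [tissue_mask()]).
#'
#' @param stain one of `"mts"`, `"he"`, `"ttc"`, `"psr"` (case-insensitive).
#' @param ... named overrides of any field listed above.
#' @return an object of class `stain_params` (a named list).
#' @export
#' @examples
#' stain_params("mts")
#' stain_params("psr", thd = 55)
stain_params <- function(stain = c("mts", "he", "ttc", "psr"), ...) {
  stain <- match.arg(tolower(stain[1]), c("mts", "he", "ttc", "psr"))
  p <- list(
    stain = stain,
    r_limit = switch(stain, mts = 150, he = 200, NA_real_),
    br_ratio_min = if (stain == "mts") 1.2 else NA_real_,
    std_max = if (stain == "ttc") 20 else NA_real_,
    thd = if (stain == "psr") 40 else NA_real_,
    he_close_radius = if (stain == "he") 3L else NA_integer_,
    he_min_area_frac = if (stain == "he") 0.001 else NA_real_,
    background_white_min = 230,
    background_black_max = 10,
    background_saturation = 30,
    tissue_min_area = 64L,
    tissue_fill_holes = FALSE
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown stain_params field(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p <- utils::modifyList(p, over)
  }
  .check_range <- function(v, lo, hi, nm) {
    if (!is.na(v) && (v < lo || v > hi))
      stop("stain_params$", nm, " must lie in [", lo, ", ", hi, "]", call. = FALSE)
  }
  .check_range(p$r_limit, 0, 255, "r_limit")
  .check_range(p$thd, 0, 255, "thd")
  .check_range(p$background_white_min, 0, 255, "background_white_min")
  .check_range(p$background_black_max, 0, 255, "background_black_max")
  if (!is.na(p$br_ratio_min) && p$br_ratio_min < 0)
    stop("stain_params$br_ratio_min must be >= 0", call. = FALSE)
  if (!is.na(p$std_max) && p$std_max < 0)
    stop("stain_params$std_max must be >= 0", call. = FALSE)
  class(p) <- "stain_params"
  p
}

#' @export
print.stain_params <- function(x, ...) {
  cat("Stain classification thresholds (", toupper(x$stain), ")\n", sep = "")
  act <- switch(x$stain,
    mts = c("r_limit", "br_ratio_min"),
    he  = c("r_limit", "he_close_radius", "he_min_area_frac"),
    ttc = "std_max",
    psr = "thd")
  for (nm in act) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  %-22s %s\n", "background_white_min", format(x$background_white_min)))
  invisible(x)
}

.needs_stain <- function(params, stain) {
  if (!inherits(params, "stain_params"))
    stop("params must be created with stain_params()", call. = FALSE)
  if (params$stain != stain)
    stop("params$stain is '", params$stain, "' but this classifier requires '",
         stain, "'", call. = FALSE)
  invisible(params)
}
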