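## Per-pixel stain classifiers.
##
## Each rule operates on raw 8-bit RGB values; no color deconvolution, no
## learned models.  All classifiers return logical masks restricted to the
## tissue mask, so infarct masks are subsets of tissue by construction.

.channels <- function(image) {
  list(r = image[, , 1], g = image[, , 2], b = image[, , 3])
}

#' Whole-section tissue mask
#'
#' Separates stained tissue from the near-white slide background (and from
#' scanner void, i.e. near-black).  A pixel is tissue when it is not
#' near-white — `min(R,G,B) < background_white_min`, or bright but strongly
#' colored (`max - min >= background_saturation`) — and not near-black
#' (`max(R,G,B) > background_black_max`).  With `clean = TRUE`, connected
#' components (8-connectivity) smaller than `params$tissue_min_area` pixels
#' are dropped and, if `params$tissue_fill_holes`, enclosed holes are filled.
#' Hole filling is off by default so that ventricular cavities do not count
#' as tissue.
#'
#' @param image RGB array.
#' @param params [stain_params()] (any stain).
#' @param clean apply component-size cleanup (and optional hole filling).
#' @return logical matrix, `TRUE` on tissue.
#' @export
tissue_mask <- function(image, params = stain_params("mts"), clean = TRUE) {
  validate_image(image)
  ch <- .channels(image)
  mn <- pmin(ch$r, ch$g, ch$b)
  mx <- pmax(ch$r, ch$g, ch$b)
  tis <- (mn < params$background_white_min | (mx - mn) >= params$background_saturation) &
    mx > params$background_black_max
  dim(tis) <- dim(image)[1:2]
  if (clean) {
    if (params$tissue_min_area > 0 && any(tis))
      tis <- filter_small_components(tis, params$tissue_min_area)
    if (isTRUE(params$tissue_fill_holes) && any(tis))
      tis <- fill_mask_holes(tis)
  }
  tis
}

#' Infarct classification for Masson's trichrome (MTS)
#'
#' Scar collagen stains blue, viable myocardium red, so infarct pixels have
#' a low R value and a dominant B.  A pixel within tissue is infarct iff
#' `R <= r_limit` and `B / R >= br_ratio_min`; `R = 0` is treated as a ratio
#' of `+Inf` (maximally blue).
#'
#' @param image RGB array.
#' @param params [stain_params()] with `stain = "mts"`.
#' @param tissue optional precomputed [tissue_mask()]; computed if `NULL`.
#' @return logical infarct mask (subset of the tissue mask).
#' @export
classify_mts <- function(image, params = stain_params("mts"), tissue = NULL) {
  validate_image(image)
  .needs_stain(params, "mts")
  if (is.null(tissue)) tissue <- tissue_mask(image, params)
  validate_mask(tissue, image)
  ch <- .channels(image)
  ratio <- ifelse(ch$r > 0, ch$b / ch$r, Inf)
  m <- (ch$r <= params$r_limit) & (ratio >= params$br_ratio_min) & tissue
  dim(m) <- dim(tissue)
  m
}

#' Infarct classification for TTC
#'
#' TTC turns viable myocardium deep red while the infarct remains off-white
#' with nearly equal R, G and B.  A pixel within tissue is infarct iff the
#' sample standard deviation (n - 1 denominator) of its three channel values
#' is at most `std_max`.  The rule is applied only inside the tissue mask:
#' the white slide background also has near-zero channel spread, and the
#' restriction is what keeps it out of the infarct.  The Phthalo-blue
#' perfused area needs no special handling — blue dominance gives it a large
#' channel spread, well above any sensible `std_max`.
#'
#' @inheritParams classify_mts
#' @param params [stain_params()] with `stain = "ttc"`.
#' @return logical infarct mask.
#' @export
classify_ttc <- function(image, params = stain_params("ttc"), tissue = NULL) {
  validate_image(image)
  .needs_stain(params, "ttc")
  if (is.null(tissue)) tissue <- tissue_mask(image, params)
  validate_mask(tissue, image)
  ch <- .channels(image)
  mu <- (ch$r + ch$g + ch$b) / 3
  s <- sqrt(((ch$r - mu)^2 + (ch$g - mu)^2 + (ch$b - mu)^2) / 2)
  m <- (s <= params$std_max) & tissue
  dim(m) <- dim(tissue)
  m
}

#' Infarct classification for picrosirius red (PSR)
#'
#' The collagen-rich infarct is saturated red against pale normal tissue.
#' Per pixel, `mean_GB = (G + B) / 2`; a pixel within tissue is infarct iff
#' `R - mean_GB >= thd`.  `mean_GB` is a half-integer and is compared
#' exactly, so no float rounding can flip a pixel at the threshold.  The
#' margin form keeps `thd` meaningful as the user-determined sensitivity
#' control (a bare `R > mean_GB` would admit any faintly warm pixel).
#'
#' @inheritParams classify_mts
#' @param params [stain_params()] with `stain = "psr"`.
#' @return logical infarct mask.
#' @export
classify_psr <- function(image, params = stain_params("psr"), tissue = NULL) {
  validate_image(image)
  .needs_stain(params, "psr")
  if (is.null(tissue)) tissue <- tissue_mask(image, params)
  validate_mask(tissue, image)
  ch <- .channels(image)
  m <- (ch$r - (ch$g + ch$b) / 2 >= params$thd) & tissue
  dim(m) <- dim(tissue)
  m
}

#' Green-revealing transform for H&E sections
#'
#' H&E gives infarct and normal myocardium similar pink hues; the reliable
#' difference is an elevated G in the infarct.  Two sequential per-pixel
#' passes reveal it:
#' 1. an R value exceeding `r_limit` is set to 0, G and B unchanged — this
#'    strips the strong eosin red from normal tissue and turns it light
#'    blue, while leaving pure green a fixed point;
#' 2. if `R < G` or `B < G` the pixel keeps only its green (`R` and `B` set
#'    to 0); otherwise all three channels are suppressed to 0.
#'
#' The result renders the infarct as green on a dark background and is a
#' visualization aid; the binary decision in [classify_he()] uses strict
#' green dominance.
#'
#' @inheritParams classify_mts
#' @param params [stain_params()] with `stain = "he"`.
#' @return transformed RGB array of the same dimensions.
#' @export
transform_he <- function(image, params = stain_params("he")) {
  validate_image(image)
  .needs_stain(params, "he")
  out <- image
  r <- out[, , 1]; g <- out[, , 2]; b <- out[, , 3]
  r[r > params$r_limit] <- 0L
  keep <- (r < g) | (b < g)
  r[] <- 0L
  b[] <- 0L
  g[!keep] <- 0L
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' Infarct classification for H&E
#'
#' Applies the step-1 red removal of [transform_he()], marks pixels whose
#' green strictly dominates the surviving R and the B as candidates,
#' then keeps only large, dense green areas: candidates are morphologically
#' closed (disc radius `he_close_radius`), components (8-connectivity) of the
#' closed mask whose candidate content is below `he_min_area_frac` of the
#' tissue area are discarded, the mask reverts to the candidate pixels of
#' the surviving components, and candidate components still smaller than the
#' same area floor are dropped.  Sparse green speckle in normal tissue is
#' removed by this density filter; the speckle is why H&E, unlike the other
#' stains, needs more than a per-pixel rule.
#'
#' @inheritParams classify_mts
#' @param params [stain_params()] with `stain = "he"`.
#' @return logical infarct mask.
#' @export
classify_he <- function(image, params = stain_params("he"), tissue = NULL) {
  validate_image(image)
  .needs_stain(params, "he")
  if (is.null(tissue)) tissue <- tissue_mask(image, params)
  validate_mask(tissue, image)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  r[r > params$r_limit] <- 0L
  cand <- (g > r) & (g > b) & tissue
  dim(cand) <- dim(tissue)
  if (!any(cand)) return(cand)
  closed <- close_mask(cand, params$he_close_radius)
  lab <- label_components(closed)
  ## component "area" = candidate pixels it contains, not the closed hull
  cand_per_lab <- tabulate(lab[cand], nbins = max(lab))
  min_area <- params$he_min_area_frac * sum(tissue)
  keep <- which(cand_per_lab >= min_area)
  m <- cand & matrix(lab %in% keep, nrow(lab), ncol(lab))
  ## speckle that closing happened to merge into a dense component is still
  ## isolated in the candidate mask; apply the same area floor to it
  filter_small_components(m, min_area)
}

#' Dispatch a stain-specific infarct classifier
#'
#' @param image RGB array.
#' @param params [stain_params()]; `params$stain` selects the rule.
#' @param tissue optional precomputed tissue mask.
#' @return logical infarct mask.
#' @export
classify_stain <- function(image, params, tissue = NULL) {
  switch(params$stain,
    mts = classify_mts(image, params, tissue),
    ttc = classify_ttc(image, params, tissue),
    psr = classify_psr(image, params, tissue),
    he  = classify_he(image, params, tissue),
    stop("unknown stain: ", params$stain, call. = FALSE))
}
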