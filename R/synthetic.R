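## Synthetic stained-section generator with exact ground truth.
##
## Emulates the features the classifiers key on: a near-white slide
## background, a ventricular-cross-section-shaped tissue region painted in
## the stain's "normal" palette, an embedded infarct (compact blobs or a
## diffuse fibrosis fraction) in the stain's "infarct" palette, independent
## per-channel Gaussian pixel noise, optional bubble artifacts, and sparse
## green speckle for H&E.  Truth masks are the painted regions before noise
## and are exact by construction.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Reference palettes for the synthetic generator
#'
#' Per-class RGB means used to paint synthetic sections.  The channel each
#' stain's rule keys on is anchored to the characteristic values of that
#' stain (MTS scar R low vs normal R high; TTC off-white infarct with equal
#' channels vs dominant-red viable tissue; PSR saturated-red infarct vs pale
#' normal; H&E elevated G in the infarct); companion channels are plausible
#' completions.
#'
#' @param stain `"mts"`, `"he"`, `"ttc"` or `"psr"`.
#' @return list with RGB triplets `normal`, `infarct`, `background`,
#'   `bubble`.
#' @export
default_palette <- function(stain = c("mts", "he", "ttc", "psr")) {
  stain <- match.arg(tolower(stain[1]), c("mts", "he", "ttc", "psr"))
  pal <- switch(stain,
    mts = list(normal = c(251, 120, 120), infarct = c(41, 80, 200)),
    ttc = list(normal = c(187, 69, 61),   infarct = c(133, 136, 134)),
    psr = list(normal = c(204, 191, 174), infarct = c(240, 129, 143)),
    he  = list(normal = c(230, 99, 180),  infarct = c(140, 174, 150)))
  pal$background <- c(255, 255, 255)
  pal$bubble <- c(210, 208, 212)
  pal
}

.disc_mask <- function(h, w, center, radius) {
  dr <- outer(seq_len(h) - center[1], rep(1, w))
  dc <- outer(rep(1, h), seq_len(w) - center[2])
  dr^2 + dc^2 <= radius^2
}

.ellipse_mask <- function(h, w, center, semiaxes, inner_frac = 0) {
  dr <- outer(seq_len(h) - center[1], rep(1, w)) / semiaxes[1]
  dc <- outer(rep(1, h), seq_len(w) - center[2]) / semiaxes[2]
  d2 <- dr^2 + dc^2
  m <- d2 <= 1
  if (inner_frac > 0) m <- m & d2 > inner_frac^2
  m
}

.paint <- function(image, mask, rgb) {
  rgb <- as.integer(rgb)
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[mask] <- rgb[ch]
    image[, , ch] <- plane
  }
  image
}

#' Generate one synthetic stained section with ground truth
#'
#' @param stain `"mts"`, `"he"`, `"ttc"` or `"psr"`.
#' @param width,height canvas size in pixels.
#' @param tissue list describing the tissue region: `shape` (`"ellipse"`,
#'   with `inner_frac > 0` giving an annulus mimicking a ventricular wall
#'   around a cavity), `center` `c(row, col)` and `semiaxes`
#'   `c(row, col)` in pixels; sensible defaults fill most of the canvas.
#' @param blobs list of infarct blobs `c(row, col, radius)` in pixels; the
#'   default is one compact blob inside the tissue.  Every blob must lie
#'   entirely within the tissue region.  Ignored in diffuse mode.
#' @param diffuse_frac if non-`NULL`, diffuse-fibrosis mode: this fraction
#'   of tissue pixels (exactly, rounded to a pixel count) is painted in the
#'   infarct palette as scattered single pixels.
#' @param bubbles list of bubble artifacts `c(row, col, radius)`; bubbles
#'   are painted over everything in the bubble palette and are excluded
#'   from the truth infarct mask.
#' @param palette per-class RGB means, see [default_palette()].
#' @param noise_sd per-channel Gaussian noise standard deviation (0-255
#'   scale), added to every pixel and clipped to `[0, 255]`.
#' @param speckle_frac fraction of normal-tissue pixels painted as isolated
#'   infarct-palette speckle (not part of the truth infarct); defaults to
#'   1% for H&E, mimicking the strong-but-sparse green of normal H&E
#'   tissue, and 0 for the other stains.
#' @param seed RNG seed; the fixture is bit-reproducible given the seed.
#' @return object of class `section_fixture`: `image` (RGB array),
#'   `truth_infarct` and `truth_tissue` (logical matrices, the exact
#'   painted regions before noise), `counts` (exact pixel counts),
#'   `bubble_rois` (0-based half-open bounding rectangles), `stain`,
#'   `palette`, `noise_sd`, `seed`.
#' @export
make_section <- function(stain = c("mts", "he", "ttc", "psr"),
                         width = 220L, height = 220L,
                         tissue = list(), blobs = NULL, diffuse_frac = NULL,
                         bubbles = list(), palette = NULL,
                         noise_sd = 8, speckle_frac = NULL, seed = 1L) {
  stain <- match.arg(tolower(stain[1]), c("mts", "he", "ttc", "psr"))
  if (is.null(palette)) palette <- default_palette(stain)
  if (is.null(speckle_frac)) speckle_frac <- if (stain == "he") 0.01 else 0
  h <- as.integer(height); w <- as.integer(width)
  tdef <- list(shape = "ellipse",
               center = c(h / 2, w / 2),
               semiaxes = c(0.36 * h, 0.40 * w),
               inner_frac = 0)
  tissue <- utils::modifyList(tdef, tissue)
  tis <- .ellipse_mask(h, w, tissue$center, tissue$semiaxes, tissue$inner_frac)
  if (!any(tis)) stop("tissue region is empty", call. = FALSE)

  diffuse <- !is.null(diffuse_frac)
  if (diffuse) {
    if (diffuse_frac < 0 || diffuse_frac > 1)
      stop("diffuse_frac must be in [0, 1]", call. = FALSE)
    blobs <- list()
  } else if (is.null(blobs)) {
    r <- 0.16 * min(h, w)
    blobs <- list(c(tissue$center[1] + 0.10 * h, tissue$center[2], r))
  }
  inf <- matrix(FALSE, h, w)
  for (b in blobs) {
    bm <- .disc_mask(h, w, b[1:2], b[3])
    if (any(bm & !tis))
      stop("infarct blob at (", b[1], ", ", b[2], ") radius ", b[3],
           " extends outside the tissue region", call. = FALSE)
    inf <- inf | bm
  }

  .with_seed(seed, {
    if (diffuse) {
      idx <- which(tis)
      n_fib <- round(diffuse_frac * length(idx))
      if (n_fib > 0) inf[sample(idx, n_fib)] <- TRUE
    }
    img <- array(0L, dim = c(h, w, 3L))
    img <- .paint(img, !tis, palette$background)
    img <- .paint(img, tis, palette$normal)
    img <- .paint(img, inf, palette$infarct)
    ## sparse speckle in normal tissue, same palette as the infarct,
    ## excluded from the truth (it is what the density filter must reject)
    if (speckle_frac > 0) {
      normal_idx <- which(tis & !inf)
      n_sp <- round(speckle_frac * length(normal_idx))
      if (n_sp > 0) {
        sp <- matrix(FALSE, h, w)
        sp[sample(normal_idx, n_sp)] <- TRUE
        img <- .paint(img, sp, palette$infarct)
      }
    }
    bubble_rois <- list()
    for (bb in bubbles) {
      bm <- .disc_mask(h, w, bb[1:2], bb[3])
      img <- .paint(img, bm, palette$bubble)
      inf <- inf & !bm
      bubble_rois[[length(bubble_rois) + 1L]] <-
        c(max(floor(bb[1] - bb[3]) - 1, 0), max(floor(bb[2] - bb[3]) - 1, 0),
          min(ceiling(bb[1] + bb[3]) + 1, h), min(ceiling(bb[2] + bb[3]) + 1, w))
    }
    if (noise_sd > 0) {
      noise <- round(rnorm(length(img), 0, noise_sd))
      img <- array(as.integer(pmin(pmax(img + noise, 0L), 255L)), dim = dim(img))
    }
    storage.mode(img) <- "integer"
    structure(list(image = img,
                   truth_infarct = inf,
                   truth_tissue = tis,
                   counts = list(tissue = sum(tis), infarct = sum(inf)),
                   bubble_rois = bubble_rois,
                   stain = stain, palette = palette,
                   noise_sd = noise_sd, seed = seed),
              class = "section_fixture")
  })
}

#' @export
print.section_fixture <- function(x, ...) {
  cat(sprintf("Synthetic %s section %dx%d: %d tissue px, %d infarct px (%.2f%%), noise sd %g, seed %d\n",
              toupper(x$stain), nrow(x$truth_tissue), ncol(x$truth_tissue),
              x$counts$tissue, x$counts$infarct,
              100 * x$counts$infarct / x$counts$tissue, x$noise_sd, x$seed))
  invisible(x)
}

#' Generate a serial-section stack with analytic volumes
#'
#' Builds `n_sections` synthetic sections whose infarct follows a stated 3-D
#' geometry sampled at the mid-plane of each stained slab (slab i covers
#' `[(i-1)(h1+h2), i(h1+h2))` micrometers), together with the analytic
#' infarct and tissue volumes of the continuous geometry for recovery tests.
#' The tissue is a cylinder of constant circular cross-section; its analytic
#' volume (and, for `"cylinder"` infarct geometry, the analytic infarct
#' volume) is defined from the rasterized disc area, making those cases
#' exact by construction, while the `"spherical-cap"` infarct volume is the
#' continuous sphere-slab integral, so recovery carries rasterization and
#' sampling error.
#'
#' @param stain stain for the rendered sections.
#' @param n_sections number of stained sections (>= 1).
#' @param h1 stained-section thickness, micrometers.
#' @param h2 removed-tissue thickness between sections, micrometers.
#' @param pixel_size Px, micrometers per pixel.
#' @param geometry `"spherical-cap"` (infarct is a sphere of radius
#'   `sphere_radius_um` centered mid-stack on the tissue axis, clipped to
#'   the stack) or `"cylinder"` (constant radius `cylinder_radius_px`).
#' @param tissue_radius_px tissue disc radius in pixels.
#' @param sphere_radius_um sphere radius, micrometers.
#' @param cylinder_radius_px cylinder radius, pixels.
#' @param width,height canvas size of each section.
#' @param noise_sd per-channel noise sd for the rendered images.
#' @param seed RNG seed (sections use `seed`, `seed + 1`, ...).
#' @return list with `sections` (list of [make_section()] fixtures),
#'   `analytic` (`infarct_mm3`, `tissue_mm3`), and the stack geometry
#'   (`h1`, `h2`, `pixel_size`, `n_sections`, `geometry`).
#' @export
make_stack <- function(stain = "mts", n_sections = 80L, h1 = 5, h2 = 10,
                       pixel_size = 10, geometry = c("spherical-cap", "cylinder"),
                       tissue_radius_px = 90, sphere_radius_um = 500,
                       cylinder_radius_px = 40, width = 220L, height = 220L,
                       noise_sd = 8, seed = 1L) {
  geometry <- match.arg(geometry)
  n <- as.integer(n_sections)
  if (n < 1L) stop("n_sections must be >= 1", call. = FALSE)
  H <- n * (h1 + h2)               # full stack extent, micrometers
  center <- c(height / 2, width / 2)
  z_mid <- (seq_len(n) - 0.5) * (h1 + h2)
  r_px <- switch(geometry,
    "spherical-cap" = {
      z0 <- H / 2
      sqrt(pmax(sphere_radius_um^2 - (z_mid - z0)^2, 0)) / pixel_size
    },
    "cylinder" = rep(cylinder_radius_px, n))
  sections <- lapply(seq_len(n), function(i) {
    blobs <- if (r_px[i] >= 1) list(c(center[1], center[2], r_px[i])) else list()
    make_section(stain, width = width, height = height,
                 tissue = list(center = center,
                               semiaxes = c(tissue_radius_px, tissue_radius_px)),
                 blobs = blobs, noise_sd = noise_sd, speckle_frac = 0,
                 seed = seed + i - 1L)
  })
  tissue_px_area <- sum(.ellipse_mask(height, width, center,
                                      c(tissue_radius_px, tissue_radius_px)))
  tissue_mm3 <- physical_area(tissue_px_area, pixel_size) * H / 1000
  infarct_mm3 <- switch(geometry,
    "spherical-cap" = {
      z0 <- H / 2; rho <- sphere_radius_um
      a <- max(0, z0 - rho); b <- min(H, z0 + rho)
      ## integral of pi * (rho^2 - (z - z0)^2) dz over [a, b], um^3 -> mm^3
      f <- function(z) rho^2 * z - (z - z0)^3 / 3
      pi * (f(b) - f(a)) / 1e9
    },
    "cylinder" = {
      a_px <- sum(.disc_mask(height, width, center, cylinder_radius_px))
      physical_area(a_px, pixel_size) * H / 1000
    })
  list(sections = sections,
       analytic = list(infarct_mm3 = infarct_mm3, tissue_mm3 = tissue_mm3),
       h1 = h1, h2 = h2, pixel_size = pixel_size,
       n_sections = n, geometry = geometry)
}

#' Compose single sections into one slide scan
#'
#' Stacks section images along one axis with background-colored gaps, the
#' layout of several sections scanned on one slide, and returns the exact
#' split boundaries that recover each section.
#'
#' @param sections list of [make_section()] fixtures (equal canvas sizes).
#' @param gap background gap between sections, pixels.
#' @param axis `"row"` (sections stacked vertically) or `"column"`.
#' @return list with `image` (the slide) and `bounds` (list of 0-based
#'   half-open `c(start, end)` boundaries, one per section).
#' @export
make_slide <- function(sections, gap = 12L, axis = c("row", "column")) {
  axis <- match.arg(axis)
  stopifnot(length(sections) >= 1L)
  imgs <- lapply(sections, `[[`, "image")
  dims <- vapply(imgs, function(x) dim(x)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all sections must share the same canvas size", call. = FALSE)
  h <- dims[1, 1]; w <- dims[2, 1]; n <- length(imgs)
  gap <- as.integer(gap)
  bg <- as.integer(sections[[1]]$palette$background)
  if (axis == "row") {
    H <- n * h + (n - 1L) * gap
    slide <- array(0L, dim = c(H, w, 3L))
    for (ch in 1:3) slide[, , ch] <- bg[ch]
    bounds <- vector("list", n)
    for (i in seq_len(n)) {
      top <- (i - 1L) * (h + gap)
      slide[(top + 1L):(top + h), , ] <- imgs[[i]]
      bounds[[i]] <- c(top, top + h)
    }
  } else {
    W <- n * w + (n - 1L) * gap
    slide <- array(0L, dim = c(h, W, 3L))
    for (ch in 1:3) slide[, , ch] <- bg[ch]
    bounds <- vector("list", n)
    for (i in seq_len(n)) {
      left <- (i - 1L) * (w + gap)
      slide[, (left + 1L):(left + w), ] <- imgs[[i]]
      bounds[[i]] <- c(left, left + w)
    }
  }
  list(image = slide, bounds = bounds)
}
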