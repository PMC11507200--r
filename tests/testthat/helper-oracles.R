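# Literal per-pixel reference implementations of the classification rules.
# These are deliberately scalar loops, independent of the vectorized code
# paths they check.

oracle_tissue <- function(image, params) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    px <- image[i, j, ]
    mn <- min(px); mx <- max(px)
    out[i, j] <- (mn < params$background_white_min ||
                    (mx - mn) >= params$background_saturation) &&
      mx > params$background_black_max
  }
  out
}

oracle_mts <- function(image, params, tissue) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r <- image[i, j, 1]; b <- image[i, j, 3]
    ratio <- if (r > 0) b / r else Inf
    out[i, j] <- r <= params$r_limit && ratio >= params$br_ratio_min && tissue[i, j]
  }
  out
}

oracle_ttc <- function(image, params, tissue) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    out[i, j] <- stats::sd(image[i, j, ]) <= params$std_max && tissue[i, j]
  }
  out
}

oracle_psr <- function(image, params, tissue) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    r <- image[i, j, 1]; g <- image[i, j, 2]; b <- image[i, j, 3]
    out[i, j] <- (r - (g + b) / 2) >= params$thd && tissue[i, j]
  }
  out
}

oracle_he_transform <- function(image, params) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- array(0L, dim = dim(image))
  for (i in seq_len(h)) for (j in seq_len(w)) {
    px <- image[i, j, ]
    if (px[1] > params$r_limit) px[1] <- 0L  # step 1: remove strong red
    if (px[1] < px[2] || px[3] < px[2]) {    # step 2: keep green only
      out[i, j, 2] <- px[2]
    }                                        # else: all channels suppressed
  }
  out
}

# green-dominance candidate used by the H&E binary decision (before the
# density filter)
oracle_he_candidate <- function(image, params, tissue) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    px <- image[i, j, ]
    if (px[1] > params$r_limit) px[1] <- 0L
    out[i, j] <- px[2] > px[1] && px[2] > px[3] && tissue[i, j]
  }
  out
}

# uniform-random RGB test image
random_image <- function(h, w) {
  array(sample.int(256L, h * w * 3L, replace = TRUE) - 1L, dim = c(h, w, 3L))
}

# image made of one repeated RGB triplet
solid_image <- function(h, w, rgb) {
  img <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}

all_true <- function(image) matrix(TRUE, dim(image)[1], dim(image)[2])

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
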