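# The characteristic palette pixels used throughout come from the stains'
# typical appearance: MTS scar is blue with low R (~41) against red normal
# tissue (R ~251); TTC leaves the infarct off-white with nearly equal
# channels (133,136,134) against dominant-red viable tissue (187,69,61);
# PSR stains the infarct saturated red (240,129,143) against pale normal
# tissue (204,191,174); H&E shows elevated green in the infarct (G 174 vs 99).

palette_cases <- list(
  mts = list(infarct = c(41, 80, 200), normal = c(251, 120, 120)),
  ttc = list(infarct = c(133, 136, 134), normal = c(187, 69, 61)),
  psr = list(infarct = c(240, 129, 143), normal = c(204, 191, 174)),
  he  = list(infarct = c(140, 174, 150), normal = c(230, 99, 180))
)

classify_single_pixel <- function(stain, rgb) {
  img <- solid_image(1, 1, rgb)
  p <- stain_params(stain)
  tis <- all_true(img)
  m <- switch(stain,
    mts = classify_mts(img, p, tissue = tis),
    ttc = classify_ttc(img, p, tissue = tis),
    psr = classify_psr(img, p, tissue = tis),
    he  = {
      # single-pixel check of the green-dominance decision, bypassing the
      # density filter (which needs spatial context)
      t1 <- img; if (t1[1, 1, 1] > p$r_limit) t1[1, 1, 1] <- 0L
      matrix(t1[1, 1, 2] > t1[1, 1, 1] & t1[1, 1, 2] > t1[1, 1, 3], 1, 1)
    })
  m[1, 1]
}

test_that("characteristic palette pixels classify correctly at default thresholds", {
  for (stain in names(palette_cases)) {
    expect_true(classify_single_pixel(stain, palette_cases[[stain]]$infarct),
                label = paste(stain, "infarct pixel"))
    expect_false(classify_single_pixel(stain, palette_cases[[stain]]$normal),
                 label = paste(stain, "normal pixel"))
  }
})

test_that("TTC per-pixel channel spread matches its closed form", {
  # off-white infarct: sample sd ~1.53; deep-red viable tissue: ~70.9
  expect_equal(stats::sd(c(133, 136, 134)), 1.5275, tolerance = 1e-4)
  expect_gt(stats::sd(c(187, 69, 61)), 70)
  # pure white has zero spread but is background, so it must not classify
  img <- solid_image(2, 2, c(255, 255, 255))
  p <- stain_params("ttc")
  expect_false(any(classify_ttc(img, p)))
})

test_that("PSR margin rule is exact at the threshold and symmetric in gray", {
  p <- stain_params("psr")
  # margin exactly thd is infarct; half a unit below is not
  at <- solid_image(1, 1, c(176, 136, 136))    # margin = 40
  below <- solid_image(1, 1, c(175, 135, 136)) # margin = 39.5
  expect_true(classify_psr(at, p, tissue = all_true(at))[1, 1])
  expect_false(classify_psr(below, p, tissue = all_true(below))[1, 1])
  # any gray pixel has zero margin
  for (g in c(10, 100, 200))
    expect_false(classify_psr(solid_image(1, 1, rep(g, 3)), p,
                              tissue = all_true(at))[1, 1])
})

test_that("degenerate all-black and all-white images yield empty infarct masks", {
  p <- stain_params("mts")
  black <- solid_image(8, 8, c(0, 0, 0))
  white <- solid_image(8, 8, c(255, 255, 255))
  expect_false(any(classify_mts(black, p)))
  expect_false(any(classify_mts(white, p)))
  expect_false(any(tissue_mask(white, p)))
  expect_false(any(tissue_mask(black, p)))
})

test_that("vectorized classifiers equal the per-pixel oracles bit-exactly", {
  set.seed(42)
  for (rep in 1:20) {
    img <- random_image(16, 16)
    for (stain in c("mts", "ttc", "psr")) {
      p <- stain_params(stain)
      tis <- tissue_mask(img, p, clean = FALSE)
      expect_identical(tis, oracle_tissue(img, p))
      got <- switch(stain,
        mts = classify_mts(img, p, tissue = tis),
        ttc = classify_ttc(img, p, tissue = tis),
        psr = classify_psr(img, p, tissue = tis))
      ora <- switch(stain,
        mts = oracle_mts(img, p, tis),
        ttc = oracle_ttc(img, p, tis),
        psr = oracle_psr(img, p, tis))
      expect_identical(got, ora, label = paste(stain, "rep", rep))
    }
    p <- stain_params("he")
    expect_identical(transform_he(img, p), oracle_he_transform(img, p))
  }
})

test_that("H&E transform fixes pure green and reveals the elevated-green infarct", {
  p <- stain_params("he")
  green <- solid_image(1, 1, c(0, 255, 0))
  expect_identical(transform_he(green, p), green)
  # infarct pixel survives both steps as pure green
  inf <- solid_image(1, 1, c(140, 174, 150))
  expect_identical(transform_he(inf, p)[1, 1, ], c(0L, 174L, 0L))
  # strong eosin red is stripped in step 1
  nor <- solid_image(1, 1, c(230, 99, 180))
  expect_identical(transform_he(nor, p)[1, 1, 1], 0L)
})

test_that("raising a permissive threshold never shrinks the infarct mask", {
  set.seed(7)
  for (rep in 1:10) {
    img <- random_image(24, 24)
    tis <- tissue_mask(img, stain_params("mts"), clean = FALSE)
    m1 <- classify_mts(img, stain_params("mts", r_limit = 120), tissue = tis)
    m2 <- classify_mts(img, stain_params("mts", r_limit = 200), tissue = tis)
    expect_true(all(m2[m1]))
    p1 <- classify_psr(img, stain_params("psr", thd = 70), tissue = tis)
    p2 <- classify_psr(img, stain_params("psr", thd = 20), tissue = tis)
    expect_true(all(p2[p1]))
    t1 <- classify_ttc(img, stain_params("ttc", std_max = 10), tissue = tis)
    t2 <- classify_ttc(img, stain_params("ttc", std_max = 40), tissue = tis)
    expect_true(all(t2[t1]))
  }
})

test_that("infarct masks are always subsets of the tissue mask", {
  set.seed(99)
  for (rep in 1:5) {
    img <- random_image(24, 24)
    for (stain in c("mts", "ttc", "psr", "he")) {
      p <- stain_params(stain)
      tis <- tissue_mask(img, p)
      m <- classify_stain(img, p, tissue = tis)
      expect_true(all(tis[m]))
    }
  }
  for (stain in c("mts", "ttc", "psr", "he")) {
    fx <- make_section(stain, seed = 5)
    p <- stain_params(stain)
    tis <- tissue_mask(fx$image, p)
    expect_true(all(tis[classify_stain(fx$image, p, tissue = tis)]))
  }
})

test_that("noise-free fixtures are classified perfectly within tissue", {
  for (stain in c("mts", "ttc", "psr", "he")) {
    fx <- make_section(stain, noise_sd = 0, speckle_frac = 0, seed = 2)
    p <- stain_params(stain)
    tis <- tissue_mask(fx$image, p)
    expect_identical(tis, fx$truth_tissue, label = paste(stain, "tissue"))
    expect_identical(classify_stain(fx$image, p, tissue = tis), fx$truth_infarct,
                     label = paste(stain, "infarct"))
  }
})

test_that("tissue mask recovers the generated tissue area closely under noise", {
  for (stain in c("mts", "psr")) {
    fx <- make_section(stain, noise_sd = 8, seed = 4)
    tis <- tissue_mask(fx$image, stain_params(stain))
    expect_lt(abs(sum(tis) - fx$counts$tissue) / fx$counts$tissue, 0.02)
  }
  # annulus tissue: the cavity is not filled by default
  fx <- make_section("mts", tissue = list(inner_frac = 0.5),
                     blobs = list(c(169, 110, 12)), noise_sd = 0,
                     speckle_frac = 0, seed = 4)
  expect_identical(tissue_mask(fx$image, stain_params("mts")), fx$truth_tissue)
})

test_that("H&E density filter keeps dense green blobs and rejects speckle", {
  p <- stain_params("he")
  # one compact blob + 1% scattered speckle: a single surviving component
  # overlapping the truth blob
  fx <- make_section("he", noise_sd = 8, speckle_frac = 0.01, seed = 6)
  m <- classify_he(fx$image, p)
  expect_identical(max(label_components(m)), 1L)
  expect_gt(dice(m, fx$truth_infarct), 0.8)
  # two blobs -> two components
  fx2 <- make_section("he",
                      blobs = list(c(85, 85, 20), c(135, 135, 20)),
                      noise_sd = 0, speckle_frac = 0, seed = 6)
  expect_identical(max(label_components(classify_he(fx2$image, p))), 2L)
  # no green-dominant pixels -> empty mask
  img <- solid_image(16, 16, c(200, 90, 150))
  expect_false(any(classify_he(img, p)))
})

test_that("stain parameter validation rejects mismatches and bad thresholds", {
  img <- solid_image(2, 2, c(100, 100, 100))
  expect_error(classify_mts(img, stain_params("ttc")), "requires 'mts'")
  expect_error(classify_ttc(img, stain_params("psr")), "requires 'ttc'")
  expect_error(stain_params("mts", r_limit = 300), "must lie in")
  expect_error(stain_params("psr", thd = -5), "must lie in")
  expect_error(stain_params("mts", nonsense = 1), "unknown")
  expect_error(stain_params("xyz"))
})
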