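# small hand-built cube: rows x cols, two bands at 670 and 800 nm plus a
# third band so index pairs need not be the mask pair
make_flat_cube <- function(rows, cols, r670, r800, r550 = 0.1,
                           geotransform = c(0, 1, 0, 0, 0, -1)) {
  arr <- array(0, dim = c(rows, cols, 3))
  arr[, , 1] <- r550; arr[, , 2] <- r670; arr[, , 3] <- r800
  hypercube(arr, c(550, 670, 800), geotransform = geotransform)
}

pixel_model <- function(slope, intercept, level = "pixel") {
  structure(list(metal = "Cu", level = level, slope = slope,
                 intercept = intercept, form = "linear", r_cal = -0.9, n = 26),
            class = "index_regression")
}

cu_index <- structure(list(metal = "Cu", lambda_i = 800, lambda_j = 550,
                           r_cal = -0.9, p_cal = 1e-6, n = 26),
                      class = "optimized_index")

test_that("NDVI vegetation masking follows the threshold rule", {
  cube <- make_flat_cube(4, 5, r670 = 0.05, r800 = 0.45)
  expect_true(all(vegetation_mask(cube)))            # NDVI 0.8 >= 0.3
  soil <- make_flat_cube(4, 5, r670 = 0.20, r800 = 0.22)
  expect_false(any(vegetation_mask(soil)))           # NDVI ~0.05
  expect_true(all(vegetation_mask(soil, threshold = -1)))
  expect_error(vegetation_mask(cube, red_nm = 400), "no band within")

  # raising the threshold never unmasks a pixel
  cb <- generate_cube(tiny_config(seed = 5))$cube
  m1 <- vegetation_mask(cb, threshold = 0.3)
  m2 <- vegetation_mask(cb, threshold = 0.5)
  expect_true(all(!m2 | m1))
})

test_that("polygon clipping honors the even-odd pixel-center rule", {
  layer <- matrix(1, 6, 8)
  attr(layer, "geotransform") <- c(0, 1, 0, 6, 0, -1)  # centers x=0.5..7.5, y=5.5..0.5
  full <- clip_to_polygon(layer, cbind(c(-1, 9, 9, -1), c(-1, -1, 7, 7)))
  expect_true(all(full == 1))

  none <- clip_to_polygon(layer, cbind(c(100, 101, 101), c(100, 100, 101)))
  expect_true(all(none == -9999))

  # half-plane: keep x < 3.2 -> centers 0.5, 1.5, 2.5 in each row
  half <- clip_to_polygon(layer, cbind(c(-1, 3.2, 3.2, -1), c(-1, -1, 7, 7)))
  expect_equal(sum(half == 1), 6 * 3)

  # brute-force per-pixel oracle on a random triangle
  set.seed(4)
  tri <- cbind(runif(3, 0, 8), runif(3, 0, 6))
  clipped <- clip_to_polygon(layer, tri)
  gt <- attr(layer, "geotransform")
  inside_naive <- matrix(FALSE, 6, 8)
  for (r in 1:6) for (cc in 1:8) {
    px <- gt[1] + (cc - 0.5) * gt[2]; py <- gt[4] + (r - 0.5) * gt[6]
    cnt <- 0
    for (e in 1:3) {
      a <- tri[e, ]; b <- tri[if (e == 3) 1 else e + 1, ]
      if ((a[2] > py) != (b[2] > py) &&
          px < (b[1] - a[1]) * (py - a[2]) / (b[2] - a[2]) + a[1]) cnt <- cnt + 1
    }
    inside_naive[r, cc] <- cnt %% 2 == 1
  }
  expect_equal(unclass(clipped) == 1, inside_naive)

  expect_error(clip_to_polygon(layer, cbind(1:2, 1:2)), ">= 3")
})

test_that("metal mapping equals the pointwise index-then-predict composition", {
  model <- pixel_model(-191.54, 129.93)
  cube <- make_flat_cube(6, 6, r670 = 0.05, r800 = 0.45, r550 = 0.3)
  # uniform vegetated cube: index (800,550) = (0.45-0.3)/0.75 = 0.2
  cmap <- map_metal(cube, cu_index, model)
  expect_true(all(abs(cmap - 91.622) < 1e-9))

  leafm <- pixel_model(-85.07, 62.34, level = "leaf")
  expect_error(map_metal(cube, cu_index, leafm), "level")

  # oracle equivalence on a random 10x10 cube, including the nodata pattern
  set.seed(8)
  arr <- array(runif(10 * 10 * 3, 0.02, 0.6), dim = c(10, 10, 3))
  rc <- hypercube(arr, c(550, 670, 800))
  cmap2 <- map_metal(rc, cu_index, model)
  for (r in 1:10) for (cc in 1:10) {
    sp <- spectrum(rc$wavelength, arr[r, cc, ])
    nd <- ndvi_index(sp, 800, 670)
    if (is.na(nd) || nd < 0.3) {
      expect_equal(unclass(cmap2)[r, cc], rc$nodata)
    } else {
      v <- ndvi_index(sp, 800, 550)
      expect_equal(unclass(cmap2)[r, cc], as.numeric(predict(model, v)),
                   tolerance = 1e-12)
    }
  }
})

test_that("bare soil maps to nodata and negative predictions are flagged", {
  cb <- generate_cube(tiny_config(seed = 2))
  sim <- generate_sample_set(tiny_config(seed = 2))
  fit <- suppressWarnings(specmetal_fit(sim$samples, "Cu", level = "pixel"))
  cmap <- map_metal(cb$cube, fit$index, fit$model)
  mask <- vegetation_mask(cb$cube)
  expect_true(all(unclass(cmap)[!mask] == cb$cube$nodata))
  expect_true(all(unclass(cmap)[mask] != cb$cube$nodata))
  neg <- attr(cmap, "negative")
  expect_true(all(unclass(cmap)[neg] < 0))
  expect_false(any(neg & !mask))
})

test_that("concentration maps round-trip through ENVI rasters", {
  cb <- generate_cube(tiny_config(seed = 11))
  sim <- generate_sample_set(tiny_config(seed = 11))
  fit <- suppressWarnings(specmetal_fit(sim$samples, "Zn", level = "pixel"))
  cmap <- map_metal(cb$cube, fit$index, fit$model)
  base <- file.path(withr::local_tempdir(), "zn_map")
  write_envi(unclass(cmap), base, geotransform = cb$cube$geotransform)
  back <- read_envi(base)
  expect_identical(dim(back), dim(cmap))
  expect_identical(as.vector(unclass(back)), as.vector(unclass(cmap)))
  expect_equal(attr(back, "nodata"), -9999)
})

test_that("margin diagnostics find mixed pixels and their bias direction", {
  full <- matrix(TRUE, 5, 5)
  d0 <- mixed_pixel_diagnostic(full)
  expect_equal(d0$n_margin, 0)

  lone <- matrix(FALSE, 5, 5); lone[3, 3] <- TRUE
  d1 <- mixed_pixel_diagnostic(lone)
  expect_equal(d1$n_margin, 1)
  expect_true(d1$margin[3, 3])

  # patchy synthetic cube + negative-slope model: soil mixing lowers the
  # index, hence margins overestimate relative to interiors
  cfg <- generator_config(seed = 31, cube_shape = c(60, 60))
  cb <- generate_cube(cfg)
  sim <- generate_sample_set(cfg)
  fitcu <- suppressWarnings(specmetal_fit(sim$samples, "Cu", level = "pixel"))
  cmap <- map_metal(cb$cube, fitcu$index, fitcu$model)
  mask <- vegetation_mask(cb$cube)
  dg <- mixed_pixel_diagnostic(mask, predicted = unclass(cmap),
                               truth = cb$truth$conc$Cu)
  expect_gt(dg$n_margin, 0)
  if (fitcu$model$slope < 0) {
    expect_gte(dg$bias_margin, dg$bias_interior)
  } else {
    expect_lte(dg$bias_margin, dg$bias_interior)
  }
})
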