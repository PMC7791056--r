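test_that("wide spectral tables parse, validate, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,a,b",
               "500,0.10,0.20",
               "510,0.11,0.21",
               "520,0.12,0.22"), path)
  sp <- read_spectra(path)
  expect_length(sp, 2)
  expect_equal(sp$a$value, c(0.10, 0.11, 0.12))
  expect_equal(sp$b$wavelength, c(500, 510, 520))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,a", "520,0.1", "500,0.2"), bad)
  expect_error(read_spectra(bad), "increasing")

  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,a", "500,0.1", "510,oops"), bad2)
  expect_error(read_spectra(bad2), "row 2.*'a'")

  out <- withr::local_tempfile(fileext = ".csv")
  write_spectra(sp, out)
  back <- read_spectra(out)
  expect_equal(back$a$value, sp$a$value, tolerance = 1e-12)
  expect_equal(back$b$value, sp$b$value, tolerance = 1e-12)
})

test_that("spectrum constructor enforces its invariants", {
  expect_error(spectrum(c(500, 500, 510), rep(0.1, 3)), "increasing")
  expect_error(spectrum(c(500, 510), c(0.1, 1.3)), "1.2")
  s <- spectrum(c(500, 510), c(0.9, 1.1))
  expect_true(s$overshoot)
  expect_silent(spectrum(c(500, 510), c(2, 5), quantity = "radiance"))
})

test_that("VNIR restriction keeps only 400-1000 nm and is idempotent", {
  full <- spectrum(seq(350, 2500, 50), rep(0.2, 44))
  v <- restrict_vnir(full)
  expect_true(all(v$wavelength >= 400 & v$wavelength <= 1000))
  expect_identical(restrict_vnir(v)$value, v$value)
  expect_error(restrict_vnir(full, lo = 3000, hi = 4000), "no bands")
})

test_that("Savitzky-Golay filter is polynomial-exact and reduces noise", {
  lam <- seq(400, 1000, 5)
  const <- spectrum(lam, rep(0.3, length(lam)))
  expect_equal(savgol_smooth(const)$value, const$value, tolerance = 1e-10)

  # degree-2 polynomial reproduced exactly on the interior with polyorder 3
  quad <- 0.2 + 1e-7 * (lam - 700)^2
  sq <- savgol_smooth(spectrum(lam, quad), window = 11, polyorder = 3)
  interior <- 6:(length(lam) - 5)
  expect_equal(sq$value[interior], quad[interior], tolerance = 1e-10)

  expect_error(savgol_smooth(const, window = 10), "odd")
  expect_error(savgol_smooth(const, window = 11, polyorder = 11), "polyorder")
  expect_error(savgol_smooth(spectrum(lam[1:5], quad[1:5]), window = 11),
               "exceeds")

  # smoothing strictly shrinks white-noise residuals in >= 95% of trials
  truth <- 0.2 + 0.2 / (1 + exp(-(lam - 710) / 12))
  improved <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- truth + rnorm(length(lam), 0, 0.01)
    sm <- savgol_smooth(spectrum(lam, pmin(pmax(noisy, 0), 1)))$value
    sd(sm - truth) < sd(noisy - truth)
  }, TRUE)
  expect_gte(mean(improved), 0.95)
})

test_that("empirical line interpolates panels and inverts known gain/offset", {
  lam <- seq(450, 900, 50)
  nb <- length(lam)
  dark <- list(radiance = rep(10, nb), reflectance = rep(0.05, nb))
  bright <- list(radiance = rep(80, nb), reflectance = rep(0.6, nb))
  q <- spectrum(lam, rep(10, nb), quantity = "radiance")
  out <- empirical_line(q, list(dark, bright))
  expect_equal(out$value, rep(0.05, nb), tolerance = 1e-12)
  expect_equal(out$quantity, "reflectance")

  gain <- 2; offset <- 0.01
  refl <- seq(0.1, 0.55, length.out = nb)
  panels <- list(
    list(radiance = (0.05 - offset) / gain * rep(1, nb), reflectance = rep(0.05, nb)),
    list(radiance = (0.6 - offset) / gain * rep(1, nb), reflectance = rep(0.6, nb)))
  cf <- empirical_line_coef(panels)
  expect_equal(cf$gain, rep(gain, nb), tolerance = 1e-9)
  expect_equal(cf$offset, rep(offset, nb), tolerance = 1e-9)

  ident <- list(list(radiance = rep(0, nb), reflectance = rep(0, nb)),
                list(radiance = rep(1, nb), reflectance = rep(1, nb)))
  sp <- spectrum(lam, refl, quantity = "radiance")
  expect_equal(empirical_line(sp, ident)$value, refl, tolerance = 1e-12)

  expect_error(empirical_line(q, list(dark)), ">= 2")
  same <- list(list(radiance = rep(5, nb), reflectance = rep(0.1, nb)),
               list(radiance = rep(5, nb), reflectance = rep(0.5, nb)))
  expect_error(empirical_line(q, same), "band 1")
})

test_that("empirical line inverts random gain/offset transforms (property)", {
  lam <- seq(450, 900, 30)
  nb <- length(lam)
  for (s in 1:20) {
    set.seed(s)
    gain <- runif(nb, 0.5, 3)
    offset <- runif(nb, -0.02, 0.05)
    refl <- runif(nb, 0.02, 0.9)
    panels <- list(
      list(radiance = 0.05 * gain + offset, reflectance = rep(0.05, nb)),
      list(radiance = 0.90 * gain + offset, reflectance = rep(0.90, nb)))
    rad <- spectrum(lam, refl * gain + offset, quantity = "radiance")
    out <- empirical_line(rad, panels)
    expect_equal(out$value, refl, tolerance = 1e-9)
    # recovered per-band coefficients invert the generating gain/offset
    expect_equal(attr(out, "gain"), 1 / gain, tolerance = 1e-9)
    expect_equal(attr(out, "offset"), -offset / gain, tolerance = 1e-9)
  }
})

test_that("band-grid resampling uses nearest-within-tolerance else interpolation", {
  src <- spectrum(seq(400, 1000, 1), seq(0.1, 0.7, length.out = 601))
  grid <- band_grid(vnir_band_grid())
  rs <- resample_to_grid(src, grid)
  # linear source: interpolated and nearest values agree with the line
  line <- approx(src$wavelength, src$value, xout = grid$centers)$y
  expect_equal(rs$value[attr(rs, "mode") == "interp"],
               line[attr(rs, "mode") == "interp"], tolerance = 1e-12)
  expect_true(all(abs(rs$value - line) < 0.001 + 1e-12))

  same <- resample_to_grid(rs, band_grid(rs$wavelength))
  expect_identical(same$value, rs$value)
  expect_true(all(attr(same, "mode") == "nearest"))

  expect_error(resample_to_grid(rs, band_grid(c(500, 1100))), "outside")
})

test_that("ENVI raster writing round-trips cubes bit-identically", {
  cfg <- silent_config(seed = 8)
  cb <- generate_cube(cfg)
  base <- file.path(withr::local_tempdir(), "cube")
  write_envi(cb$cube, base)
  back <- read_envi(base)
  expect_s3_class(back, "hypercube")
  expect_identical(back$data, cb$cube$data)
  expect_equal(back$wavelength, cb$cube$wavelength, tolerance = 1e-9)
  expect_equal(back$geotransform, cb$cube$geotransform, tolerance = 1e-9)
  expect_equal(back$nodata, cb$cube$nodata)
})
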