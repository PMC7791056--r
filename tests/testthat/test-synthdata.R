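test_that("leaf spectra reproduce pigment-driven shapes", {
  lam <- vnir_band_grid()
  at <- function(sp, w) sp$value[which.min(abs(sp$wavelength - w))]

  healthy <- generate_leaf_spectrum(1, 0, 1, lam)
  expect_true(all(healthy$value >= 0 & healthy$value <= 1))
  expect_lt(at(healthy, 550), at(healthy, 800))   # green below NIR plateau
  expect_lt(at(healthy, 670), at(healthy, 550))   # red absorption trough

  stressed <- generate_leaf_spectrum(0.5, 0, 1, lam)
  expect_gt(at(stressed, 550), at(healthy, 550))  # chlorosis brightens green
  expect_gt(at(stressed, 720), at(healthy, 720))  # red edge slides shortward

  red_leaf <- generate_leaf_spectrum(1, 0.8, 1, lam)
  expect_gt(at(red_leaf, 650), at(healthy, 650))  # anthocyanin red bump
  expect_equal(at(red_leaf, 900), at(healthy, 900), tolerance = 1e-12)

  # NIR plateau scales with the structure proxy within 0.30-0.45
  lo_struct <- generate_leaf_spectrum(1, 0, 0, lam)
  expect_equal(at(lo_struct, 950), 0.30, tolerance = 0.01)
  expect_equal(at(healthy, 950), 0.45, tolerance = 0.01)

  expect_error(generate_leaf_spectrum(1.2, 0, 1, lam), "\\[0, 1\\]")
  expect_error(generate_leaf_spectrum(0.5, -0.1, 1, lam), "\\[0, 1\\]")
})

test_that("sample sets are seed-deterministic and respect physical bounds", {
  cfg <- tiny_config(seed = 7)
  a <- generate_sample_set(cfg)
  b <- generate_sample_set(cfg)
  expect_identical(a, b)

  ss <- a$samples
  for (lev in c("leaf", "canopy", "pixel")) {
    expect_true(all(ss[[lev]] >= 0 & ss[[lev]] <= 1))
  }
  for (m in c("Cr", "Cu", "Ni", "Zn")) {
    expect_true(all(ss$leaf_conc[[m]] >= 0))
    expect_true(all(ss$soil_conc[[m]] >= 0))
  }
  mp <- cfg$metal_params$leaf
  for (i in seq_len(nrow(mp))) {
    x <- ss$leaf_conc[[mp$metal[i]]]
    expect_true(all(x >= mp$lo[i] & x <= mp$hi[i]))
  }
  expect_error(generate_sample_set(generator_config(n_samples = 3)), ">= 4")
})

test_that("zero effect sizes and zero noise give identical leaf spectra", {
  cfg <- silent_config(seed = 2,
                       effect_sizes = c(Cr = 0, Cu = 0, Ni = 0, Zn = 0))
  sim <- generate_sample_set(cfg)
  S <- sim$samples$leaf
  expect_true(all(abs(sweep(S, 2, S[1, ])) < 1e-12))
  # no planted signal: no index can reach significance
  expect_null(sim$truth$planted_index$Cu)
})

test_that("planted index is monotone in the driving metal when noise-free", {
  cfg <- silent_config(seed = 4,
                       effect_sizes = c(Cr = 0, Cu = 0.35, Ni = 0, Zn = 0))
  sim <- generate_sample_set(cfg)
  v <- index_values(sim$samples, sim$truth$planted_index$Cu, level = "leaf")
  ord <- order(sim$truth$leaf_conc$Cu)
  expect_true(all(diff(v[ord]) > 0) || all(diff(v[ord]) < 0))
})

test_that("leaf Cu dispersion matches the reference CV regime across seeds", {
  cvs <- vapply(1:20, function(s) {
    sim <- generate_sample_set(tiny_config(seed = s))
    x <- sim$samples$leaf_conc$Cu
    100 * sd(x) / mean(x)
  }, 1)
  target <- 33.89
  expect_gt(mean(cvs), target / 2)
  expect_lt(mean(cvs), target * 2)
})

test_that("synthetic cube has hotspot, vegetation classes, and valid truth", {
  cfg <- generator_config(seed = 9, cube_shape = c(40, 40))
  cb <- generate_cube(cfg)
  expect_s3_class(cb$cube, "hypercube")
  expect_true(all(cb$cube$data >= 0 & cb$cube$data <= 1))
  veg <- cb$truth$vegetated
  expect_true(any(veg) && any(!veg))
  # every vegetated pixel carries a truth concentration, soil pixels none
  expect_true(all(is.finite(cb$truth$conc$Cu[veg])))
  expect_true(all(is.na(cb$truth$conc$Cu[!veg])))

  # bare-soil pixels fall below the NDVI vegetation threshold
  mask <- vegetation_mask(cb$cube)
  expect_true(all(!mask[!veg]))

  # central-quarter truth exceeds the outside (hotspot)
  rows <- cfg$cube_shape[1]; cols <- cfg$cube_shape[2]
  rc <- (rows / 4 + 1):(3 * rows / 4); cc <- (cols / 4 + 1):(3 * cols / 4)
  inner <- matrix(FALSE, rows, cols); inner[rc, cc] <- TRUE
  expect_gt(mean(cb$truth$contamination[inner]), mean(cb$truth$contamination[!inner]))
})

test_that("noise-free uniform vegetation collapses to a single pixel spectrum", {
  cfg <- silent_config(seed = 3, soil_fraction_range = c(0, 0))
  cb <- generate_cube(cfg, hotspot_amplitude = 0, texture_amplitude = 0,
                      margin_soil_fraction = 0)
  expect_equal(sd(cb$truth$contamination), 0)
  veg <- which(cb$truth$vegetated)
  S <- matrix(cb$cube$data, ncol = length(cb$cube$wavelength))[veg, ]
  expect_true(all(abs(sweep(S, 2, S[1, ])) == 0))
})

test_that("sample sets round-trip through delimited text", {
  sim <- generate_sample_set(tiny_config(seed = 5, n_samples = 6))
  dir <- withr::local_tempdir()
  write_sample_set(sim, dir)
  spectra <- read_spectra(file.path(dir, "spectra_leaf.csv"))
  expect_length(spectra, 6)
  expect_equal(spectra[[1]]$value, unname(sim$samples$leaf[1, ]),
               tolerance = 1e-12)
  chem <- read.csv(file.path(dir, "chemistry_leaf.csv"))
  expect_equal(chem$Cu, sim$samples$leaf_conc$Cu, tolerance = 1e-10)
})
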