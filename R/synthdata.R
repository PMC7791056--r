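#' Reference concentration statistics for the four study metals
#'
#' Mean, SD and observed range (mg kg-1) of Cr, Cu, Ni and Zn in brownfield
#' soil and bramble leaves, used as the default sampling distributions of the
#' synthetic-data generator.
#'
#' @return List with data frames `leaf` and `soil`
#'   (columns `metal`, `mean`, `sd`, `lo`, `hi`).
#' @export
default_metal_params <- function() {
  list(
    soil = data.frame(
      metal = c("Cr", "Cu", "Ni", "Zn"),
      mean = c(2022.5, 72.9, 92.55, 4320),
      sd = c(345.29, 16.14, 38.7, 836.11),
      lo = c(1600, 56, 55, 3100),
      hi = c(3100, 130, 200, 6100),
      stringsAsFactors = FALSE
    ),
    leaf = data.frame(
      metal = c("Cr", "Cu", "Ni", "Zn"),
      mean = c(2.14, 17.44, 1.71, 86.91),
      sd = c(0.51, 5.91, 0.44, 24.27),
      lo = c(1.14, 10.13, 0.53, 45.21),
      hi = c(3.04, 27.91, 2.64, 149.12),
      stringsAsFactors = FALSE
    )
  )
}

#' Synthetic-study generator configuration
#'
#' Bundles and validates all knobs of the synthetic data generator: the number
#' of co-located field plots, the per-metal concentration distributions, the
#' strength of the metal-to-pigment coupling, measurement-noise levels, the
#' canopy/pixel soil-mixing range, the image band grid and the cube size.
#'
#' Cr, Cu and Ni jointly depress the chlorophyll proxy (raising green and
#' red-edge reflectance), Zn raises the anthocyanin proxy (raising red
#' reflectance), each scaled by its entry in `effect_sizes`. The four metals
#' co-vary through a shared latent contamination factor (`metal_correlation`),
#' emulating a single pollution source.
#'
#' @param n_samples Number of co-located leaf/canopy/pixel plots (>= 4).
#' @param metal_params Per-metal mean/SD/range, as [default_metal_params()].
#' @param effect_sizes Named vector (Cr, Cu, Ni, Zn), dimensionless
#'   pigment-response coefficients.
#' @param noise_sd_additive Additive reflectance noise SD (reflectance units).
#' @param noise_sd_multiplicative Multiplicative noise SD (relative).
#' @param proxy_jitter_sd SD of the biological scatter added to the pigment
#'   proxies (limits how far index-metal correlations can climb).
#' @param structure_sd SD of the metal-independent leaf-structure proxy
#'   (NIR plateau variability across leaves).
#' @param brightness_sd SD (log scale) of per-sample multiplicative
#'   brightness; normalized-difference indices cancel it exactly, but it
#'   dominates Euclidean spectral distances the way illumination and
#'   leaf-angle effects do in the field.
#' @param spectral_texture_sd Per-band SD of smooth, sample-specific spectral
#'   fine structure (correlation length ~2.5 bands), emulating biochemical
#'   variation between leaves beyond the three modeled pigment axes. This is
#'   part of the noise-free biological spectrum, not sensor noise.
#' @param metal_correlation Correlation of each metal with the latent
#'   contamination factor, in \[0, 1).
#' @param soil_fraction_range Range of the soil fraction mixed into canopy and
#'   pixel spectra, within \[0, 1\].
#' @param seed Integer RNG seed.
#' @param cube_shape Cube dimensions `c(rows, cols)`.
#' @param band_grid Wavelength grid (nm), strictly increasing within
#'   \[400, 1000\].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 40,
                             metal_params = default_metal_params(),
                             effect_sizes = c(Cr = 0.2, Cu = 0.35,
                                              Ni = 0.2, Zn = 0.75),
                             noise_sd_additive = 0.005,
                             noise_sd_multiplicative = 0.02,
                             proxy_jitter_sd = 0.04,
                             structure_sd = 0.12,
                             brightness_sd = 0.08,
                             spectral_texture_sd = 0.006,
                             metal_correlation = 0.9,
                             soil_fraction_range = c(0.05, 0.35),
                             seed = 1L,
                             cube_shape = c(100, 100),
                             band_grid = vnir_band_grid()) {
  for (comp in c("leaf", "soil")) {
    mp <- metal_params[[comp]]
    stopifnot(is.data.frame(mp), all(c("metal", "mean", "sd", "lo", "hi") %in% names(mp)))
    if (any(mp$sd < 0)) stop("metal SDs must be >= 0", call. = FALSE)
    if (any(mp$mean <= 0)) stop("metal means must be > 0", call. = FALSE)
    if (any(mp$lo < 0) || any(mp$hi <= mp$lo)) {
      stop("metal ranges must satisfy 0 <= lo < hi", call. = FALSE)
    }
  }
  if (length(soil_fraction_range) != 2L || any(soil_fraction_range < 0) ||
      any(soil_fraction_range > 1) || diff(soil_fraction_range) < 0) {
    stop("soil_fraction_range must be an interval within [0, 1]", call. = FALSE)
  }
  if (noise_sd_additive < 0 || noise_sd_multiplicative < 0 ||
      proxy_jitter_sd < 0 || structure_sd < 0 || brightness_sd < 0 ||
      spectral_texture_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (metal_correlation < 0 || metal_correlation >= 1) {
    stop("metal_correlation must be in [0, 1)", call. = FALSE)
  }
  band_grid <- as.numeric(band_grid)
  if (any(diff(band_grid) <= 0) || min(band_grid) < 400 || max(band_grid) > 1000) {
    stop("band_grid must be strictly increasing within [400, 1000] nm", call. = FALSE)
  }
  if (length(cube_shape) != 2L || any(cube_shape < 4)) {
    stop("cube_shape must be c(rows, cols), both >= 4", call. = FALSE)
  }
  es <- effect_sizes[c("Cr", "Cu", "Ni", "Zn")]
  if (anyNA(es)) stop("effect_sizes must name Cr, Cu, Ni, Zn", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), metal_params = metal_params,
                 effect_sizes = es, noise_sd_additive = noise_sd_additive,
                 noise_sd_multiplicative = noise_sd_multiplicative,
                 proxy_jitter_sd = proxy_jitter_sd,
                 structure_sd = structure_sd, brightness_sd = brightness_sd,
                 spectral_texture_sd = spectral_texture_sd,
                 metal_correlation = metal_correlation,
                 soil_fraction_range = soil_fraction_range,
                 seed = as.integer(seed), cube_shape = as.integer(cube_shape),
                 band_grid = band_grid),
            class = "generator_config")
}

# Vectorized parametric green-leaf reflectance model.
# chl, anth, struct: equal-length proxy vectors in [0,1]; lam: wavelengths.
# Returns an n x length(lam) matrix. Components:
#   - flat visible baseline 0.05;
#   - Gaussian green peak at 550 nm whose height grows as chlorophyll falls;
#   - logistic red edge whose inflection slides from 720 nm (chl = 1)
#     to 690 nm (chl = 0), reaching an NIR plateau of 0.30-0.45 set by the
#     leaf-structure proxy;
#   - Gaussian red bump at 650 nm proportional to the anthocyanin proxy.
.leaf_reflectance <- function(chl, anth, struct, lam) {
  n <- length(chl)
  green_h <- 0.05 + 0.20 * (1 - chl)
  plateau <- 0.25 + 0.15 * struct
  red_h <- 0.22 * anth
  infl <- 685 + 40 * chl
  g_shape <- exp(-((lam - 550)^2) / (2 * 30^2))
  a_shape <- exp(-((lam - 650)^2) / (2 * 12^2))
  val <- matrix(0.05, n, length(lam))
  val <- val + outer(green_h, g_shape) + outer(red_h, a_shape)
  edge <- 1 / (1 + exp(-(outer(-infl, lam, `+`)) / 10))
  val <- val + plateau * edge
  pmin(pmax(val, 0), 1)
}

#' Generate a noise-free synthetic leaf spectrum
#'
#' Parametric green-leaf model driven by three normalized pigment/structure
#' proxies. Falling chlorophyll raises the green peak and shifts the red-edge
#' inflection toward shorter wavelengths; anthocyanin raises red (~650 nm)
#' reflectance locally; leaf structure scales the NIR plateau (0.30-0.45).
#'
#' @param chlorophyll,anthocyanin,structure Proxies in \[0, 1\].
#' @param band_grid Wavelength grid (nm).
#' @return A leaf-level [spectrum].
#' @examples
#' healthy <- generate_leaf_spectrum(1, 0, 1)
#' stressed <- generate_leaf_spectrum(0.4, 0.6, 1)
#' @export
generate_leaf_spectrum <- function(chlorophyll, anthocyanin, structure,
                                   band_grid = vnir_band_grid()) {
  p <- c(chlorophyll, anthocyanin, structure)
  if (length(p) != 3L || anyNA(p) || any(p < 0 | p > 1)) {
    stop("proxies must be single values in [0, 1]", call. = FALSE)
  }
  val <- .leaf_reflectance(chlorophyll, anthocyanin, structure,
                           as.numeric(band_grid))[1, ]
  spectrum(band_grid, val, level = "leaf")
}

#' Fixed soil endmember spectrum
#'
#' Linear reflectance ramp 0.08 -> 0.25 across the grid; its only role is
#' spectral contrast with vegetation for mixing and NDVI masking.
#'
#' @param band_grid Wavelength grid (nm).
#' @return Numeric reflectance vector.
#' @export
soil_spectrum <- function(band_grid = vnir_band_grid()) {
  seq(0.08, 0.25, length.out = length(band_grid))
}

# Correlated truncated-normal draws: z shares latent factor t, out-of-range
# values are re-drawn (keeping t) and finally clipped as a safety net.
.draw_trunc <- function(n, t, mean, sd, lo, hi, rho) {
  z <- rho * t + sqrt(1 - rho^2) * stats::rnorm(n)
  x <- mean + sd * z
  for (k in 1:100) {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) break
    x[bad] <- mean + sd * (rho * t[bad] + sqrt(1 - rho^2) * stats::rnorm(length(bad)))
  }
  pmin(pmax(x, max(lo, 0)), hi)
}

.clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Pigment proxies from leaf concentrations (vectorized over samples).
# u: matrix of range-normalized concentrations in [0,1], columns Cr,Cu,Ni,Zn.
.proxies_from_u <- function(u, effect_sizes, jitter_sd, n, structure_sd = 0) {
  jit <- function(s) if (s > 0) stats::rnorm(n, 0, s) else 0
  chl <- .clamp(0.92 - (effect_sizes["Cr"] * u[, "Cr"] +
                        effect_sizes["Cu"] * u[, "Cu"] +
                        effect_sizes["Ni"] * u[, "Ni"]) + jit(jitter_sd), 0.02, 1)
  anth <- .clamp(0.05 + effect_sizes["Zn"] * u[, "Zn"] + jit(jitter_sd), 0, 1)
  struct <- .clamp(0.7 + jit(structure_sd), 0, 1)
  list(chl = chl, anth = anth, struct = struct)
}

# Per-sample multiplicative brightness (illumination/leaf-angle surrogate);
# exactly cancelled by normalized-difference indices.
.apply_brightness <- function(val, brightness_sd) {
  if (brightness_sd <= 0) return(val)
  val * exp(stats::rnorm(nrow(val), 0, brightness_sd))
}

# Smooth sample-specific spectral fine structure: band-wise white noise
# filtered with a Gaussian kernel (sd 2.5 bands) and rescaled to the target
# marginal SD. Gives every band pair idiosyncratic biological variance.
.spectral_texture <- function(n, k, sd) {
  if (sd <= 0) return(matrix(0, n, k))
  half <- 8L
  kern <- stats::dnorm(-half:half, sd = 2.5)
  kern <- kern / sqrt(sum(kern^2))  # unit output variance before scaling
  pad <- matrix(stats::rnorm(n * (k + 2L * half)), n)
  out <- matrix(0, n, k)
  for (d in seq_along(kern)) {
    out <- out + kern[d] * pad[, d:(d + k - 1L), drop = FALSE]
  }
  sd * out
}

.add_noise <- function(val, cfg) {
  n <- nrow(val); k <- ncol(val)
  if (cfg$noise_sd_multiplicative > 0) {
    val <- val * (1 + matrix(stats::rnorm(n * k, 0, cfg$noise_sd_multiplicative), n, k))
  }
  if (cfg$noise_sd_additive > 0) {
    val <- val + matrix(stats::rnorm(n * k, 0, cfg$noise_sd_additive), n, k)
  }
  .clamp(val)
}

#' Generate a synthetic co-located sample set with ground truth
#'
#' Draws soil and leaf metal concentrations from truncated normal
#' distributions (correlated across metals through a shared latent
#' contamination factor), maps Cr/Cu/Ni to a chlorophyll decline and Zn to an
#' anthocyanin increase, builds noise-free leaf spectra from the pigment
#' proxies, then adds multiplicative and additive Gaussian noise. Canopy and
#' pixel spectra are convex leaf/soil mixtures with per-sample soil fractions
#' drawn from `soil_fraction_range` (pixel level re-draws its own fractions
#' and noise, emulating a coarser footprint).
#'
#' @param config A [generator_config()].
#' @return List with elements `samples` (class `sample_set`: `ids`,
#'   `wavelength`, spectra matrices `leaf`, `canopy`, `pixel` of size
#'   samples x bands, concentration data frames `leaf_conc`, `soil_conc`) and
#'   `truth` (pigment proxies, soil fractions, noise-free leaf spectra, and
#'   the planted best index pair per metal, found by an exhaustive search on
#'   the noise-free spectra).
#' @export
generate_sample_set <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_samples
  if (n < 4L) stop("n_samples must be >= 4 (calibration/validation split)", call. = FALSE)
  set.seed(config$seed)
  lam <- config$band_grid
  metals <- c("Cr", "Cu", "Ni", "Zn")
  rho <- config$metal_correlation
  t <- stats::rnorm(n)

  draw_panel <- function(mp) {
    out <- sapply(metals, function(m) {
      i <- match(m, mp$metal)
      .draw_trunc(n, t, mp$mean[i], mp$sd[i], mp$lo[i], mp$hi[i], rho)
    })
    as.data.frame(out)
  }
  leaf_conc <- draw_panel(config$metal_params$leaf)
  soil_conc <- draw_panel(config$metal_params$soil)

  mp <- config$metal_params$leaf
  u <- sapply(metals, function(m) {
    i <- match(m, mp$metal)
    .clamp((leaf_conc[[m]] - mp$lo[i]) / (mp$hi[i] - mp$lo[i]))
  })
  colnames(u) <- metals
  px <- .proxies_from_u(u, config$effect_sizes, config$proxy_jitter_sd, n,
                        structure_sd = config$structure_sd)

  clean <- .leaf_reflectance(px$chl, px$anth, px$struct, lam)
  clean <- .clamp(clean + .spectral_texture(n, length(lam),
                                            config$spectral_texture_sd))
  leaf <- .add_noise(.apply_brightness(clean, config$brightness_sd), config)

  soil <- soil_spectrum(lam)
  f_can <- stats::runif(n, config$soil_fraction_range[1], config$soil_fraction_range[2])
  canopy <- .add_noise(
    .apply_brightness(clean * (1 - f_can) + outer(f_can, soil),
                      config$brightness_sd), config)
  f_pix <- stats::runif(n, config$soil_fraction_range[1], config$soil_fraction_range[2])
  pixel <- .add_noise(
    .apply_brightness(clean * (1 - f_pix) + outer(f_pix, soil),
                      config$brightness_sd), config)

  ids <- sprintf("plot%02d", seq_len(n))
  rownames(leaf) <- rownames(canopy) <- rownames(pixel) <- ids
  samples <- structure(list(ids = ids, wavelength = lam, leaf = leaf,
                            canopy = canopy, pixel = pixel,
                            leaf_conc = cbind(sample_id = ids, leaf_conc),
                            soil_conc = cbind(sample_id = ids, soil_conc)),
                       class = "sample_set")

  planted <- lapply(metals, function(m) {
    tryCatch({
      cm <- .correlation_map_mat(clean, leaf_conc[[m]], lam, metal = m)
      select_best_index(cm)
    }, error = function(e) NULL)
  })
  names(planted) <- metals

  truth <- list(leaf_conc = leaf_conc, soil_conc = soil_conc,
                chlorophyll = px$chl, anthocyanin = px$anth,
                structure = px$struct, soil_fraction_canopy = f_can,
                soil_fraction_pixel = f_pix, clean_leaf = clean,
                planted_index = planted)
  list(samples = samples, truth = truth)
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d samples, %d bands [%.1f, %.1f] nm, levels leaf/canopy/pixel\n",
              length(x$ids), length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Extract one sample's spectrum from a sample set
#'
#' @param samples A `sample_set`.
#' @param i Sample index or id.
#' @param level Acquisition level.
#' @return A [spectrum].
#' @export
get_spectrum <- function(samples, i, level = c("leaf", "canopy", "pixel")) {
  level <- match.arg(level)
  if (is.character(i)) i <- match(i, samples$ids)
  spectrum(samples$wavelength, samples[[level]][i, ], level = level)
}

#' Generate a synthetic hyperspectral cube with per-pixel truth
#'
#' Lays out bramble-like vegetation patches (random discs) over bare soil,
#' drives a smooth spatial contamination field with a central hotspot, derives
#' per-pixel leaf metal concentrations and pigment proxies from that field,
#' and renders pixel spectra with the leaf model. Vegetated pixels bordering
#' soil receive extra soil mixing (the mixed-pixel margin effect); bare-soil
#' pixels carry the soil ramp spectrum. Reproducible from `config$seed`.
#'
#' @param config A [generator_config()].
#' @param hotspot_amplitude Peak added contamination at the cube center (in
#'   normalized contamination units).
#' @param texture_amplitude Multiplier on the low-frequency background
#'   contamination texture (0 gives a spatially uniform background).
#' @param margin_soil_fraction Extra soil fraction on vegetated pixels
#'   adjacent to bare soil.
#' @return List with `cube` (a [hypercube]) and `truth`: `contamination`
#'   (rows x cols normalized field), `vegetated` (logical ground-truth mask),
#'   and `conc`, one rows x cols concentration matrix per metal (NA on bare
#'   soil).
#' @export
generate_cube <- function(config = generator_config(), hotspot_amplitude = 0.5,
                          texture_amplitude = 1, margin_soil_fraction = 0.2) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1000L)
  rows <- config$cube_shape[1]; cols <- config$cube_shape[2]
  lam <- config$band_grid
  metals <- c("Cr", "Cu", "Ni", "Zn")

  X <- matrix(rep((seq_len(cols) - 0.5) / cols, each = rows), rows, cols)
  Y <- matrix(rep((seq_len(rows) - 0.5) / rows, times = cols), rows, cols)

  # smooth contamination field: low-frequency texture + central hotspot
  ph <- stats::runif(4, 0, 2 * pi)
  texture <- texture_amplitude *
    (0.15 * sin(2 * pi * (1.3 * X + 0.6 * Y) + ph[1]) +
     0.12 * sin(2 * pi * (0.7 * X - 1.1 * Y) + ph[2]))
  hotspot <- hotspot_amplitude * exp(-((X - 0.5)^2 + (Y - 0.5)^2) / (2 * 0.22^2))
  contamination <- .clamp(0.25 + hotspot + texture)

  # vegetation patches: union of random discs, bramble-like cover
  veg <- matrix(FALSE, rows, cols)
  n_disc <- max(6L, round(rows * cols / 700))
  cx <- stats::runif(n_disc); cy <- stats::runif(n_disc)
  rad <- stats::runif(n_disc, 0.08, 0.18)
  for (d in seq_len(n_disc)) {
    veg <- veg | ((X - cx[d])^2 + (Y - cy[d])^2 <= rad[d]^2)
  }
  # keep the hotspot observable: vegetate a central disc
  veg <- veg | ((X - 0.5)^2 + (Y - 0.5)^2 <= 0.1^2)

  # margin pixels: vegetated with a bare-soil 8-neighbour
  margin <- veg & !.erode8(veg)

  mp <- config$metal_params$leaf
  conc <- lapply(metals, function(m) {
    i <- match(m, mp$metal)
    cm <- mp$lo[i] + contamination * (mp$hi[i] - mp$lo[i])
    cm[!veg] <- NA_real_
    cm
  })
  names(conc) <- metals

  idx <- which(veg)
  nv <- length(idx)
  u <- cbind(Cr = contamination[idx], Cu = contamination[idx],
             Ni = contamination[idx], Zn = contamination[idx])
  # a 1-m pixel averages many leaves, shrinking leaf-to-leaf pigment scatter
  px <- .proxies_from_u(u, config$effect_sizes, config$proxy_jitter_sd / 3, nv,
                        structure_sd = config$structure_sd / 3)
  leaf_val <- .leaf_reflectance(px$chl, px$anth, px$struct, lam)
  leaf_val <- .clamp(leaf_val + .spectral_texture(nv, length(lam),
                                                  config$spectral_texture_sd))

  soil <- soil_spectrum(lam)
  # patch interiors are densely vegetated; soil shows mainly at margins
  f0 <- config$soil_fraction_range[1]
  f <- stats::runif(nv, f0, min(config$soil_fraction_range[2], f0 + 0.05))
  f <- f + margin_soil_fraction * (margin[idx])
  f <- .clamp(f)
  mixed <- .apply_brightness(leaf_val * (1 - f) + outer(f, soil),
                             config$brightness_sd)

  npix <- rows * cols
  flat <- matrix(rep(soil, each = npix), npix, length(lam))
  flat[idx, ] <- mixed
  flat <- .add_noise(flat, config)

  arr <- array(flat, dim = c(rows, cols, length(lam)))
  cube <- hypercube(arr, lam,
                    geotransform = c(500000, 1, 0, 4500000, 0, -1),
                    nodata = -9999, crs = "local metric")
  list(cube = cube,
       truth = list(contamination = contamination, vegetated = veg,
                    margin = margin, conc = conc))
}

# 8-neighbour erosion of a logical matrix (FALSE border outside the raster
# counts as background only for margin detection when requested).
.erode8 <- function(m) {
  rows <- nrow(m); cols <- ncol(m)
  pad <- matrix(TRUE, rows + 2, cols + 2)  # off-raster treated as vegetated
  pad[2:(rows + 1), 2:(cols + 1)] <- m
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & pad[(2 + dr):(rows + 1 + dr), (2 + dc):(cols + 1 + dc)]
  }
  out
}

#' Write a synthetic sample set (and its truth) as delimited text
#'
#' Emits wide spectral tables (`spectra_<level>.csv`), chemistry tables
#' (`chemistry_leaf.csv`, `chemistry_soil.csv`) and a truth sidecar
#' (`truth.csv`) into `dir`.
#'
#' @param sim Output of [generate_sample_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample_set <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- sim$samples
  for (lev in c("leaf", "canopy", "pixel")) {
    df <- data.frame(wavelength_nm = ss$wavelength, check.names = FALSE)
    for (i in seq_along(ss$ids)) df[[ss$ids[i]]] <- ss[[lev]][i, ]
    utils::write.table(df, file.path(dir, sprintf("spectra_%s.csv", lev)),
                       sep = ",", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(ss$leaf_conc, file.path(dir, "chemistry_leaf.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(ss$soil_conc, file.path(dir, "chemistry_soil.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  tr <- sim$truth
  truth_df <- data.frame(sample_id = ss$ids, chlorophyll = tr$chlorophyll,
                         anthocyanin = tr$anthocyanin, structure = tr$structure,
                         soil_fraction_canopy = tr$soil_fraction_canopy,
                         soil_fraction_pixel = tr$soil_fraction_pixel)
  utils::write.table(truth_df, file.path(dir, "truth.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
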