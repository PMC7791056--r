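#' Vegetation mask from a red/NIR NDVI threshold
#'
#' Keeps pixels whose NDVI `(rho_nir - rho_red)/(rho_nir + rho_red)` reaches
#' the threshold (default 0.3, the conventional sparse-vegetation cutoff);
#' pixels with undefined NDVI are masked.
#'
#' @param cube A [hypercube].
#' @param red_nm,nir_nm Red and NIR wavelengths (nm), resolved to the nearest
#'   band center.
#' @param threshold NDVI cutoff; a pixel is kept iff `NDVI >= threshold`.
#' @param tolerance Band-matching tolerance (nm).
#' @return Logical rows x cols matrix (`TRUE` = vegetated).
#' @export
vegetation_mask <- function(cube, red_nm = 670, nir_nm = 800, threshold = 0.3,
                            tolerance = 2.6) {
  stopifnot(inherits(cube, "hypercube"))
  ir <- resolve_band(cube$wavelength, red_nm, tolerance)
  ii <- resolve_band(cube$wavelength, nir_nm, tolerance)
  red <- cube$data[, , ir]
  nir <- cube$data[, , ii]
  red[red == cube$nodata] <- NA_real_
  nir[nir == cube$nodata] <- NA_real_
  s <- nir + red
  ndvi <- (nir - red) / s
  ndvi[!is.finite(s) | s <= 1e-9] <- NA_real_
  keep <- is.finite(ndvi) & ndvi >= threshold
  keep
}

# Even-odd point-in-polygon, vectorized over points; points exactly on an
# edge are treated as inside.
.point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    inbox <- px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
             py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    onedge <- onedge | (abs(cross) <= eps * max(1, abs(xi) + abs(yj)) & inbox)
    crosses <- ((yi > py) != (yj > py)) &
               (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

#' Clip a raster layer to a site polygon
#'
#' Sets pixels whose centers fall outside the polygon to the nodata value.
#' Inclusion follows the even-odd rule; a center exactly on an edge is kept.
#'
#' @param layer Numeric matrix (rows x cols), e.g. a concentration map.
#' @param polygon Two-column matrix of (x, y) vertices (>= 3), in the same
#'   coordinate frame as the geotransform.
#' @param geotransform Length-6 affine transform (see [hypercube()]); defaults
#'   to the layer's `geotransform` attribute.
#' @param nodata Sentinel written outside the polygon; defaults to the layer's
#'   `nodata` attribute or -9999.
#' @return The clipped layer (attributes preserved).
#' @export
clip_to_polygon <- function(layer, polygon, geotransform = NULL, nodata = NULL) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || ncol(polygon) != 2L) {
    stop("polygon needs >= 3 (x, y) vertices", call. = FALSE)
  }
  if (is.null(geotransform)) geotransform <- attr(layer, "geotransform")
  if (is.null(geotransform)) geotransform <- c(0, 1, 0, 0, 0, -1)
  if (is.null(nodata)) nodata <- attr(layer, "nodata")
  if (is.null(nodata)) nodata <- -9999
  ctr <- pixel_centers(list(geotransform = geotransform),
                       dims = dim(layer))
  keep <- .point_in_polygon(as.vector(ctr$x), as.vector(ctr$y), polygon)
  out <- layer
  out[!matrix(keep, nrow(layer), ncol(layer))] <- nodata
  attributes(out) <- attributes(layer)
  dim(out) <- dim(layer)
  out
}

#' Map a metal concentration over a hyperspectral cube
#'
#' Per unmasked pixel: the optimized two-band index is computed from that
#' pixel's spectrum and the pixel-level regression applied — exactly the
#' pointwise composition of [ndvi_index()] and [predict.index_regression()].
#' Non-vegetation (NDVI below `threshold`) and, optionally, pixels outside the
#' site polygon are set to nodata. Negative predictions are retained but
#' reported in a QA flag layer.
#'
#' @param cube A [hypercube] of surface reflectance.
#' @param index An `optimized_index` (band pair).
#' @param model An `index_regression` or [specmetal_fit()] with
#'   `level = "pixel"`; a level mismatch is an error so leaf-level equations
#'   are never silently applied to image pixels.
#' @param threshold NDVI vegetation-mask threshold.
#' @param polygon Optional site polygon (see [clip_to_polygon()]).
#' @param red_nm,nir_nm Mask bands.
#' @return Object of class `concentration_map`: numeric rows x cols matrix
#'   (mg kg-1) with attributes `nodata`, `geotransform`, `negative` (QA
#'   layer) and `provenance`.
#' @export
map_metal <- function(cube, index, model, threshold = 0.3, polygon = NULL,
                      red_nm = 670, nir_nm = 800) {
  stopifnot(inherits(cube, "hypercube"))
  if (inherits(model, "specmetal_fit")) {
    if (is.null(index)) index <- model$index
    model <- model$model
  }
  stopifnot(inherits(index, "optimized_index"), inherits(model, "index_regression"))
  if (!identical(model$level, "pixel")) {
    stop("model level is '", model$level,
         "': refusing to apply a non-pixel calibration to image pixels",
         call. = FALSE)
  }
  mask <- vegetation_mask(cube, red_nm = red_nm, nir_nm = nir_nm,
                          threshold = threshold)
  bi <- resolve_band(cube$wavelength, index$lambda_i)
  bj <- resolve_band(cube$wavelength, index$lambda_j)
  vi <- cube$data[, , bi]
  vj <- cube$data[, , bj]
  s <- vi + vj
  idx <- (vi - vj) / s
  idx[!is.finite(s) | s <= 1e-9] <- NA_real_
  pred <- predict(model, idx)
  dim(pred) <- dim(idx)
  out <- pred
  out[!mask | !is.finite(pred)] <- cube$nodata
  neg <- is.finite(pred) & pred < 0 & mask
  attr(out, "nodata") <- cube$nodata
  attr(out, "geotransform") <- cube$geotransform
  if (!is.null(polygon)) {
    out <- clip_to_polygon(out, polygon, geotransform = cube$geotransform,
                           nodata = cube$nodata)
    neg[out == cube$nodata] <- FALSE
  }
  attr(out, "negative") <- neg
  attr(out, "provenance") <- list(
    metal = model$metal,
    index = c(lambda_i = index$lambda_i, lambda_j = index$lambda_j),
    model = c(slope = model$slope, intercept = model$intercept),
    form = model$form, mask_threshold = threshold,
    mask_bands = c(red = red_nm, nir = nir_nm))
  class(out) <- c("concentration_map", class(out))
  out
}

#' @export
print.concentration_map <- function(x, ...) {
  pv <- attr(x, "provenance")
  nd <- attr(x, "nodata")
  v <- x[x != nd]
  cat(sprintf("<concentration_map> %s: %d x %d px, %d mapped, range [%.3g, %.3g] mg/kg\n",
              pv$metal, nrow(x), ncol(x), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Mixed-pixel margin diagnostic
#'
#' Vegetated pixels bordering bare soil carry mixed spectra whose depressed
#' index values bias concentration estimates (overestimation under a
#' negative-slope calibration). This flags margin pixels — vegetated pixels
#' with a masked pixel within `margin_width` (Chebyshev distance) — and, when
#' predictions and ground truth are supplied, contrasts the mean
#' (predicted - truth) bias on margins against patch interiors.
#'
#' @param mask Logical vegetation mask (rows x cols).
#' @param margin_width Neighbourhood radius in pixels.
#' @param predicted,truth Optional matrices aligned with `mask` (nodata/NA
#'   ignored).
#' @param nodata Sentinel in `predicted`.
#' @return List with `margin` (logical matrix), `n_margin`, `n_interior` and,
#'   when data are given, `bias_margin`, `bias_interior`.
#' @export
mixed_pixel_diagnostic <- function(mask, margin_width = 1, predicted = NULL,
                                   truth = NULL, nodata = -9999) {
  stopifnot(is.logical(mask), is.matrix(mask))
  interior <- mask
  for (k in seq_len(margin_width)) interior <- .erode8(interior)
  margin <- mask & !interior
  out <- list(margin = margin, n_margin = sum(margin),
              n_interior = sum(mask & !margin))
  if (!is.null(predicted) && !is.null(truth)) {
    err <- predicted - truth
    err[predicted == nodata] <- NA_real_
    out$bias_margin <- mean(err[margin], na.rm = TRUE)
    out$bias_interior <- mean(err[mask & !margin], na.rm = TRUE)
  }
  out
}
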