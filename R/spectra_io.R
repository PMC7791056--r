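#' Read spectra from a wide delimited-text table
#'
#' Expects a header row and a first column named `wavelength_nm`; every further
#' column is one sample's spectrum. Wavelengths must be strictly increasing.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @param level,quantity Tags applied to every returned spectrum.
#' @return Named list of [spectrum] objects, one per sample column.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, sep = ",",
                         level = c("leaf", "canopy", "pixel"),
                         quantity = c("reflectance", "radiance")) {
  level <- match.arg(level)
  quantity <- match.arg(quantity)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("spectral table needs wavelength_nm plus >= 1 sample column",
                          call. = FALSE)
  num <- lapply(seq_along(df), function(j) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(x) & !(df[[j]] %in% c("NA", "")))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row %d, column '%s'",
                   bad[1], names(df)[j]), call. = FALSE)
    }
    x
  })
  wl <- num[[1]]
  if (any(diff(wl) <= 0)) {
    stop("wavelength_nm column must be strictly increasing", call. = FALSE)
  }
  out <- lapply(num[-1], function(v) spectrum(wl, v, level = level, quantity = quantity))
  names(out) <- names(df)[-1]
  out
}

#' Write spectra as a wide delimited-text table
#'
#' @param spectra A single [spectrum] or a (named) list of spectra sharing one
#'   wavelength grid.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, sep = ",") {
  if (inherits(spectra, "spectrum")) spectra <- list(sample = spectra)
  wl <- spectra[[1]]$wavelength
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wavelength, wl))) {
      stop("all spectra must share one wavelength grid", call. = FALSE)
    }
  }
  nm <- names(spectra)
  if (is.null(nm)) nm <- paste0("S", seq_along(spectra))
  df <- data.frame(wavelength_nm = wl, check.names = FALSE)
  for (k in seq_along(spectra)) df[[nm[k]]] <- spectra[[k]]$value
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a spectrum to the VNIR domain
#'
#' Keeps bands with `lo <= wavelength <= hi`. The 400-1000 nm default is the
#' domain shared by field spectroradiometer and airborne VNIR data, on which
#' the whole index search operates.
#'
#' @param sp A [spectrum].
#' @param lo,hi Inclusive wavelength bounds in nm.
#' @return A [spectrum] on the restricted grid.
#' @export
restrict_vnir <- function(sp, lo = 400, hi = 1000) {
  stopifnot(inherits(sp, "spectrum"))
  keep <- sp$wavelength >= lo & sp$wavelength <= hi
  if (!any(keep)) {
    stop(sprintf("no bands in [%g, %g] nm", lo, hi), call. = FALSE)
  }
  spectrum(sp$wavelength[keep], sp$value[keep],
           level = sp$level, quantity = sp$quantity)
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Local least-squares polynomial filtering, the standard noise-suppression
#' step for reflectance spectra. Defaults (window 11 bands, cubic) preserve
#' the red-edge shape at 5.2-nm sampling. Exact on polynomials of degree
#' `<= polyorder`, so a constant or low-degree spectrum passes through
#' unchanged.
#'
#' @param sp A [spectrum] (or a plain numeric vector, smoothed as-is).
#' @param window Odd window length in bands; must satisfy
#'   `polyorder < window <= n_bands`.
#' @param polyorder Polynomial order of the local fit.
#' @return Smoothed spectrum on the same grid.
#' @export
savgol_smooth <- function(sp, window = 11, polyorder = 3) {
  vec <- if (inherits(sp, "spectrum")) sp$value else as.numeric(sp)
  n <- length(vec)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window > n) stop("window exceeds the number of bands", call. = FALSE)
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  sm <- as.numeric(signal::sgolayfilt(vec, p = polyorder, n = window))
  if (!inherits(sp, "spectrum")) return(sm)
  # the filter can nudge values a hair outside [0,1]; clamp to the physical range
  if (sp$quantity == "reflectance") sm <- pmin(pmax(sm, 0), 1.2)
  spectrum(sp$wavelength, sm, level = sp$level, quantity = sp$quantity)
}

#' Per-band empirical-line coefficients from calibration panels
#'
#' Least-squares gain/offset per band mapping at-sensor radiance to surface
#' reflectance, using ground panels of known reflectance. With exactly two
#' panels the fitted line interpolates them.
#'
#' @param panels List of panels, each a list with numeric vectors `radiance`
#'   and `reflectance` of equal band count.
#' @return List with numeric vectors `gain` and `offset` (one entry per band).
#' @export
empirical_line_coef <- function(panels) {
  if (!is.list(panels) || length(panels) < 2L) {
    stop("empirical-line fit needs >= 2 calibration panels", call. = FALSE)
  }
  rad <- do.call(rbind, lapply(panels, function(p) as.numeric(p$radiance)))
  ref <- do.call(rbind, lapply(panels, function(p) as.numeric(p$reflectance)))
  if (!all(dim(rad) == dim(ref))) {
    stop("panel radiance/reflectance lengths disagree", call. = FALSE)
  }
  nb <- ncol(rad)
  gain <- offset <- numeric(nb)
  for (b in seq_len(nb)) {
    x <- rad[, b]
    if (max(x) - min(x) <= 0) {
      stop(sprintf("identical panel radiances in band %d: singular fit", b),
           call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(1, x), ref[, b])
    offset[b] <- fit$coefficients[1]
    gain[b] <- fit$coefficients[2]
  }
  list(gain = gain, offset = offset)
}

#' Empirical-line radiance-to-reflectance correction
#'
#' Applies per-band gain/offset fitted from calibration panels (see
#' [empirical_line_coef()]) to spectra or a hyperspectral cube.
#'
#' @param x A [spectrum], a list of spectra, a numeric matrix
#'   (samples x bands), or a [hypercube].
#' @param panels Calibration panels, as for [empirical_line_coef()].
#' @return Object of the same shape as `x`, in reflectance units, with the
#'   fitted `gain` and `offset` attached as attributes.
#' @export
empirical_line <- function(x, panels) {
  cf <- empirical_line_coef(panels)
  apply_band <- function(v) cf$gain * v + cf$offset
  out <- if (inherits(x, "spectrum")) {
    spectrum(x$wavelength, apply_band(x$value), level = x$level,
             quantity = "reflectance")
  } else if (inherits(x, "hypercube")) {
    d <- x$data
    for (b in seq_len(dim(d)[3])) d[, , b] <- cf$gain[b] * d[, , b] + cf$offset[b]
    hypercube(d, x$wavelength, geotransform = x$geotransform,
              nodata = x$nodata, crs = x$crs)
  } else if (is.matrix(x)) {
    sweep(sweep(x, 2, cf$gain, `*`), 2, cf$offset, `+`)
  } else if (is.list(x)) {
    lapply(x, empirical_line, panels = panels)
  } else {
    stop("unsupported input to empirical_line", call. = FALSE)
  }
  attr(out, "gain") <- cf$gain
  attr(out, "offset") <- cf$offset
  out
}

#' Resample a spectrum onto a target band grid
#'
#' For each target center, the nearest source band is used when it lies within
#' the grid's matching tolerance; otherwise the value is linearly interpolated
#' from the bracketing source bands. Centers outside the source wavelength
#' range are an error. The per-band mode used is recorded in the `mode`
#' attribute (`"nearest"` or `"interp"`).
#'
#' @param sp A [spectrum].
#' @param grid A [band_grid] (or numeric centers, tolerance 2.6 nm).
#' @return A [spectrum] on `grid`.
#' @export
resample_to_grid <- function(sp, grid) {
  stopifnot(inherits(sp, "spectrum"))
  if (!inherits(grid, "band_grid")) grid <- band_grid(grid)
  ctr <- grid$centers
  rng <- range(sp$wavelength)
  if (any(ctr < rng[1] | ctr > rng[2])) {
    bad <- ctr[ctr < rng[1] | ctr > rng[2]][1]
    stop(sprintf("grid center %.1f nm outside source range [%.1f, %.1f] nm",
                 bad, rng[1], rng[2]), call. = FALSE)
  }
  near_idx <- vapply(ctr, function(l) which.min(abs(sp$wavelength - l)), 1L)
  near_d <- abs(sp$wavelength[near_idx] - ctr)
  use_near <- near_d <= grid$match_tolerance
  val <- stats::approx(sp$wavelength, sp$value, xout = ctr, method = "linear")$y
  val[use_near] <- sp$value[near_idx[use_near]]
  out <- spectrum(ctr, val, level = sp$level, quantity = sp$quantity)
  attr(out, "mode") <- ifelse(use_near, "nearest", "interp")
  out
}
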