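#' Construct a spectrum
#'
#' A spectrum couples a strictly increasing wavelength grid (nm) with one
#' measurement per band, tagged by acquisition level and physical quantity.
#' Reflectance values above 1 are retained (empirical-line correction can
#' slightly overshoot) but flagged; values outside \[0, 1.2\] are rejected.
#'
#' @param wavelength Numeric vector of band centers in nm, strictly increasing.
#' @param value Numeric vector, one value per band.
#' @param level Acquisition level: `"leaf"`, `"canopy"` or `"pixel"`.
#' @param quantity `"reflectance"` or `"radiance"` (radiance is unconstrained).
#' @return An object of class `spectrum`: a list with elements `wavelength`,
#'   `value`, `level`, `quantity` and an `overshoot` flag.
#' @examples
#' s <- spectrum(seq(400, 900, 10), rep(0.3, 51))
#' print(s)
#' @export
spectrum <- function(wavelength, value,
                     level = c("leaf", "canopy", "pixel"),
                     quantity = c("reflectance", "radiance")) {
  level <- match.arg(level)
  quantity <- match.arg(quantity)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) != length(value)) {
    stop("wavelength and value must have the same length", call. = FALSE)
  }
  if (length(wavelength) < 1L || anyNA(wavelength)) {
    stop("wavelength grid must be non-empty and finite", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  overshoot <- FALSE
  if (quantity == "reflectance") {
    v <- value[is.finite(value)]
    if (any(v < 0 | v > 1.2)) {
      stop("reflectance outside the tolerated [0, 1.2] range", call. = FALSE)
    }
    overshoot <- any(v > 1)
  }
  structure(list(wavelength = wavelength, value = value, level = level,
                 quantity = quantity, overshoot = overshoot),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s %s, %d bands [%.1f, %.1f] nm%s\n",
              x$level, x$quantity, length(x$wavelength),
              min(x$wavelength), max(x$wavelength),
              if (isTRUE(x$overshoot)) " (overshoot flagged)" else ""))
  invisible(x)
}

#' Band grid with matching tolerance
#'
#' A target wavelength grid plus the tolerance (nm) within which a requested
#' wavelength is considered to hit an existing band center. The default
#' tolerance, 2.6 nm, is half the 5.2-nm sampling interval of the airborne
#' VNIR imager the default grid mimics.
#'
#' @param centers Strictly increasing band centers in nm.
#' @param match_tolerance Positive matching tolerance in nm.
#' @return An object of class `band_grid`.
#' @export
band_grid <- function(centers, match_tolerance = 2.6) {
  centers <- as.numeric(centers)
  if (length(centers) < 1L || anyNA(centers) || any(diff(centers) <= 0)) {
    stop("band centers must be finite and strictly increasing", call. = FALSE)
  }
  if (!is.numeric(match_tolerance) || match_tolerance <= 0) {
    stop("match_tolerance must be > 0", call. = FALSE)
  }
  structure(list(centers = centers, match_tolerance = match_tolerance),
            class = "band_grid")
}

#' Default VNIR image band grid
#'
#' Band centers spanning 414-992 nm at a 5.2-nm sampling interval, the grid
#' of the airborne VNIR sensor emulated by the synthetic-data generator.
#'
#' @return Numeric vector of band centers (nm).
#' @export
vnir_band_grid <- function() seq(414, 992, by = 5.2)

# Nearest-band lookup: index of the band closest to lambda, error when the
# closest center is farther than `tolerance`.
resolve_band <- function(wavelength, lambda, tolerance = 2.6) {
  d <- abs(wavelength - lambda)
  i <- which.min(d)
  if (d[i] > tolerance) {
    stop(sprintf("no band within %.2f nm of %.1f nm (nearest: %.1f nm)",
                 tolerance, lambda, wavelength[i]), call. = FALSE)
  }
  i
}
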