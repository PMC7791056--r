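#' Hyperspectral reflectance cube
#'
#' In-memory raster of band reflectances with wavelength metadata and an
#' affine geotransform. The geotransform follows the common six-element
#' convention `(x0, dx, rx, y0, ry, dy)`: the world coordinates of the center
#' of pixel (row, col), 1-based, are
#' `x = x0 + (col - 0.5) dx + (row - 0.5) rx` and
#' `y = y0 + (col - 0.5) ry + (row - 0.5) dy` (dy is negative for
#' north-up rasters).
#'
#' @param data Numeric array `rows x cols x bands`.
#' @param wavelength Band centers (nm), strictly increasing, one per band.
#' @param geotransform Numeric length-6 affine transform.
#' @param nodata Sentinel value for missing pixels.
#' @param crs Free-text coordinate reference label.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(data, wavelength,
                      geotransform = c(0, 1, 0, 0, 0, -1),
                      nodata = -9999, crs = "arbitrary") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a rows x cols x bands array", call. = FALSE)
  }
  wavelength <- as.numeric(wavelength)
  if (dim(data)[3] != length(wavelength)) {
    stop("band count must equal wavelength count", call. = FALSE)
  }
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  geotransform <- as.numeric(geotransform)
  if (length(geotransform) != 6L ||
      abs(geotransform[2] * geotransform[6] - geotransform[3] * geotransform[5]) < 1e-12) {
    stop("geotransform must be length 6 and invertible", call. = FALSE)
  }
  structure(list(data = data, wavelength = wavelength,
                 geotransform = geotransform, nodata = nodata, crs = crs),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands [%.1f, %.1f] nm, nodata %g\n",
              d[1], d[2], d[3], min(x$wavelength), max(x$wavelength), x$nodata))
  invisible(x)
}

#' World coordinates of all pixel centers
#'
#' @param cube A [hypercube] (or anything with `$geotransform`).
#' @param dims Raster dimensions `c(rows, cols)`; defaults to the cube's.
#' @return List with matrices `x` and `y` (rows x cols).
#' @export
pixel_centers <- function(cube, dims = dim(cube$data)[1:2]) {
  gt <- cube$geotransform
  rows <- dims[1]; cols <- dims[2]
  cc <- matrix(rep(seq_len(cols) - 0.5, each = rows), rows, cols)
  rr <- matrix(rep(seq_len(rows) - 0.5, times = cols), rows, cols)
  list(x = gt[1] + cc * gt[2] + rr * gt[3],
       y = gt[4] + cc * gt[5] + rr * gt[6])
}

#' Write a cube (or single-band layer) as an ENVI raster
#'
#' Writes band-sequential (BSQ) binary data alongside a standard ENVI text
#' header carrying the wavelength list, the nodata sentinel and the
#' geotransform. Data are stored as 64-bit floats so a read-back is
#' bit-identical.
#'
#' @param x A [hypercube], or a numeric matrix (single band).
#' @param path Output path without extension; `<path>.dat` and `<path>.hdr`
#'   are written.
#' @param wavelength Band centers when `x` is a matrix (optional).
#' @param geotransform,nodata Metadata when `x` is a matrix.
#' @return `path`, invisibly.
#' @export
write_envi <- function(x, path, wavelength = NULL,
                       geotransform = c(0, 1, 0, 0, 0, -1), nodata = -9999) {
  if (inherits(x, "hypercube")) {
    arr <- x$data; wavelength <- x$wavelength
    geotransform <- x$geotransform; nodata <- x$nodata
  } else if (is.matrix(x)) {
    nd <- attr(x, "nodata")
    if (!is.null(nd)) nodata <- nd
    arr <- array(unclass(x), dim = c(nrow(x), ncol(x), 1L))
  } else {
    stop("x must be a hypercube or a matrix", call. = FALSE)
  }
  d <- dim(arr)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  for (b in seq_len(d[3])) {
    # BSQ, row-major within band (BIP/BIL readers expect samples fastest)
    writeBin(as.vector(t(arr[, , b])), con, size = 8, endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = {specmetal raster}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("data ignore value = %.10g", nodata),
    sprintf("geo transform = {%s}", paste(format(geotransform, digits = 15),
                                          collapse = ", ")),
    if (!is.null(wavelength)) "wavelength units = Nanometers",
    if (!is.null(wavelength)) {
      sprintf("wavelength = {%s}", paste(format(wavelength, digits = 10),
                                         collapse = ", "))
    }
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read an ENVI raster written by [write_envi()]
#'
#' Supports BSQ interleave with data type 4 (float32) or 5 (float64).
#'
#' @param path Path without extension (expects `<path>.dat` + `<path>.hdr`).
#' @return A [hypercube] when the file has wavelength metadata, otherwise (for
#'   single-band layers without wavelengths) a numeric matrix with `nodata`
#'   and `geotransform` attributes.
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  dat_path <- paste0(path, ".dat")
  if (!file.exists(hdr_path) || !file.exists(dat_path)) {
    stop("missing .hdr/.dat pair at ", path, call. = FALSE)
  }
  lines <- readLines(hdr_path, warn = FALSE)
  # fold multi-line { ... } values onto one line
  txt <- paste(lines, collapse = "\n")
  get_scalar <- function(key, default = NULL) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key, "\\s*=\\s*([^\\{\\n]+)$"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(default)
    trimws(m[2])
  }
  get_list <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(m[2], "[,\n]+")[[1]])
  }
  samples <- as.integer(get_scalar("samples"))
  rows <- as.integer(get_scalar("lines"))
  bands <- as.integer(get_scalar("bands"))
  dtype <- as.integer(get_scalar("data type"))
  interleave <- tolower(get_scalar("interleave", "bsq"))
  if (interleave != "bsq") stop("only BSQ interleave is supported", call. = FALSE)
  if (!dtype %in% c(4L, 5L)) stop("only data types 4/5 (float) supported", call. = FALSE)
  size <- if (dtype == 4L) 4L else 8L
  nodata <- as.numeric(get_scalar("data ignore value", "-9999"))
  gt <- get_list("geo transform")
  if (is.null(gt)) gt <- c(0, 1, 0, 0, 0, -1)
  wl <- get_list("wavelength(?! units)")
  con <- file(dat_path, "rb")
  on.exit(close(con))
  arr <- array(NA_real_, dim = c(rows, samples, bands))
  for (b in seq_len(bands)) {
    v <- readBin(con, "double", n = rows * samples, size = size, endian = "little")
    arr[, , b] <- matrix(v, nrow = rows, byrow = TRUE)
  }
  if (!is.null(wl) && length(wl) == bands && bands > 1L) {
    hypercube(arr, wl, geotransform = gt, nodata = nodata)
  } else if (bands == 1L) {
    out <- arr[, , 1]
    attr(out, "nodata") <- nodata
    attr(out, "geotransform") <- gt
    if (!is.null(wl)) attr(out, "wavelength") <- wl
    out
  } else {
    stop("multi-band file without wavelength metadata", call. = FALSE)
  }
}
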