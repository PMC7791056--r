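#' Normalized-difference index of a spectrum at two wavelengths
#'
#' Computes `(rho_i - rho_j) / (rho_i + rho_j)` with each wavelength resolved
#' to the nearest band center within `tolerance`. The value lies in
#' \[-1, 1\] and flips sign exactly when the wavelengths are swapped; it is
#' `NA` when the denominator is below `1e-9`.
#'
#' @param sp A [spectrum].
#' @param lambda_i,lambda_j Requested wavelengths (nm).
#' @param tolerance Band-matching tolerance (nm).
#' @return Scalar index value, or `NA` if undefined.
#' @export
ndvi_index <- function(sp, lambda_i, lambda_j, tolerance = 2.6) {
  stopifnot(inherits(sp, "spectrum"))
  i <- resolve_band(sp$wavelength, lambda_i, tolerance)
  j <- resolve_band(sp$wavelength, lambda_j, tolerance)
  ri <- sp$value[i]; rj <- sp$value[j]
  s <- ri + rj
  if (!is.finite(s) || s <= 1e-9) return(NA_real_)
  (ri - rj) / s
}

# Pearson r and two-sided p for y against each column of V (n x m).
# Columns with any NA or zero variance give NA. Returns list(r, p).
.pearson_cols <- function(V, y, n) {
  ok <- colSums(!is.finite(V)) == 0
  r <- rep(NA_real_, ncol(V))
  if (any(ok)) {
    Vc <- V[, ok, drop = FALSE]
    sv <- apply(Vc, 2, stats::sd)
    yc <- y - mean(y)
    sy <- stats::sd(y)
    # sum(v * yc) = sum((v - vbar)(y - ybar)) since yc sums to zero
    num <- colSums(Vc * yc)
    den <- (n - 1) * sv * sy
    rr <- num / pmax(den, .Machine$double.eps)
    rr[den <= 0] <- NA_real_
    rr <- pmin(pmax(rr, -1), 1)
    r[ok] <- rr
  }
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[is.na(r)] <- NA_real_
  p[abs(r) >= 1 - 1e-15] <- 0
  list(r = r, p = p)
}

#' Correlation of each single band with a metal concentration
#'
#' Pearson r and two-sided p-value between reflectance at every band and the
#' per-sample metal concentration — the screening step that locates the
#' spectral regions responsive to a metal before the two-band search.
#'
#' @param samples A `sample_set` (see [generate_sample_set()]), or a numeric
#'   samples x bands matrix with a `wavelength` attribute.
#' @param metal Metal column name in `samples$leaf_conc` (or a numeric
#'   concentration vector).
#' @param level Acquisition level of the spectra to screen.
#' @return Data frame with columns `wavelength`, `r`, `p`.
#' @export
single_band_correlation <- function(samples, metal, level = "leaf") {
  xt <- .spectra_matrix(samples, level)
  y <- .metal_vector(samples, metal)
  n <- nrow(xt$S)
  if (n < 4L) stop("need >= 4 samples", call. = FALSE)
  if (stats::sd(y) == 0) {
    warning("zero-variance concentration vector: correlations undefined",
            call. = FALSE)
    return(data.frame(wavelength = xt$wavelength,
                      r = NA_real_, p = NA_real_))
  }
  pc <- .pearson_cols(xt$S, y, n)
  data.frame(wavelength = xt$wavelength, r = pc$r, p = pc$p)
}

#' Shapiro-Wilk normality precheck
#'
#' The index-concentration correlations assume approximately normal
#' concentrations; this wraps the Shapiro-Wilk test and flags a pass at
#' `p > 0.05`. A failed check warns rather than aborts.
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return List with `statistic`, `p`, `pass`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  pass <- sw$p.value > 0.05
  if (!pass) {
    warning(sprintf("normality rejected (W = %.3f, p = %.3g)",
                    unname(sw$statistic), sw$p.value), call. = FALSE)
  }
  list(statistic = unname(sw$statistic), p = sw$p.value, pass = pass)
}

# internal: accept sample_set or matrix-with-wavelength
.spectra_matrix <- function(samples, level = "leaf") {
  if (inherits(samples, "sample_set")) {
    list(S = samples[[level]], wavelength = samples$wavelength)
  } else if (is.matrix(samples)) {
    wl <- attr(samples, "wavelength")
    if (is.null(wl)) stop("matrix input needs a 'wavelength' attribute", call. = FALSE)
    list(S = samples, wavelength = as.numeric(wl))
  } else if (is.list(samples) && all(vapply(samples, inherits, TRUE, "spectrum"))) {
    wl <- samples[[1]]$wavelength
    same <- vapply(samples, function(s) {
      length(s$wavelength) == length(wl) && all(s$wavelength == wl)
    }, TRUE)
    if (!all(same)) {
      stop("spectra are on mixed wavelength grids; resample_to_grid() them first",
           call. = FALSE)
    }
    list(S = do.call(rbind, lapply(samples, `[[`, "value")), wavelength = wl)
  } else {
    stop("unsupported spectra container", call. = FALSE)
  }
}

.metal_vector <- function(samples, metal) {
  if (is.numeric(metal)) return(as.numeric(metal))
  if (inherits(samples, "sample_set")) {
    y <- samples$leaf_conc[[metal]]
    if (is.null(y)) stop("unknown metal: ", metal, call. = FALSE)
    return(y)
  }
  stop("metal must be a numeric vector for non-sample_set input", call. = FALSE)
}

# Core pairwise index-correlation engine on a spectra matrix.
.correlation_map_mat <- function(S, y, wavelength, metal = "metal") {
  n <- nrow(S); k <- ncol(S)
  if (n < 4L) stop("need >= 4 samples", call. = FALSE)
  r <- matrix(NA_real_, k, k)
  p <- matrix(NA_real_, k, k)
  if (stats::sd(y) == 0) {
    warning("zero-variance concentration vector: map undefined", call. = FALSE)
  } else {
    for (i in seq_len(k - 1L)) {
      jj <- (i + 1L):k
      D <- S[, i] - S[, jj, drop = FALSE]
      Ssum <- S[, i] + S[, jj, drop = FALSE]
      V <- D / Ssum
      V[Ssum <= 1e-9] <- NA_real_
      pc <- .pearson_cols(V, y, n)
      r[i, jj] <- pc$r
      r[jj, i] <- -pc$r
      p[i, jj] <- pc$p
      p[jj, i] <- pc$p
    }
  }
  structure(list(wavelength = wavelength, r = r, p = p, metal = metal, n = n),
            class = "correlation_map")
}

#' Exhaustive two-band index correlation map
#'
#' For every unordered VNIR band pair, computes the normalized-difference
#' index per sample and its Pearson correlation (with two-sided p-value)
#' against the metal concentration. The matrix entry `(a, b)` corresponds to
#' the index `(rho_a - rho_b) / (rho_a + rho_b)`, so the map is antisymmetric
#' (`r[a,b] = -r[b,a]`); the diagonal (an identically-zero index) is
#' undefined. Pairs whose index is undefined for any sample are `NA`.
#'
#' @inheritParams single_band_correlation
#' @return An object of class `correlation_map`: list with `wavelength`,
#'   `r` and `p` (k x k matrices), `metal`, `n`.
#' @export
correlation_map <- function(samples, metal, level = "leaf") {
  xt <- .spectra_matrix(samples, level)
  y <- .metal_vector(samples, metal)
  .correlation_map_mat(xt$S, y, xt$wavelength,
                       metal = if (is.character(metal)) metal else "metal")
}

#' @export
print.correlation_map <- function(x, ...) {
  nd <- sum(is.finite(x$r))
  cat(sprintf("<correlation_map> %s: %d bands, n = %d, %d defined pairs, max |r| = %.3f\n",
              x$metal, length(x$wavelength), x$n, nd / 2,
              if (nd) max(abs(x$r), na.rm = TRUE) else NA))
  invisible(x)
}

#' Select the best-correlated index from a correlation map
#'
#' Among band pairs significant at `alpha`, returns the pair maximizing
#' `|r|`. Ties are broken by smaller p-value, then by the lexicographically
#' smaller `(min wavelength, max wavelength)` pair. The reported orientation
#' puts the longer wavelength first (`lambda_i > lambda_j`), with `r_cal`
#' signed for that orientation.
#'
#' @param map A `correlation_map`.
#' @param alpha Significance level for admission (default 0.05).
#' @return An object of class `optimized_index`: `metal`, `lambda_i`,
#'   `lambda_j`, `r_cal`, `p_cal`, `n`.
#' @export
select_best_index <- function(map, alpha = 0.05) {
  stopifnot(inherits(map, "correlation_map"))
  k <- length(map$wavelength)
  ut <- upper.tri(map$r)
  cand <- which(ut & is.finite(map$r) & map$p < alpha, arr.ind = TRUE)
  if (!nrow(cand)) {
    stop("no significant index: no band pair reaches p < ", alpha, call. = FALSE)
  }
  av <- abs(map$r[cand])
  pv <- map$p[cand]
  wl_lo <- map$wavelength[cand[, 1]]
  wl_hi <- map$wavelength[cand[, 2]]
  ord <- order(-av, pv, wl_lo, wl_hi)
  best <- cand[ord[1], ]
  lo <- map$wavelength[best[1]]; hi <- map$wavelength[best[2]]
  # orientation: longer wavelength is rho_i
  r_or <- map$r[best[2], best[1]]
  structure(list(metal = map$metal, lambda_i = hi, lambda_j = lo,
                 r_cal = r_or, p_cal = map$p[best[1], best[2]], n = map$n),
            class = "optimized_index")
}

#' @export
print.optimized_index <- function(x, ...) {
  cat(sprintf(
    "<optimized_index> %s: (rho_%.1f - rho_%.1f)/(rho_%.1f + rho_%.1f), r = %.3f (p = %.2g, n = %d)\n",
    x$metal, x$lambda_i, x$lambda_j, x$lambda_i, x$lambda_j,
    x$r_cal, x$p_cal, x$n))
  invisible(x)
}

# index values for an optimized_index over a spectra matrix
.index_values <- function(S, wavelength, idx, tolerance = 2.6) {
  i <- resolve_band(wavelength, idx$lambda_i, tolerance)
  j <- resolve_band(wavelength, idx$lambda_j, tolerance)
  s <- S[, i] + S[, j]
  v <- (S[, i] - S[, j]) / s
  v[!is.finite(s) | s <= 1e-9] <- NA_real_
  v
}

#' Compute an optimized index over a set of spectra
#'
#' @param samples A `sample_set`, spectra matrix (with `wavelength`
#'   attribute), or list of spectra on one grid.
#' @param index An `optimized_index` (from [select_best_index()]).
#' @param level Acquisition level when `samples` is a `sample_set`.
#' @return Numeric vector of index values, one per sample.
#' @export
index_values <- function(samples, index, level = "leaf") {
  xt <- .spectra_matrix(samples, level)
  .index_values(xt$S, xt$wavelength, index)
}
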