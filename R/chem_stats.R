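#' Bioconcentration factor (BCF)
#'
#' Ratio of the metal concentration in leaves to that in the soil the plant
#' grows on; values near or above 1 indicate active accumulation. Vectorized
#' over paired per-plot samples.
#'
#' @param leaf_conc Leaf concentration(s), mg kg-1, >= 0.
#' @param soil_conc Soil concentration(s), mg kg-1, > 0.
#' @return Dimensionless ratio(s) `leaf_conc / soil_conc`.
#' @export
bcf <- function(leaf_conc, soil_conc) {
  if (any(!is.finite(soil_conc)) || any(soil_conc <= 0)) {
    stop("soil concentration must be > 0", call. = FALSE)
  }
  if (any(leaf_conc < 0, na.rm = TRUE)) {
    stop("leaf concentration must be >= 0", call. = FALSE)
  }
  leaf_conc / soil_conc
}

#' Enrichment factor (EF)
#'
#' Ratio of the leaf metal concentration on the polluted site to that of
#' leaves from a matched uncontaminated control site.
#'
#' @param brownfield_leaf_conc Polluted-site leaf concentration(s), mg kg-1.
#' @param control_leaf_conc Control-site leaf concentration(s), mg kg-1, > 0.
#' @return Dimensionless ratio(s).
#' @export
ef <- function(brownfield_leaf_conc, control_leaf_conc) {
  if (any(!is.finite(control_leaf_conc)) || any(control_leaf_conc <= 0)) {
    stop("control concentration must be > 0", call. = FALSE)
  }
  if (any(brownfield_leaf_conc < 0, na.rm = TRUE)) {
    stop("brownfield concentration must be >= 0", call. = FALSE)
  }
  brownfield_leaf_conc / control_leaf_conc
}

#' Coefficient of variation (percent) from moments
#'
#' @param mean Arithmetic mean (non-zero).
#' @param sd Standard deviation.
#' @return `100 * sd / mean`, or `NA` with a warning when `mean` is 0.
#' @export
cv_percent <- function(mean, sd) {
  out <- 100 * sd / mean
  zero <- mean == 0
  if (any(zero)) {
    warning("CV undefined where mean is 0", call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Descriptive statistics for a metal concentration panel
#'
#' Per-metal range, mean, sample SD (n-1 denominator, the chemometrics
#' convention) and coefficient of variation.
#'
#' @param panel Data frame with one numeric column per metal; columns
#'   `sample_id`/`compartment`, if present, are ignored.
#' @return Data frame with columns `metal`, `n`, `min`, `max`, `mean`, `sd`,
#'   `cv_percent`.
#' @export
summarize_metals <- function(panel) {
  cols <- setdiff(names(panel), c("sample_id", "compartment"))
  cols <- cols[vapply(panel[cols], is.numeric, TRUE)]
  if (!length(cols)) stop("no numeric metal columns found", call. = FALSE)
  rows <- lapply(cols, function(m) {
    x <- panel[[m]]
    x <- x[is.finite(x)]
    if (length(x) < 2L) stop("need >= 2 samples per metal (", m, ")", call. = FALSE)
    if (any(x < 0)) stop("negative concentration in ", m, call. = FALSE)
    s <- stats::sd(x)
    data.frame(metal = m, n = length(x), min = min(x), max = max(x),
               mean = mean(x), sd = s,
               cv_percent = if (mean(x) == 0) NA_real_ else 100 * s / mean(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
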