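#' Kennard-Stone calibration/validation split
#'
#' Deterministic max-min design in a feature space (by default the smoothed
#' VNIR spectra): the two mutually most distant samples seed the calibration
#' set, then the sample farthest (in minimum Euclidean distance) from the
#' current set is added until `floor(fraction * n)` samples are selected.
#' The remainder forms the validation set. Distance ties are resolved by the
#' smallest sample index, so the split is reproducible.
#'
#' @param x A `sample_set` or a numeric samples x features matrix.
#' @param fraction Target calibration share in (0, 1\].
#' @param features Optional feature matrix overriding the default (smoothed
#'   leaf spectra for a `sample_set`).
#' @param level Spectra level used for the default features.
#' @return Object of class `split_result`: integer vectors `calibration` and
#'   `validation` (indices), matching `ids` when available, and `fraction`.
#' @export
kennard_stone_split <- function(x, fraction = 2 / 3, features = NULL,
                                level = "leaf") {
  if (is.null(features)) {
    if (inherits(x, "sample_set")) {
      S <- x[[level]]
      features <- t(apply(S, 1, function(v) {
        as.numeric(signal::sgolayfilt(v, p = 3, n = min(11L, length(v) - (1 - length(v) %% 2))))
      }))
    } else if (is.matrix(x)) {
      features <- x
    } else {
      features <- as.matrix(x)
    }
  }
  n <- nrow(features)
  if (n < 3L) stop("need >= 3 samples to split", call. = FALSE)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  k <- floor(fraction * n)
  if (k < 2L) stop("fraction too small: < 2 calibration samples", call. = FALSE)
  D <- as.matrix(stats::dist(features))
  m <- max(D)
  cand <- which(D == m, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  if (nrow(cand) > 1L) {
    warning("tied most-distant seed pairs; using the lowest-index pair",
            call. = FALSE)
  }
  sel <- as.integer(cand[1, ])
  while (length(sel) < k) {
    rem <- setdiff(seq_len(n), sel)
    dmin <- apply(D[rem, sel, drop = FALSE], 1, min)
    sel <- c(sel, rem[which.max(dmin)])  # which.max takes the first = lowest index
  }
  sel <- sort(sel)
  ids <- if (inherits(x, "sample_set")) x$ids else NULL
  structure(list(calibration = sel, validation = setdiff(seq_len(n), sel),
                 ids = ids, fraction = fraction),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d validation (fraction %.3f)\n",
              length(x$calibration), length(x$validation), x$fraction))
  invisible(x)
}

#' Fit a univariate index-concentration regression
#'
#' Ordinary least squares of concentration on the optimized index value.
#' Besides the default linear form `y = a x + b`, exponential
#' (`y = exp(b + a x)`, fitted on `log y`) and logarithmic
#' (`y = a log(x) + b`, requiring positive indices) forms are available via
#' the standard transform fits.
#'
#' @param index_x Index values (calibration set).
#' @param conc_y Concentrations, mg kg-1.
#' @param form `"linear"`, `"exponential"` or `"logarithmic"`.
#' @param metal,level Labels recorded on the model.
#' @return Object of class `index_regression`: `slope`, `intercept`, `form`,
#'   `r_cal` (Pearson r on the fitting scale), `n`, labels.
#' @export
fit_index_regression <- function(index_x, conc_y, form = c("linear", "exponential",
                                                           "logarithmic"),
                                 metal = "metal", level = "leaf") {
  form <- match.arg(form)
  ok <- is.finite(index_x) & is.finite(conc_y)
  x <- index_x[ok]; y <- conc_y[ok]
  n <- length(x)
  if (n < 2L) stop("need >= 2 finite calibration pairs", call. = FALSE)
  if (n == 2L) warning("two-point fit: interpolating line, r is degenerate",
                       call. = FALSE)
  xf <- switch(form, linear = x, exponential = x,
               logarithmic = {
                 if (any(x <= 0)) stop("logarithmic form needs positive indices",
                                       call. = FALSE)
                 log(x)
               })
  yf <- switch(form, linear = y, logarithmic = y,
               exponential = {
                 if (any(y <= 0)) stop("exponential form needs positive concentrations",
                                       call. = FALSE)
                 log(y)
               })
  if (stats::sd(xf) == 0) {
    if (stats::sd(yf) == 0) {
      # degenerate but well-defined: constant response
      return(structure(list(metal = metal, level = level, slope = 0,
                            intercept = yf[1], form = form, r_cal = NA_real_,
                            n = n), class = "index_regression"))
    }
    stop("zero-variance index: singular fit", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, xf), yf)
  r_cal <- if (stats::sd(yf) == 0) NA_real_ else stats::cor(xf, yf)
  structure(list(metal = metal, level = level,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 form = form, r_cal = r_cal, n = n),
            class = "index_regression")
}

#' @export
print.index_regression <- function(x, ...) {
  eq <- switch(x$form,
               linear = sprintf("y = %.4g x + %.4g", x$slope, x$intercept),
               exponential = sprintf("y = exp(%.4g + %.4g x)", x$intercept, x$slope),
               logarithmic = sprintf("y = %.4g log(x) + %.4g", x$slope, x$intercept))
  cat(sprintf("<index_regression> %s (%s level, %s): %s, r_cal = %.3f, n = %d\n",
              x$metal, x$level, x$form, eq, x$r_cal, x$n))
  invisible(x)
}

#' Predict concentrations from index values
#'
#' Applies the fitted form elementwise. Physically impossible negative
#' predictions are retained (the linear model is allowed to extrapolate) but
#' flagged in the `negative` attribute.
#'
#' @param object An `index_regression`.
#' @param newdata Numeric index values.
#' @param ... Unused.
#' @return Numeric concentrations (mg kg-1) with a logical `negative`
#'   attribute.
#' @export
predict.index_regression <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  out <- switch(object$form,
                linear = object$slope * x + object$intercept,
                exponential = exp(object$intercept + object$slope * x),
                logarithmic = object$slope * log(x) + object$intercept)
  attr(out, "negative") <- is.finite(out) & out < 0
  out
}

#' Prediction assessment: r, RMSE and RPD
#'
#' Pearson correlation between measured and predicted values, the root mean
#' square error `RMSE = sqrt(mean((predicted - measured)^2))`, and the
#' residual predictive deviation `RPD = sigma / RMSE`. By default `sigma` is
#' the sample SD (n-1) of the measured values in the assessed (validation)
#' set; `sigma` can be supplied to use, e.g., the full-dataset SD instead.
#' RPD above 2 is conventionally read as a good predictive model.
#'
#' @param measured,predicted Equal-length numeric vectors (n >= 2).
#' @param sigma Optional SD to use in the RPD numerator.
#' @return Object of class `prediction_report`: `r`, `rmse`, `rpd`, `n`,
#'   `good` (RPD > 2), `perfect` flag when RMSE is 0, and the
#'   (measured, predicted) pairs.
#' @export
assess <- function(measured, predicted, sigma = NULL) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (length(measured) != length(predicted)) {
    stop("measured and predicted must have equal length", call. = FALSE)
  }
  ok <- is.finite(measured) & is.finite(predicted)
  m <- measured[ok]; p <- predicted[ok]
  n <- length(m)
  if (n < 2L) stop("need >= 2 pairs to assess", call. = FALSE)
  rmse <- sqrt(mean((p - m)^2))
  if (is.null(sigma)) sigma <- stats::sd(m)
  perfect <- rmse == 0
  rpd <- if (perfect) Inf else sigma / rmse
  r <- if (stats::sd(m) == 0 || stats::sd(p) == 0) NA_real_ else stats::cor(m, p)
  structure(list(r = r, rmse = rmse, rpd = rpd, sigma = sigma, n = n,
                 good = is.finite(rpd) && rpd > 2, perfect = perfect,
                 pairs = data.frame(measured = m, predicted = p)),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> n = %d: r = %.3f, RMSE = %.4g, RPD = %.3g%s\n",
              x$n, x$r, x$rmse, x$rpd,
              if (isTRUE(x$good)) " (good: RPD > 2)" else ""))
  invisible(x)
}
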