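#' Fit an optimized spectral-index model for a metal
#'
#' The central estimator of the package. Given co-located reflectance spectra
#' and leaf metal concentrations it (1) splits the samples into calibration
#' and validation sets with the Kennard-Stone max-min design, (2) checks the
#' concentrations for normality (Shapiro-Wilk, warning on failure),
#' (3) searches all two-band normalized-difference indices on the calibration
#' set and keeps the pair with the highest significant `|r|`, (4) fits a
#' univariate regression of concentration on the index, and (5) predicts the
#' validation set, reporting r, RMSE and RPD.
#'
#' Passing a previously selected `index` skips the search — this is how the
#' leaf-level band pair is transferred to canopy or image-pixel spectra, where
#' only the regression coefficients are re-calibrated. Passing a `split`
#' shares one calibration/validation partition across acquisition levels.
#'
#' @param samples A `sample_set` (see [generate_sample_set()]) or a numeric
#'   samples x bands matrix with a `wavelength` attribute.
#' @param metal Metal name (column of `samples$leaf_conc`) or a numeric
#'   concentration vector (mg kg-1).
#' @param level Acquisition level of the spectra used: `"leaf"`, `"canopy"`
#'   or `"pixel"`.
#' @param fraction Calibration share for the Kennard-Stone split.
#' @param alpha Significance level for index admission.
#' @param form Regression form (see [fit_index_regression()]).
#' @param smooth Apply Savitzky-Golay smoothing before the search?
#' @param window,polyorder Smoothing parameters.
#' @param split Optional `split_result` to reuse.
#' @param index Optional `optimized_index` to reuse (skips the search).
#' @return Object of class `specmetal_fit` with components `metal`, `level`,
#'   `index` (`optimized_index`), `model` (`index_regression`), `split`,
#'   `calibration` and `validation` (index/concentration/prediction vectors),
#'   `report` (`prediction_report`), `normality` and `wavelength`.
#' @seealso [predict.specmetal_fit()], [map_metal()]
#' @examples
#' sim <- generate_sample_set(generator_config(seed = 3))
#' fit <- specmetal_fit(sim$samples, "Cu")
#' print(fit)
#' coef(fit)
#' @export
specmetal_fit <- function(samples, metal, level = c("leaf", "canopy", "pixel"),
                          fraction = 2 / 3, alpha = 0.05,
                          form = "linear", smooth = TRUE,
                          window = 11, polyorder = 3,
                          split = NULL, index = NULL) {
  level <- match.arg(level)
  xt <- .spectra_matrix(samples, level)
  S <- xt$S
  if (smooth) {
    S <- t(apply(S, 1, function(v) {
      pmin(pmax(as.numeric(signal::sgolayfilt(v, p = polyorder, n = window)), 0), 1.2)
    }))
  }
  y <- .metal_vector(samples, metal)
  if (length(y) != nrow(S)) stop("spectra/concentration length mismatch", call. = FALSE)
  metal_name <- if (is.character(metal)) metal else "metal"

  if (is.null(split)) {
    split <- kennard_stone_split(S, fraction = fraction, features = S)
  }
  cal <- split$calibration; val <- split$validation

  normality <- tryCatch(suppressWarnings(normality_check(y[cal])),
                        error = function(e) NULL)
  if (!is.null(normality) && !normality$pass) {
    warning(sprintf("%s calibration concentrations fail the normality precheck (p = %.3g)",
                    metal_name, normality$p), call. = FALSE)
  }

  if (is.null(index)) {
    Sw <- S
    attr(Sw, "wavelength") <- xt$wavelength
    map <- .correlation_map_mat(S[cal, , drop = FALSE], y[cal], xt$wavelength,
                                metal = metal_name)
    index <- select_best_index(map, alpha = alpha)
  }

  x_all <- .index_values(S, xt$wavelength, index)
  model <- fit_index_regression(x_all[cal], y[cal], form = form,
                                metal = metal_name, level = level)
  pred_val <- predict(model, x_all[val])
  report <- if (length(val) >= 2L) assess(y[val], pred_val) else NULL

  structure(list(metal = metal_name, level = level, index = index,
                 model = model, split = split,
                 calibration = list(index = x_all[cal], measured = y[cal],
                                    fitted = predict(model, x_all[cal])),
                 validation = list(index = x_all[val], measured = y[val],
                                   predicted = as.numeric(pred_val)),
                 report = report, normality = normality,
                 wavelength = xt$wavelength, smooth = smooth,
                 call = match.call()),
            class = "specmetal_fit")
}

#' @export
print.specmetal_fit <- function(x, ...) {
  cat(sprintf("Optimized spectral-index model for %s (%s level)\n",
              x$metal, x$level))
  cat(sprintf("  index: (rho_%.1f - rho_%.1f)/(rho_%.1f + rho_%.1f)\n",
              x$index$lambda_i, x$index$lambda_j,
              x$index$lambda_i, x$index$lambda_j))
  cat(sprintf("  calibration (n = %d): %s, r = %.3f\n",
              length(x$calibration$measured),
              sprintf("y = %.4g x + %.4g", x$model$slope, x$model$intercept),
              x$model$r_cal))
  if (!is.null(x$report)) {
    cat(sprintf("  validation  (n = %d): r = %.3f, RMSE = %.4g mg/kg, RPD = %.3g\n",
                x$report$n, x$report$r, x$report$rmse, x$report$rpd))
  }
  invisible(x)
}

#' @export
summary.specmetal_fit <- function(object, ...) {
  out <- list(metal = object$metal, level = object$level,
              lambda_i = object$index$lambda_i, lambda_j = object$index$lambda_j,
              slope = object$model$slope, intercept = object$model$intercept,
              form = object$model$form,
              r_cal = object$model$r_cal, p_index = object$index$p_cal,
              n_cal = length(object$calibration$measured),
              n_val = length(object$validation$measured),
              r_val = if (!is.null(object$report)) object$report$r else NA_real_,
              rmse = if (!is.null(object$report)) object$report$rmse else NA_real_,
              rpd = if (!is.null(object$report)) object$report$rpd else NA_real_,
              normality_p = if (!is.null(object$normality)) object$normality$p else NA_real_)
  class(out) <- "summary.specmetal_fit"
  out
}

#' @export
print.summary.specmetal_fit <- function(x, ...) {
  cat(sprintf("%s @ %s: index (%.1f, %.1f) nm | cal r = %.3f | val r = %.3f, RMSE = %.4g, RPD = %.3g\n",
              x$metal, x$level, x$lambda_i, x$lambda_j, x$r_cal,
              x$r_val, x$rmse, x$rpd))
  invisible(x)
}

#' @export
coef.specmetal_fit <- function(object, ...) {
  c(slope = object$model$slope, intercept = object$model$intercept)
}

#' Predict leaf metal concentrations from new spectra or index values
#'
#' @param object A [specmetal_fit()] model.
#' @param newdata Numeric index values, a `spectrum`, a list of spectra, or a
#'   samples x bands matrix with a `wavelength` attribute. Spectra are reduced
#'   to the model's optimized index first.
#' @param ... Unused.
#' @return Predicted concentrations (mg kg-1), `negative` attribute flagging
#'   sub-zero extrapolations.
#' @export
predict.specmetal_fit <- function(object, newdata, ...) {
  x <- if (is.numeric(newdata) && is.null(dim(newdata))) {
    as.numeric(newdata)
  } else if (inherits(newdata, "spectrum")) {
    ndvi_index(newdata, object$index$lambda_i, object$index$lambda_j)
  } else {
    xt <- .spectra_matrix(newdata)
    .index_values(xt$S, xt$wavelength, object$index)
  }
  predict(object$model, x)
}

#' @export
residuals.specmetal_fit <- function(object, set = c("calibration", "validation"), ...) {
  set <- match.arg(set)
  if (set == "calibration") {
    object$calibration$measured - object$calibration$fitted
  } else {
    object$validation$measured - object$validation$predicted
  }
}

#' @export
fitted.specmetal_fit <- function(object, ...) object$calibration$fitted

#' Measured-versus-predicted plot for an index model
#'
#' Scatter of validation (and optionally calibration) concentrations against
#' model predictions with the 1:1 line.
#'
#' @param x A `specmetal_fit`.
#' @param show_calibration Overlay calibration points?
#' @param ... Passed to [graphics::plot()].
#' @export
plot.specmetal_fit <- function(x, show_calibration = TRUE, ...) {
  m <- x$validation$measured; p <- x$validation$predicted
  rng <- range(c(m, p, if (show_calibration) unlist(x$calibration[c("measured", "fitted")])),
               na.rm = TRUE)
  graphics::plot(m, p, xlim = rng, ylim = rng,
                 xlab = sprintf("measured %s (mg/kg)", x$metal),
                 ylab = sprintf("predicted %s (mg/kg)", x$metal),
                 main = sprintf("%s @ %s level", x$metal, x$level),
                 pch = 19, ...)
  if (show_calibration) {
    graphics::points(x$calibration$measured, x$calibration$fitted,
                     pch = 1, col = "grey40")
  }
  graphics::abline(0, 1, lty = 2)
  if (!is.null(x$report)) {
    graphics::legend("topleft", bty = "n",
                     legend = sprintf("r = %.2f, RMSE = %.3g, RPD = %.2f",
                                      x$report$r, x$report$rmse, x$report$rpd))
  }
  invisible(x)
}
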