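#' Fit a NIPALS PLS1 regression model
#'
#' Mean-centered single-response partial least squares by NIPALS with
#' deflation. With the component count equal to the rank of the centered
#' predictor matrix the fit coincides with ordinary least squares.
#'
#' @param X numeric predictor matrix (samples x variables) or [spectrum_set()].
#' @param y numeric response vector (% SSC).
#' @param n_lv number of latent variables, `1 <= n_lv <= min(n-1, p)`.
#' @param meta optional list recorded with the model (preprocessing history,
#'   selected wavelength indices).
#' @return An object of class `pls_model` with centering vectors, per-LV
#'   weights/loadings/scores, the coefficient matrix for every component count
#'   up to `n_lv`, and `regression_vector` for `n_lv` components.
#' @export
pls_fit <- function(X, y, n_lv, meta = list()) {
  if (inherits(X, "spectrum_set")) {
    meta$history <- X$meta$history
    X <- X$intensities
  }
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("X rows and y length differ")
  if (n < 2) stop("need at least 2 samples")
  if (n_lv < 1 || n_lv > min(n - 1, p))
    stop(sprintf("n_lv must be in [1, %d]", min(n - 1, p)))
  if (sd(y) == 0) {
    warning("constant response: returning zero regression vector")
    model <- list(x_mean = colMeans(X), y_mean = mean(y),
                  weights = matrix(0, p, 1), x_loadings = matrix(0, p, 1),
                  y_loadings = 0, scores = matrix(0, n, 1),
                  coefficients = matrix(0, p, n_lv),
                  regression_vector = rep(0, p), n_lv = n_lv,
                  n_extracted = 0L, meta = meta)
    return(structure(model, class = "pls_model"))
  }
  fit <- cpp_pls_fit(X, y, as.integer(n_lv))
  model <- list(x_mean = as.numeric(fit$x_mean), y_mean = fit$y_mean,
                weights = fit$weights, x_loadings = fit$x_loadings,
                y_loadings = as.numeric(fit$y_loadings), scores = fit$scores,
                coefficients = fit$coefficients,
                regression_vector = fit$coefficients[, n_lv],
                n_lv = n_lv, n_extracted = fit$n_extracted, meta = meta)
  structure(model, class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d LVs over %d variables (y mean %.3f)\n",
              x$n_lv, length(x$regression_vector), x$y_mean))
  invisible(x)
}

#' Predict from a PLS model
#'
#' `y_hat = (X - x_mean) %*% regression_vector + y_mean`.
#'
#' @param object a `pls_model`.
#' @param newdata predictor matrix or [spectrum_set()] on the same variables.
#' @param n_lv component count to predict with (default: the fitted `n_lv`).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  if (inherits(newdata, "spectrum_set")) newdata <- newdata$intensities
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop(sprintf("newdata has %d variables; model expects %d",
                 ncol(newdata), length(object$x_mean)))
  if (n_lv < 1 || n_lv > ncol(object$coefficients)) stop("n_lv out of range")
  b <- object$coefficients[, n_lv]
  as.numeric(sweep(newdata, 2, object$x_mean) %*% b) + object$y_mean
}

# Fold assignment: LOO = 1..n; k-fold = balanced random assignment under seed.
cv_folds <- function(n, cv = c("loo", "kfold"), k = 5, seed = NULL) {
  cv <- match.arg(cv)
  if (cv == "loo") return(seq_len(n))
  if (k < 2 || k > n) stop("k must be in [2, n]")
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Cross-validated RMSE and latent-variable selection
#'
#' Computes RMSECV for component counts `1..max_lv` under leave-one-out or
#' k-fold cross-validation and selects the component count at the first
#' minimum (parsimony on ties).
#'
#' @param X predictor matrix or [spectrum_set()].
#' @param y response vector.
#' @param max_lv largest component count to evaluate; must be feasible for the
#'   smallest training fold.
#' @param cv `"loo"` or `"kfold"`.
#' @param k number of folds for `cv = "kfold"`.
#' @param seed seed for the fold assignment (k-fold only).
#' @param folds optional explicit fold id vector (overrides `cv`/`k`/`seed`),
#'   used to hold the assignment fixed across repeated objective evaluations.
#' @return An object of class `pls_cv`: `rmsecv_by_lv`, `chosen_lv`,
#'   `cv_scheme`.
#' @export
pls_rmsecv <- function(X, y, max_lv, cv = c("loo", "kfold"), k = 5,
                       seed = NULL, folds = NULL) {
  if (inherits(X, "spectrum_set")) X <- X$intensities
  X <- as.matrix(X); y <- as.numeric(y)
  cv <- match.arg(cv)
  n <- nrow(X)
  if (n != length(y)) stop("X rows and y length differ")
  if (is.null(folds)) folds <- cv_folds(n, cv, k, seed)
  folds <- as.integer(folds)
  min_train <- n - max(tabulate(folds))
  if (max_lv < 1 || max_lv > min(min_train - 1, ncol(X)))
    stop(sprintf("max_lv too large for fold size: must be <= %d",
                 min(min_train - 1, ncol(X))))
  rmse <- as.numeric(cpp_press(X, y, folds, as.integer(max_lv)))
  structure(list(rmsecv_by_lv = rmse,
                 chosen_lv = which.min(rmse),
                 cv_scheme = if (max(folds) == n) "loo" else sprintf("kfold(%d)", max(folds)),
                 folds = folds),
            class = "pls_cv")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("<pls_cv> %s; chosen LVs = %d (RMSECV %.4f)\n",
              x$cv_scheme, x$chosen_lv, x$rmsecv_by_lv[x$chosen_lv]))
  invisible(x)
}

#' Calibration/prediction performance metrics
#'
#' The correlation statistic is computed as printed in the source formula,
#' `r = 1 - SSE/SST` (algebraically a coefficient of determination); a Pearson
#' correlation variant is available via `r_method = "pearson"`. RMSE uses the
#' `1/n` denominator.
#'
#' @param y measured values.
#' @param y_hat predicted values.
#' @param r_method `"printed"` (default, `1 - SSE/SST`) or `"pearson"`.
#' @return An object of class `pls_metrics`: `r`, `rmse`, `n`, plus the
#'   evaluation inputs `y`, `y_hat`, `y_bar`.
#' @export
pls_evaluate <- function(y, y_hat, r_method = c("printed", "pearson")) {
  r_method <- match.arg(r_method)
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  if (length(y) != length(y_hat)) stop("y and y_hat lengths differ")
  n <- length(y)
  if (n < 2) stop("need at least 2 samples")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("undefined r: constant y")
  sse <- sum((y - y_hat)^2)
  r <- if (r_method == "printed") 1 - sse / sst else cor(y, y_hat)
  structure(list(r = r, rmse = sqrt(sse / n), n = n,
                 y = y, y_hat = y_hat, y_bar = mean(y),
                 r_method = r_method),
            class = "pls_metrics")
}

#' @export
print.pls_metrics <- function(x, ...) {
  cat(sprintf("<pls_metrics> n=%d r=%.4f rmse=%.4f\n", x$n, x$r, x$rmse))
  invisible(x)
}

# Integer split sizes for an "a:b" ratio string.
split_sizes <- function(n, ratio) {
  parts <- suppressWarnings(as.integer(strsplit(ratio, ":")[[1]]))
  if (length(parts) != 2 || anyNA(parts) || any(parts <= 0))
    stop("ratio must be of the form 'a:b' with positive integers")
  n_cal <- round(n * parts[1] / sum(parts))
  n_cal <- max(2, min(n - 1, n_cal))
  c(cal = n_cal, pred = n - n_cal)
}

#' Split samples into calibration and prediction sets
#'
#' Random partition at a fixed ratio (default 3:1), deterministic under the
#' seed. Sizes round to the ratio (96 samples at 3:1 give 72/24).
#'
#' @param set a [spectrum_set()].
#' @param ref reference table aligned to `set` (columns `sample_id`,
#'   `ssc_percent`).
#' @param ratio ratio string `"cal:pred"`.
#' @param seed integer seed.
#' @return List with elements `cal` and `pred`, each holding `spectra` and
#'   `reference`, plus the index vectors `cal_idx`, `pred_idx`.
#' @export
split_calibration_prediction <- function(set, ref, ratio = "3:1", seed = 1) {
  stopifnot(inherits(set, "spectrum_set"))
  ref <- align_reference(set, ref)
  n <- nrow(set$intensities)
  if (n < 4) stop("need at least 4 samples to split")
  sizes <- split_sizes(n, ratio)
  cal_idx <- sort(with_seed(seed, sample(n, sizes[["cal"]])))
  pred_idx <- setdiff(seq_len(n), cal_idx)
  list(cal = list(spectra = subset_samples(set, cal_idx),
                  reference = ref[cal_idx, , drop = FALSE]),
       pred = list(spectra = subset_samples(set, pred_idx),
                   reference = ref[pred_idx, , drop = FALSE]),
       cal_idx = cal_idx, pred_idx = pred_idx)
}
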