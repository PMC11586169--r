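#' Monte-Carlo outlier scan
#'
#' Repeats random calibration/validation splits; in each run a PLS model is
#' fitted on the calibration part (latent variables chosen by an inner
#' cross-validated RMSECV, capped at `max_lv`) and the prediction errors of
#' the held-out samples are recorded. Samples whose error distribution over
#' the runs has an anomalous mean or standard deviation are candidate
#' outliers.
#'
#' @param X predictor matrix or [spectrum_set()].
#' @param y response vector (% SSC) or reference table.
#' @param n_runs number of random splits (>= 100).
#' @param validation_fraction fraction held out each run (0 < f < 0.5).
#' @param max_lv cap on the latent-variable count during scanning.
#' @param seed integer seed controlling all splits.
#' @param inner_cv,inner_k inner cross-validation scheme for per-run LV choice.
#' @param error_type `"absolute"` (default) aggregates `|e|`; `"signed"` keeps
#'   the sign.
#' @param k_sigma flagging threshold in robust-sd units (see [flag_outliers()]).
#' @param min_appearances minimum times each sample must be held out.
#' @return An object of class `mc_outlier_report`: per-sample statistics
#'   (`mean_error`, `std_error`, `times_in_validation`), the full per-run
#'   error log, thresholds and default `flagged_ids`.
#' @export
mc_outlier_scan <- function(X, y, n_runs = 500, validation_fraction = 0.25,
                            max_lv = 15, seed = 1,
                            inner_cv = "kfold", inner_k = 5,
                            error_type = c("absolute", "signed"),
                            k_sigma = 2.5, min_appearances = 20) {
  error_type <- match.arg(error_type)
  ids <- NULL
  if (inherits(X, "spectrum_set")) { ids <- X$sample_ids; X <- X$intensities }
  if (is.data.frame(y)) y <- y$ssc_percent
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(ids)) ids <- rownames(X) %||% sprintf("S%03d", seq_len(n))
  if (n_runs < 100) stop_field("n_runs", "must be >= 100")
  if (validation_fraction <= 0 || validation_fraction >= 0.5)
    stop_field("validation_fraction", "must be in (0, 0.5)")
  if (n < 10) stop("need at least 10 samples")
  n_val <- max(1, floor(validation_fraction * n))
  n_cal <- n - n_val
  cap <- if (inner_cv == "loo") min(max_lv, n_cal - 2, ncol(X))
         else min(max_lv, n_cal - ceiling(n_cal / inner_k) - 1, ncol(X))
  if (cap < 1) stop("too few samples for the inner cross-validation")
  log_run <- integer(0); log_sample <- integer(0); log_error <- numeric(0)
  with_seed(seed, {
    for (run in seq_len(n_runs)) {
      val <- sample(n, n_val)
      cal <- setdiff(seq_len(n), val)
      cv <- pls_rmsecv(X[cal, , drop = FALSE], y[cal], max_lv = cap,
                       cv = inner_cv, k = inner_k,
                       seed = NULL, folds = cv_folds(length(cal), inner_cv, inner_k))
      fit <- pls_fit(X[cal, , drop = FALSE], y[cal], n_lv = cv$chosen_lv)
      e <- predict(fit, X[val, , drop = FALSE]) - y[val]
      if (error_type == "absolute") e <- abs(e)
      log_run <- c(log_run, rep(run, n_val))
      log_sample <- c(log_sample, val)
      log_error <- c(log_error, e)
    }
  })
  times <- tabulate(log_sample, nbins = n)
  if (any(times == 0))
    stop(sprintf("sample(s) never held out (%s): increase n_runs",
                 paste(ids[times == 0], collapse = ", ")))
  if (any(times < min_appearances))
    stop(sprintf("sample(s) held out fewer than %d times: increase n_runs",
                 min_appearances))
  mean_e <- vapply(seq_len(n), function(i) mean(log_error[log_sample == i]),
                   numeric(1))
  std_e <- vapply(seq_len(n), function(i) sd(log_error[log_sample == i]),
                  numeric(1))
  report <- structure(
    list(stats = data.frame(sample_id = ids, mean_error = mean_e,
                            std_error = std_e, times_in_validation = times,
                            stringsAsFactors = FALSE),
         error_log = data.frame(run = log_run, sample = log_sample,
                                error = log_error),
         params = list(n_runs = n_runs,
                       validation_fraction = validation_fraction,
                       max_lv = cap, seed = seed, error_type = error_type,
                       k_sigma = k_sigma)),
    class = "mc_outlier_report")
  report$flagged_ids <- flag_outliers(report, k_sigma)
  report
}

#' Flag anomalous samples from a Monte-Carlo outlier report
#'
#' A sample is flagged when its mean error exceeds
#' `mean(mean_errors) + k_sigma * sd(mean_errors)` or its error standard
#' deviation exceeds the analogous bound on the std errors.
#'
#' @param report an `mc_outlier_report`.
#' @param k_sigma threshold multiplier (default 2.5).
#' @return Character vector of flagged sample ids (possibly empty); the
#'   thresholds used are attached as attribute `thresholds`.
#' @export
flag_outliers <- function(report, k_sigma = 2.5) {
  stopifnot(inherits(report, "mc_outlier_report"))
  s <- report$stats
  if (nrow(s) == 0) stop("empty report")
  thr_mean <- mean(s$mean_error) + k_sigma * sd(s$mean_error)
  thr_std <- mean(s$std_error) + k_sigma * sd(s$std_error)
  # numerical floor: an exactly-fitting model leaves machine-noise errors that
  # must not be flagged however they spread
  floor_ <- 1e-8
  flagged <- s$sample_id[(s$mean_error > pmax(thr_mean, floor_)) |
                         (s$std_error > pmax(thr_std, floor_))]
  attr(flagged, "thresholds") <- c(mean_error = thr_mean, std_error = thr_std)
  flagged
}

#' @export
print.mc_outlier_report <- function(x, ...) {
  cat(sprintf("<mc_outlier_report> %d samples, %d runs; %d flagged\n",
              nrow(x$stats), x$params$n_runs, length(x$flagged_ids)))
  if (length(x$flagged_ids))
    cat("flagged:", paste(x$flagged_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a Monte-Carlo outlier report (mean vs STD of prediction error)
#'
#' @param x an `mc_outlier_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mc_outlier_report <- function(x, ...) {
  s <- x$stats
  flagged <- s$sample_id %in% x$flagged_ids
  graphics::plot(s$mean_error, s$std_error,
                 col = ifelse(flagged, "red", "black"),
                 pch = ifelse(flagged, 17, 1),
                 xlab = "mean prediction error (% SSC)",
                 ylab = "STD of prediction error (% SSC)", ...)
  if (any(flagged))
    graphics::text(s$mean_error[flagged], s$std_error[flagged],
                   s$sample_id[flagged], pos = 2, cex = 0.8, col = "red")
  invisible(x)
}

#' Remove flagged samples from a spectrum set and its reference table
#'
#' @param set a [spectrum_set()].
#' @param ref reference table.
#' @param ids sample ids to drop; unknown ids raise an error.
#' @return List with the reduced `spectra` and `reference`.
#' @export
remove_samples <- function(set, ref, ids) {
  stopifnot(inherits(set, "spectrum_set"))
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, set$sample_ids)
  if (length(unknown))
    stop(sprintf("unknown sample id(s): %s", paste(unknown, collapse = ", ")))
  keep <- setdiff(set$sample_ids, ids)
  list(spectra = subset_samples(set, keep),
       reference = ref[ref$sample_id %in% keep, , drop = FALSE])
}
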