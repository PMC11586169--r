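#' Preprocessing configuration
#'
#' @param method one of `"raw"`, `"msc"`, `"snv"`, `"gf"`, `"gf+msc"`.
#' @param gf_window odd Gaussian-filter window length (>= 3), in grid points.
#' @param gf_sigma Gaussian kernel sd in grid-index units; default `window/5`.
#' @param msc_reference `"mean"` (mean spectrum of the set the correction is
#'   fitted on) or an explicit numeric reference spectrum.
#' @param truncate_factor edge-frame rejection threshold: frames whose total
#'   intensity exceeds `truncate_factor` times the median frame total are
#'   dropped from the ends of each scan; must be > 1.
#' @param snv_denom `"n-1"` (sample sd, default) or `"n"` for the SNV scale.
#' @return A validated list of class `preprocess_config`.
#' @export
preprocess_config <- function(method = c("raw", "msc", "snv", "gf", "gf+msc"),
                              gf_window = 11, gf_sigma = gf_window / 5,
                              msc_reference = "mean",
                              truncate_factor = 1.5,
                              snv_denom = c("n-1", "n")) {
  method <- match.arg(method)
  snv_denom <- match.arg(snv_denom)
  if (gf_window < 3 || gf_window %% 2 == 0)
    stop_field("gf_window", "must be odd and >= 3")
  if (gf_sigma <= 0) stop_field("gf_sigma", "must be > 0")
  if (truncate_factor <= 1) stop_field("truncate_factor", "must be > 1")
  structure(list(method = method, gf_window = gf_window, gf_sigma = gf_sigma,
                 msc_reference = msc_reference,
                 truncate_factor = truncate_factor, snv_denom = snv_denom),
            class = "preprocess_config")
}

#' Drop inflated edge frames from multi-frame scans
#'
#' When the fruit is entering or leaving the beam the light crosses only
#' pericarp, so those frames are much brighter than frames through the pulp
#' and cavity. Frames whose total intensity exceeds
#' `truncate_factor * median(frame totals)` are stripped from the leading and
#' trailing ends of each scan; the retained block is contiguous and never
#' empty.
#'
#' @param x a frames-by-wavelengths matrix (one sample) or a `frame_stack`
#'   from [simulate_multiframe()].
#' @param truncate_factor threshold multiplier (> 1).
#' @return Same type as `x` with edge frames removed.
#' @export
truncate_edge_frames <- function(x, truncate_factor = 1.5) {
  if (truncate_factor <= 1) stop_field("truncate_factor", "must be > 1")
  if (inherits(x, "frame_stack")) {
    x$frames <- lapply(x$frames, truncate_edge_frames, truncate_factor)
    return(x)
  }
  fm <- as.matrix(x)
  if (nrow(fm) == 0) stop("no frames supplied")
  totals <- rowSums(fm)
  thr <- truncate_factor * median(totals)
  ok <- which(totals <= thr)
  if (length(ok) == 0) stop("no informative frames: all frame totals exceed threshold")
  fm[min(ok):max(ok), , drop = FALSE]
}

#' Average retained frames into one spectrum per sample
#'
#' @param x a frames-by-wavelengths matrix or a `frame_stack`.
#' @return For a matrix, the pointwise mean spectrum; for a `frame_stack`, a
#'   [spectrum_set()] with one averaged spectrum per sample.
#' @export
average_frames <- function(x) {
  if (inherits(x, "frame_stack")) {
    X <- t(vapply(x$frames, function(fm) average_frames(fm),
                  numeric(length(x$wavelengths))))
    return(spectrum_set(x$wavelengths, X, x$sample_ids,
                        meta = list(history = "frame_average")))
  }
  fm <- as.matrix(x)
  if (nrow(fm) == 0) stop("no frames to average")
  colMeans(fm)
}

#' Normalized Gaussian smoothing kernel
#'
#' @param window odd window length >= 3.
#' @param sigma kernel sd in index units.
#' @return Weights summing exactly to 1.
#' @export
gaussian_kernel <- function(window, sigma = window / 5) {
  if (window %% 2 == 0 || window < 3) stop_field("gf_window", "must be odd and >= 3")
  if (sigma <= 0) stop_field("gf_sigma", "must be > 0")
  d <- seq_len(window) - (window + 1) / 2
  w <- exp(-d^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian filter a spectrum or spectrum set
#'
#' Convolution with a normalized Gaussian kernel; edges are handled by
#' reflection padding, so a constant spectrum passes through unchanged.
#'
#' @param x numeric vector or [spectrum_set()].
#' @param window odd window length (grid points).
#' @param sigma kernel sd in index units.
#' @return Same type as `x`, smoothed.
#' @export
gaussian_filter <- function(x, window = 11, sigma = window / 5) {
  if (inherits(x, "spectrum_set")) {
    x$intensities <- t(apply(x$intensities, 1, gaussian_filter,
                             window = window, sigma = sigma))
    rownames(x$intensities) <- x$sample_ids
    return(add_history(x, sprintf("gf(window=%d,sigma=%g)", window, sigma)))
  }
  v <- as.numeric(x)
  if (window > length(v)) stop("gf_window exceeds spectrum length")
  w <- gaussian_kernel(window, sigma)
  p <- (window - 1) / 2
  padded <- c(v[(p + 1):2], v, v[(length(v) - 1):(length(v) - p)])
  out <- stats::filter(padded, w, sides = 2)
  as.numeric(out[(p + 1):(p + length(v))])
}

#' Standard normal variate transform
#'
#' Centers each spectrum to mean 0 and scales to unit standard deviation,
#' removing additive offsets and multiplicative path-length/scatter effects.
#'
#' @param x numeric vector or [spectrum_set()].
#' @param denom `"n-1"` (sample sd) or `"n"`.
#' @return Same type as `x`, transformed.
#' @export
snv <- function(x, denom = c("n-1", "n")) {
  denom <- match.arg(denom)
  if (inherits(x, "spectrum_set")) {
    x$intensities <- t(apply(x$intensities, 1, snv, denom = denom))
    rownames(x$intensities) <- x$sample_ids
    return(add_history(x, sprintf("snv(denom=%s)", denom)))
  }
  v <- as.numeric(x)
  if (length(v) < 2) stop("SNV needs at least 2 points")
  s <- sd(v)
  if (denom == "n") s <- s * sqrt((length(v) - 1) / length(v))
  if (!is.finite(s) || s == 0) stop("constant spectrum: SNV undefined")
  (v - mean(v)) / s
}

#' Multiplicative scatter correction
#'
#' Each spectrum `s` is regressed on a reference spectrum `r` by least squares
#' (`s ~ a*r + b`) and corrected as `(s - b)/a`, removing per-sample additive
#' and multiplicative scatter.
#'
#' @param set a [spectrum_set()].
#' @param reference `"mean"` for the mean spectrum of `set`, or an explicit
#'   numeric spectrum on the same grid (e.g. the calibration-set mean, reused
#'   for prediction samples).
#' @return The corrected `spectrum_set`; the reference actually used is stored
#'   in `meta$msc_reference`.
#' @export
msc <- function(set, reference = "mean") {
  stopifnot(inherits(set, "spectrum_set"))
  r <- if (identical(reference, "mean")) colMeans(set$intensities)
       else as.numeric(reference)
  if (length(r) != length(set$wavelengths))
    stop("MSC reference length does not match wavelength grid")
  if (identical(reference, "mean") && nrow(set$intensities) < 2)
    stop("MSC with mean reference needs at least 2 spectra")
  vr <- var(r)
  if (vr == 0) stop("MSC reference spectrum is constant")
  rc <- r - mean(r)
  X <- set$intensities
  # least-squares slope of s on r: sum((s - mean(s)) * (r - mean(r))) / sum((r - mean(r))^2)
  a <- as.numeric((X - rowMeans(X)) %*% rc) / sum(rc^2)
  bad <- which(abs(a) < 1e-12)
  if (length(bad))
    stop(sprintf("MSC slope is zero for sample(s): %s",
                 paste(set$sample_ids[bad], collapse = ", ")))
  b <- rowMeans(X) - a * mean(r)
  set$intensities <- (X - b) / a
  rownames(set$intensities) <- set$sample_ids
  set$meta$msc_reference <- r
  add_history(set, "msc")
}

#' Apply a configured preprocessing method to a spectrum set
#'
#' Dispatches on `config$method`; `"gf+msc"` applies the Gaussian filter first
#' and MSC second. The preprocessing history is appended in `meta$history`.
#'
#' @param set a [spectrum_set()].
#' @param config a [preprocess_config()].
#' @param msc_reference_spectrum optional explicit MSC reference (overrides
#'   `config$msc_reference`; used to apply a calibration-set reference to
#'   prediction samples without leakage).
#' @return The transformed `spectrum_set`.
#' @export
preprocess <- function(set, config, msc_reference_spectrum = NULL) {
  stopifnot(inherits(set, "spectrum_set"), inherits(config, "preprocess_config"))
  ref <- msc_reference_spectrum %||% config$msc_reference
  switch(config$method,
    raw = add_history(set, "raw"),
    gf = gaussian_filter(set, config$gf_window, config$gf_sigma),
    snv = snv(set, config$snv_denom),
    msc = msc(set, ref),
    `gf+msc` = msc(gaussian_filter(set, config$gf_window, config$gf_sigma), ref),
    stop(sprintf("unknown preprocessing method '%s'", config$method))
  )
}
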