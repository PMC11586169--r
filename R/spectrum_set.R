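#' Spectrum set container
#'
#' The object every stage of the workflow transforms: a wavelength grid in nm,
#' a samples-by-wavelengths intensity matrix, unique sample identifiers and a
#' free-form metadata list carrying provenance (orientation tag, append-only
#' preprocessing history).
#'
#' @param wavelengths strictly increasing numeric vector of wavelengths (nm).
#' @param intensities numeric matrix, one row per sample, one column per
#'   wavelength; all values finite.
#' @param sample_ids character vector of unique sample identifiers; defaults to
#'   `S001, S002, ...`.
#' @param meta list of provenance fields; `meta$history` is an append-only
#'   character vector of processing steps.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavelengths, intensities, sample_ids = NULL,
                         meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.matrix(intensities)
  if (length(wavelengths) < 2) stop("need at least 2 wavelengths")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (ncol(intensities) != length(wavelengths))
    stop(sprintf("intensity matrix has %d columns but %d wavelengths",
                 ncol(intensities), length(wavelengths)))
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  if (is.null(sample_ids))
    sample_ids <- sprintf("S%03d", seq_len(nrow(intensities)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(intensities))
    stop("one sample id per spectrum required")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (is.null(meta$history)) meta$history <- character()
  rownames(intensities) <- sample_ids
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 sample_ids = sample_ids, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d samples x %d wavelengths (%.2f-%.2f nm)\n",
              nrow(x$intensities), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (length(x$meta$history))
    cat("history:", paste(x$meta$history, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$intensities)

add_history <- function(set, step) {
  set$meta$history <- c(set$meta$history, step)
  set
}

# Subset samples by position or id, keeping both matrix and ids consistent.
subset_samples <- function(set, idx) {
  if (is.character(idx)) {
    pos <- match(idx, set$sample_ids)
    if (anyNA(pos)) stop(sprintf("unknown sample id(s): %s",
                                 paste(idx[is.na(pos)], collapse = ", ")))
    idx <- pos
  }
  set$intensities <- set$intensities[idx, , drop = FALSE]
  set$sample_ids <- set$sample_ids[idx]
  rownames(set$intensities) <- set$sample_ids
  set
}

#' Read and write spectrum sets as CSV
#'
#' CSV dialect: header row holds `sample_id` followed by the wavelengths in nm;
#' each following row holds a sample id and its intensities.
#'
#' @param set a [spectrum_set()].
#' @param path file path.
#' @return `write_spectra()` returns `path` invisibly; `read_spectra()` returns
#'   a `spectrum_set`.
#' @export
write_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  df <- data.frame(sample_id = set$sample_ids, set$intensities,
                   check.names = FALSE)
  colnames(df) <- c("sample_id", format(set$wavelengths, trim = TRUE, digits = 10))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  wl <- as.numeric(colnames(df)[-1])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  spectrum_set(wl, m, sample_ids = df[[1]])
}

#' Read and write SSC reference tables
#'
#' A reference table is a data frame with columns `sample_id` and
#' `ssc_percent` (% soluble solids), the regression target.
#'
#' @param ref data frame with columns `sample_id`, `ssc_percent`.
#' @param path file path.
#' @export
write_reference <- function(ref, path) {
  stopifnot(all(c("sample_id", "ssc_percent") %in% names(ref)))
  write.csv(ref[, c("sample_id", "ssc_percent")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  df <- read.csv(path)
  if (!all(c("sample_id", "ssc_percent") %in% names(df)))
    stop("reference CSV needs columns sample_id, ssc_percent")
  df$sample_id <- as.character(df$sample_id)
  df
}

# Align a reference table to a spectrum set's sample order; errors on mismatch.
align_reference <- function(set, ref) {
  pos <- match(set$sample_ids, ref$sample_id)
  if (anyNA(pos)) stop("reference table is missing sample(s): ",
                       paste(set$sample_ids[is.na(pos)], collapse = ", "))
  ref[pos, , drop = FALSE]
}
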