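#' Configuration for the synthetic Vis-NIR transmission generator
#'
#' Defines a synthetic calibration problem mimicking full-transmission
#' acquisition of fruit on a conveyor: a smooth lamp-like source envelope,
#' Beer-Lambert absorption by a small number of Gaussian constituent bands,
#' large sample-to-sample multiplicative/additive scatter, detector noise, an
#' orientation-dependent path-length factor, and (optionally) several frames
#' per sample with inflated-intensity edge frames where light crosses only the
#' pericarp.
#'
#' The soluble solids content of sample *i* is an affine function of the first
#' band's concentration, `ssc = ssc_intercept + ssc_slope * c1`, and the
#' reported reference value adds refractometer noise of sd `ref_noise_sd`.
#'
#' Default band structure follows fruit NIR physics: the SSC (sugar) band is a
#' weak shoulder (amplitude 0.08 AU per unit concentration at 840 nm) on
#' dominant water bands (0.40 and 0.60 AU at 910 and 960 nm) whose
#' concentrations vary independently of SSC. Together with per-sample
#' path-length variability this reproduces the error magnitudes typical of
#' whole-fruit transmission calibrations (prediction RMSE several times the
#' reference-measurement floor) rather than an idealized low-noise problem.
#'
#' @param n_samples number of fruit samples.
#' @param n_wavelengths number of points on the wavelength grid (>= 2).
#' @param wl_min,wl_max wavelength range in nm.
#' @param band_centers,band_widths,band_amplitudes centers (nm), Gaussian sd
#'   (nm) and absorbance amplitude per unit concentration for each informative
#'   band; all three must share one length.
#' @param ssc_mean,ssc_sd population mean and sd of true SSC (% soluble solids).
#' @param ssc_intercept,ssc_slope affine map from the first band concentration
#'   to true SSC (% per concentration unit).
#' @param ref_noise_sd sd of reference-measurement noise (%; refractometer
#'   precision).
#' @param scatter_mult_sd,scatter_add_sd sd of per-sample multiplicative
#'   (around 1) and additive (intensity counts) scatter.
#' @param path_sd sd of the per-sample relative optical path length (around
#'   1): fruit-size variation scales the whole absorbance profile
#'   (Beer-Lambert), a nonlinear effect scatter correction cannot remove and
#'   the main reason calibration error on real fruit far exceeds the
#'   reference-measurement floor.
#' @param interferent_sd relative concentration sd of the non-SSC bands
#'   (water and other matrix constituents vary strongly between fruit, so the
#'   overall band depth is dominated by composition unrelated to SSC).
#' @param noise_sd sd of additive detector noise (intensity counts).
#' @param path_factor global path-length/orientation factor scaling transmitted
#'   intensity (1 = short-path orientation; < 1 emulates a longer optical path).
#' @param frames_per_sample frames acquired per sample as it crosses the beam.
#' @param edge_frame_factor intensity inflation of the first and last frame
#'   (pericarp-only transmission); must be > 1.
#' @param i0_peak,i0_center,i0_width source envelope: peak counts, center (nm)
#'   and Gaussian width (nm) of the halogen-lamp-like spectrum.
#' @param seed integer seed; identical config + seed reproduces output
#'   bit-for-bit.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 96,
                       n_wavelengths = 2048,
                       wl_min = 560, wl_max = 1072,
                       band_centers = c(840, 910, 960),
                       band_widths = c(15, 15, 15),
                       band_amplitudes = c(0.08, 0.40, 0.60),
                       ssc_mean = 5, ssc_sd = 0.8,
                       ssc_intercept = 2, ssc_slope = 3,
                       ref_noise_sd = 0.1,
                       scatter_mult_sd = 0.15,
                       scatter_add_sd = 300,
                       path_sd = 0.10,
                       interferent_sd = 0.5,
                       noise_sd = 150,
                       path_factor = 1,
                       frames_per_sample = 1,
                       edge_frame_factor = 2.5,
                       i0_peak = 60000, i0_center = 800, i0_width = 200,
                       seed = 1) {
  cfg <- list(n_samples = n_samples, n_wavelengths = n_wavelengths,
              wl_min = wl_min, wl_max = wl_max,
              n_informative_bands = length(band_centers),
              band_centers = band_centers, band_widths = band_widths,
              band_amplitudes = band_amplitudes,
              ssc_mean = ssc_mean, ssc_sd = ssc_sd,
              ssc_intercept = ssc_intercept, ssc_slope = ssc_slope,
              ref_noise_sd = ref_noise_sd,
              scatter_mult_sd = scatter_mult_sd,
              scatter_add_sd = scatter_add_sd, noise_sd = noise_sd,
              path_sd = path_sd, interferent_sd = interferent_sd,
              path_factor = path_factor,
              frames_per_sample = frames_per_sample,
              edge_frame_factor = edge_frame_factor,
              i0_peak = i0_peak, i0_center = i0_center, i0_width = i0_width,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 2) stop_field("n_samples", "need at least 2 samples")
  if (cfg$n_wavelengths < 2) stop_field("n_wavelengths", "must be >= 2")
  if (!(cfg$wl_min < cfg$wl_max)) stop_field("wl_min", "wl_min must be < wl_max")
  if (length(cfg$band_widths) != cfg$n_informative_bands)
    stop_field("band_widths", "length must match band_centers")
  if (length(cfg$band_amplitudes) != cfg$n_informative_bands)
    stop_field("band_amplitudes", "length must match band_centers")
  if (any(cfg$band_centers < cfg$wl_min | cfg$band_centers > cfg$wl_max))
    stop_field("band_centers", "must lie within [wl_min, wl_max]")
  if (any(cfg$band_widths <= 0)) stop_field("band_widths", "must be > 0")
  for (f in c("ssc_sd", "ref_noise_sd", "scatter_mult_sd", "scatter_add_sd",
              "noise_sd", "path_sd", "interferent_sd"))
    if (cfg[[f]] < 0) stop_field(f, "must be >= 0")
  if (cfg$ssc_mean <= 0) stop_field("ssc_mean", "must be > 0")
  if (cfg$ssc_slope <= 0) stop_field("ssc_slope", "must be > 0")
  if (cfg$path_factor <= 0) stop_field("path_factor", "must be > 0")
  if (cfg$frames_per_sample < 1) stop_field("frames_per_sample", "must be >= 1")
  if (cfg$edge_frame_factor <= 1) stop_field("edge_frame_factor", "must be > 1")
  if (cfg$i0_peak <= 0) stop_field("i0_peak", "must be > 0")
  invisible(cfg)
}

#' Source envelope and band absorptivity profiles of a simulated instrument
#'
#' @param config a [sim_config()].
#' @return `lamp_envelope()`: the smooth source spectrum I0 at each grid point.
#'   `band_profiles()`: a bands-by-wavelengths matrix of Gaussian absorptivity
#'   profiles (amplitude already applied).
#' @export
lamp_envelope <- function(config) {
  wl <- sim_wavelengths(config)
  config$i0_peak * exp(-(wl - config$i0_center)^2 / (2 * config$i0_width^2))
}

#' @rdname lamp_envelope
#' @export
band_profiles <- function(config) {
  wl <- sim_wavelengths(config)
  G <- vapply(seq_len(config$n_informative_bands), function(j) {
    config$band_amplitudes[j] *
      exp(-(wl - config$band_centers[j])^2 / (2 * config$band_widths[j]^2))
  }, numeric(length(wl)))
  t(G)
}

sim_wavelengths <- function(config) {
  seq(config$wl_min, config$wl_max, length.out = config$n_wavelengths)
}

# Truncated-normal draws (> lower) by per-element redraw; deterministic for a
# fixed RNG state.
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# Sample-level draws shared by single- and multi-frame generation. RNG order
# is fixed so both entry points see identical sample-level quantities.
sim_sample_level <- function(config) {
  n <- config$n_samples
  ssc_true <- rnorm_trunc(n, config$ssc_mean, config$ssc_sd,
                          lower = config$ssc_intercept + 1e-6)
  conc <- matrix(0, n, config$n_informative_bands)
  conc[, 1] <- (ssc_true - config$ssc_intercept) / config$ssc_slope
  if (config$n_informative_bands > 1)
    for (j in 2:config$n_informative_bands)
      conc[, j] <- rnorm_trunc(n, 1, config$interferent_sd, lower = 0)
  mult <- rnorm_trunc(n, 1, config$scatter_mult_sd, lower = 0.2)
  add <- rnorm(n, 0, config$scatter_add_sd)
  path_len <- rnorm_trunc(n, 1, config$path_sd, lower = 0.2)
  ref_noise <- rnorm(n, 0, config$ref_noise_sd)
  list(ssc_true = ssc_true, conc = conc, mult = mult, add = add,
       path_len = path_len, ref_noise = ref_noise)
}

# Noise-free transmitted signal (before scatter/noise): I0 * 10^(-l_i * A_i),
# with l_i the per-sample relative path length.
sim_clean_transmission <- function(config, draws) {
  i0 <- lamp_envelope(config)
  A <- draws$conc %*% band_profiles(config)   # samples x wavelengths absorbance
  sweep(10^(-A * draws$path_len), 2, i0, `*`)
}

sim_truth <- function(config, draws) {
  wl <- sim_wavelengths(config)
  ranges <- lapply(seq_len(config$n_informative_bands), function(j) {
    idx <- which(abs(wl - config$band_centers[j]) <= 2.5 * config$band_widths[j])
    c(start = min(idx), end = max(idx))
  })
  list(informative_ranges = ranges,
       informative_indices = sort(unique(unlist(lapply(ranges, function(r)
         seq(r[["start"]], r[["end"]]))))),
       true_coefficients = config$band_amplitudes,
       ssc_relation = list(intercept = config$ssc_intercept,
                           slope = config$ssc_slope, band = 1L),
       per_sample_ssc = draws$ssc_true,
       concentrations = draws$conc,
       seed = config$seed,
       config = unclass(config))
}

#' Generate a synthetic transmission calibration problem
#'
#' Produces a spectrum set, an SSC reference table and the generating ground
#' truth. The measured intensity is
#' `path_factor * mult_i * I0(wl) * 10^(-A_i(wl)) + add_i + noise`, with
#' per-sample absorbance `A_i = sum_j c_ij * g_j(wl)` over Gaussian bands, and
#' the reference SSC is the affine function of the first band concentration
#' plus reference noise.
#'
#' @param config a [sim_config()].
#' @return A list with elements `spectra` ([spectrum_set()]), `reference`
#'   (data frame `sample_id`, `ssc_percent`) and `truth` (informative index
#'   ranges, band coefficients, noise-free SSC, concentrations, config echo).
#' @export
simulate_spectra <- function(config) {
  validate_sim_config(config)
  n <- config$n_samples; m <- config$n_wavelengths
  out <- with_seed(config$seed, {
    draws <- sim_sample_level(config)
    clean <- sim_clean_transmission(config, draws)
    X <- matrix(0, n, m)
    for (i in seq_len(n)) {
      X[i, ] <- config$path_factor * draws$mult[i] * clean[i, ] +
        draws$add[i] + rnorm(m, 0, config$noise_sd)
    }
    list(draws = draws, X = X)
  })
  ids <- sprintf("S%03d", seq_len(n))
  set <- spectrum_set(sim_wavelengths(config), out$X, ids,
                      meta = list(source = "simulate_spectra",
                                  path_factor = config$path_factor))
  ref <- data.frame(sample_id = ids,
                    ssc_percent = out$draws$ssc_true + out$draws$ref_noise)
  list(spectra = set, reference = ref, truth = sim_truth(config, out$draws))
}

#' Generate multi-frame scans with inflated edge frames
#'
#' Emulates multi-point acquisition as the fruit crosses the beam: each sample
#' yields `frames_per_sample` spectra sharing the sample's scatter and
#' composition; the first and last frame are inflated by `edge_frame_factor`
#' (light passing mainly through pericarp), so edge truncation is exercisable.
#' With `frames_per_sample = 1` the output equals [simulate_spectra()].
#'
#' @param config a [sim_config()].
#' @return A list of class `frame_stack`: `wavelengths`, `frames` (per-sample
#'   list of frames-by-wavelengths matrices), `sample_ids`, `reference`,
#'   `truth`.
#' @export
simulate_multiframe <- function(config) {
  validate_sim_config(config)
  n <- config$n_samples; m <- config$n_wavelengths
  Fn <- config$frames_per_sample
  out <- with_seed(config$seed, {
    draws <- sim_sample_level(config)
    clean <- sim_clean_transmission(config, draws)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      fm <- matrix(0, Fn, m)
      for (f in seq_len(Fn)) {
        edge <- if (Fn > 1 && (f == 1 || f == Fn)) config$edge_frame_factor else 1
        fm[f, ] <- edge * config$path_factor * draws$mult[i] * clean[i, ] +
          draws$add[i] + rnorm(m, 0, config$noise_sd)
      }
      frames[[i]] <- fm
    }
    list(draws = draws, frames = frames)
  })
  ids <- sprintf("S%03d", seq_len(n))
  structure(list(wavelengths = sim_wavelengths(config), frames = out$frames,
                 sample_ids = ids,
                 reference = data.frame(sample_id = ids,
                                        ssc_percent = out$draws$ssc_true +
                                          out$draws$ref_noise),
                 truth = sim_truth(config, out$draws)),
            class = "frame_stack")
}

#' Convert transmission intensities to apparent absorbance
#'
#' Computes `-log10(I / I0)` against a source envelope; values are floored at
#' a small positive transmittance to keep the log finite under additive noise.
#'
#' @param set a [spectrum_set()] of transmission intensities.
#' @param i0 source envelope (defaults to the simulated lamp envelope only if
#'   supplied); a numeric vector matching the wavelength grid.
#' @return A `spectrum_set` of absorbance values.
#' @export
to_absorbance <- function(set, i0) {
  stopifnot(inherits(set, "spectrum_set"), length(i0) == length(set$wavelengths))
  tr <- sweep(set$intensities, 2, i0, `/`)
  tr[tr < 1e-12] <- 1e-12
  set$intensities <- -log10(tr)
  add_history(set, "absorbance")
}

#' Write a ground-truth record as JSON
#'
#' @param truth the `truth` element returned by [simulate_spectra()].
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
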