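#' Pipeline configuration
#'
#' Assembles the end-to-end workflow configuration: exactly one data source
#' (simulation block or CSV input paths), the preprocessing method, the
#' calibration/prediction split, Monte-Carlo outlier removal, wavelength
#' selection, and the final PLSR settings. Every random stage consumes an
#' independent seed derived from `master_seed`.
#'
#' @param simulate a [sim_config()], or `NULL` when reading from files.
#' @param spectra_csv,reference_csv input paths (used when `simulate` is
#'   `NULL`).
#' @param preprocess a [preprocess_config()].
#' @param split_ratio calibration:prediction ratio string.
#' @param outlier list: `enabled`, `n_runs`, `validation_fraction`, `max_lv`,
#'   `k_sigma`, `mode` (`"pre_split"`: scan the pooled sample set before
#'   splitting, the mode matching removal from the full sample table;
#'   `"post_split"`: scan and remove within the calibration set only).
#' @param selection list: `enabled`, `bin_width`, `subset_size`, `cv`,
#'   `k_folds`, `max_lv`, plus the annealing parameters `sa_L`,
#'   `sa_cooling`, `sa_decrement_fraction`, `sa_alpha`.
#' @param plsr list: `max_lv`, `cv` (`"loo"`/`"kfold"`), `k_folds`.
#' @param master_seed integer master seed.
#' @param make_plots write PNG diagnostics.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL,
                            spectra_csv = NULL, reference_csv = NULL,
                            preprocess = preprocess_config("gf+msc"),
                            split_ratio = "3:1",
                            outlier = list(),
                            selection = list(),
                            plsr = list(),
                            master_seed = 1,
                            make_plots = TRUE) {
  if (is.null(simulate) == (is.null(spectra_csv) || is.null(reference_csv)))
    stop("provide exactly one data source: a simulate block or both CSV paths")
  outlier <- utils::modifyList(
    list(enabled = TRUE, n_runs = 500, validation_fraction = 0.25,
         max_lv = 15, k_sigma = 2.5, mode = "pre_split",
         inner_cv = "kfold", inner_k = 5, min_appearances = 20), outlier)
  selection <- utils::modifyList(
    list(enabled = TRUE, bin_width = 16, subset_size = 20,
         cv = "kfold", k_folds = 5, max_lv = 20,
         sa_L = 500, sa_cooling = "adaptive_decrement",
         sa_decrement_fraction = 0.005, sa_alpha = 0.95), selection)
  plsr <- utils::modifyList(list(max_lv = 20, cv = "loo", k_folds = 5), plsr)
  if (!outlier$mode %in% c("pre_split", "post_split"))
    stop_field("outlier$mode", "must be 'pre_split' or 'post_split'")
  structure(list(simulate = simulate, spectra_csv = spectra_csv,
                 reference_csv = reference_csv, preprocess = preprocess,
                 split_ratio = split_ratio, outlier = outlier,
                 selection = selection, plsr = plsr,
                 master_seed = master_seed, make_plots = make_plots),
            class = "pipeline_config")
}

# Fit + evaluate one model on a calibration/prediction pair; returns the
# one-row metrics table (LVs | Rc | RMSEC | Rp | RMSEP) and the model.
fit_and_report <- function(label, Xc, yc, Xp, yp, max_lv, cv, k_folds, seed) {
  cap <- if (cv == "loo") min(max_lv, nrow(Xc) - 2, ncol(Xc))
         else min(max_lv, nrow(Xc) - ceiling(nrow(Xc) / k_folds) - 1, ncol(Xc))
  cvres <- pls_rmsecv(Xc, yc, max_lv = cap, cv = cv, k = k_folds, seed = seed)
  model <- pls_fit(Xc, yc, n_lv = cvres$chosen_lv)
  mc <- pls_evaluate(yc, predict(model, Xc))
  mp <- pls_evaluate(yp, predict(model, Xp))
  list(row = data.frame(model = label, LVs = cvres$chosen_lv,
                        Rc = mc$r, RMSEC = mc$rmse,
                        Rp = mp$r, RMSEP = mp$rmse),
       model = model, cv = cvres,
       cal_metrics = mc, pred_metrics = mp)
}

#' Run the end-to-end calibration workflow
#'
#' Stage order: acquire (simulate or read; multi-frame scans are edge-truncated
#' and averaged) -> optional pooled outlier removal -> calibration/prediction
#' split -> preprocessing (MSC reference fitted on calibration samples only
#' and reused for prediction samples) -> optional calibration-set outlier
#' removal -> full-spectrum PLSR -> binning + BVS-PLS + simulated annealing ->
#' selected-variable PLSR -> report. All intermediates are written under
#' `out_dir`; the run is deterministic for a fixed config and master seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` writes nothing.
#' @return A list of class `run_report`: `metrics` (table with columns
#'   model | LVs | Rc | RMSEC | Rp | RMSEP), `selection`, `outliers_removed`,
#'   `split`, `config_echo`, `seeds`, `version`, `timestamp`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- list(split = derive_seed(config$master_seed, "split"),
                outlier = derive_seed(config$master_seed, "outlier"),
                selection = derive_seed(config$master_seed, "selection"),
                plsr = derive_seed(config$master_seed, "plsr"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # --- acquire -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    if (sim$frames_per_sample > 1) {
      stack <- simulate_multiframe(sim)
      stack <- truncate_edge_frames(stack, config$preprocess$truncate_factor)
      set <- average_frames(stack)
      ref <- stack$reference; truth <- stack$truth
    } else {
      g <- simulate_spectra(sim)
      set <- g$spectra; ref <- g$reference; truth <- g$truth
    }
  } else {
    set <- read_spectra(config$spectra_csv)
    ref <- align_reference(set, read_reference(config$reference_csv))
    truth <- NULL
  }
  if (!is.null(out_dir)) {
    write_spectra(set, file.path(out_dir, "spectra_raw.csv"))
    write_reference(ref, file.path(out_dir, "reference.csv"))
    if (!is.null(truth))
      write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
  }

  # --- pooled outlier removal (pre-split mode) -----------------------------
  outliers_removed <- character(0)
  out_report <- NULL
  ob <- config$outlier
  if (isTRUE(ob$enabled) && ob$mode == "pre_split") {
    pooled <- preprocess(set, config$preprocess)
    out_report <- mc_outlier_scan(pooled, ref, n_runs = ob$n_runs,
                                  validation_fraction = ob$validation_fraction,
                                  max_lv = ob$max_lv, seed = seeds$outlier,
                                  inner_cv = ob$inner_cv, inner_k = ob$inner_k,
                                  k_sigma = ob$k_sigma,
                                  min_appearances = ob$min_appearances)
    outliers_removed <- out_report$flagged_ids
    if (length(outliers_removed)) {
      red <- remove_samples(set, ref, outliers_removed)
      set <- red$spectra; ref <- red$reference
    }
  }

  # --- split ---------------------------------------------------------------
  sp <- split_calibration_prediction(set, ref, config$split_ratio, seeds$split)
  cal <- sp$cal; pred <- sp$pred

  # --- preprocessing (calibration-fitted, applied to prediction) -----------
  cal_p <- preprocess(cal$spectra, config$preprocess)
  msc_ref <- cal_p$meta$msc_reference
  pred_p <- preprocess(pred$spectra, config$preprocess,
                       msc_reference_spectrum = msc_ref)

  # --- calibration-only outlier removal (post-split mode) ------------------
  if (isTRUE(ob$enabled) && ob$mode == "post_split") {
    out_report <- mc_outlier_scan(cal_p, cal$reference, n_runs = ob$n_runs,
                                  validation_fraction = ob$validation_fraction,
                                  max_lv = ob$max_lv, seed = seeds$outlier,
                                  inner_cv = ob$inner_cv, inner_k = ob$inner_k,
                                  k_sigma = ob$k_sigma,
                                  min_appearances = ob$min_appearances)
    outliers_removed <- out_report$flagged_ids
    if (length(outliers_removed)) {
      red <- remove_samples(cal_p, cal$reference, outliers_removed)
      cal_p <- red$spectra; cal$reference <- red$reference
    }
  }
  yc <- cal$reference$ssc_percent
  yp <- pred$reference$ssc_percent

  # --- full-spectrum model -------------------------------------------------
  pb <- config$plsr
  full <- fit_and_report("full_spectrum", cal_p$intensities, yc,
                         pred_p$intensities, yp,
                         pb$max_lv, pb$cv, pb$k_folds, seeds$plsr)
  metrics <- full$row
  models <- list(full_spectrum = full$model)

  # --- wavelength selection + selected-variable model ----------------------
  selection <- NULL
  sb <- config$selection
  if (isTRUE(sb$enabled)) {
    selection <- combined_select(cal_p, yc, bin_width = sb$bin_width,
                                 subset_size = sb$subset_size,
                                 cv = sb$cv, k_folds = sb$k_folds,
                                 max_lv = sb$max_lv,
                                 sa = sa_config(L = sb$sa_L,
                                                cooling = sb$sa_cooling,
                                                decrement_fraction = sb$sa_decrement_fraction,
                                                alpha = sb$sa_alpha,
                                                seed = seeds$selection))
    Xc_sel <- bin_spectra(cal_p, sb$bin_width)$set$intensities[, selection$groups, drop = FALSE]
    Xp_sel <- bin_spectra(pred_p, sb$bin_width)$set$intensities[, selection$groups, drop = FALSE]
    sel <- fit_and_report("selected", Xc_sel, yc, Xp_sel, yp,
                          pb$max_lv, pb$cv, pb$k_folds, seeds$plsr)
    metrics <- rbind(metrics, sel$row)
    models$selected <- sel$model
  }

  report <- structure(
    list(metrics = metrics,
         selection = selection,
         outliers_removed = outliers_removed,
         outlier_report = out_report,
         split = list(ratio = config$split_ratio,
                      n_cal = length(yc), n_pred = length(yp),
                      cal_ids = cal_p$sample_ids, pred_ids = pred_p$sample_ids),
         models = models,
         pred_eval = full$pred_metrics,
         truth = truth,
         config_echo = serialize_config(config),
         seeds = seeds,
         version = as.character(utils::packageVersion("specselect")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_report")
  if (!is.null(out_dir)) write_run_outputs(report, cal_p, pred_p, out_dir,
                                           config$make_plots)
  report
}

serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  m <- x$metrics
  m[, -1] <- lapply(m[, -1], function(v) round(v, 4))
  print(m, row.names = FALSE)
  if (length(x$outliers_removed))
    cat("outliers removed:", paste(x$outliers_removed, collapse = ", "), "\n")
  if (!is.null(x$selection))
    cat(sprintf("selected %d groups -> %d original wavelengths\n",
                length(x$selection$groups), length(x$selection$original_indices)))
  invisible(x)
}

# Serialize all run artifacts: metrics table, model JSON, selection JSON,
# outlier CSV/plot, preprocessed spectra, report JSON and diagnostics.
write_run_outputs <- function(report, cal_p, pred_p, out_dir, make_plots) {
  write_spectra(cal_p, file.path(out_dir, "spectra_calibration_preprocessed.csv"))
  write_spectra(pred_p, file.path(out_dir, "spectra_prediction_preprocessed.csv"))
  write.csv(report$metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  for (nm in names(report$models))
    write_model(report$models[[nm]], file.path(out_dir, paste0("model_", nm, ".json")))
  if (!is.null(report$outlier_report)) {
    write.csv(report$outlier_report$stats,
              file.path(out_dir, "outlier_stats.csv"), row.names = FALSE)
  }
  if (!is.null(report$selection)) {
    sel <- report$selection
    jsonlite::write_json(
      list(groups = sel$groups, original_indices = sel$original_indices,
           original_ranges = sel$original_ranges,
           wavelength_ranges_nm = sel$wavelength_ranges_nm,
           objective_final = sel$objective_final,
           bvs_trace = sel$bvs$rmsecv_trace,
           bvs_elimination_order = sel$bvs$elimination_order,
           sa_trace = sel$sa$rmsecv_trace),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    write.csv(data.frame(iteration = seq_along(sel$bvs$rmsecv_trace) - 1,
                         rmsecv = sel$bvs$rmsecv_trace),
              file.path(out_dir, "bvs_rmsecv_trace.csv"), row.names = FALSE)
  }
  rep_json <- list(metrics = report$metrics,
                   outliers_removed = report$outliers_removed,
                   selection = if (!is.null(report$selection))
                     list(groups = report$selection$groups,
                          original_ranges = report$selection$original_ranges),
                   split = report$split, seeds = report$seeds,
                   config = report$config_echo, version = report$version,
                   timestamp = report$timestamp)
  jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(make_plots)) write_run_plots(report, cal_p, out_dir)
  invisible(out_dir)
}

write_run_plots <- function(report, cal_p, out_dir) {
  png_plot <- function(name, expr) {
    grDevices::png(file.path(out_dir, name), width = 900, height = 600)
    on.exit(grDevices::dev.off())
    expr
  }
  png_plot("spectra_preprocessed.png", {
    graphics::matplot(cal_p$wavelengths, t(cal_p$intensities), type = "l",
                      lty = 1, col = grDevices::adjustcolor("steelblue", 0.4),
                      xlab = "wavelength (nm)", ylab = "intensity",
                      main = "Calibration spectra after preprocessing")
  })
  if (!is.null(report$outlier_report))
    png_plot("outliers.png", plot(report$outlier_report,
                                  main = "Monte-Carlo outlier scan"))
  if (!is.null(report$selection))
    png_plot("bvs_trace.png", {
      tr <- report$selection$bvs$rmsecv_trace
      graphics::plot(seq_along(tr) - 1, tr, type = "b", pch = 16,
                     xlab = "BVS iteration", ylab = "RMSECV (% SSC)",
                     main = "Backward elimination RMSECV trace")
    })
  pm <- report$pred_eval
  png_plot("predicted_vs_measured.png", {
    m <- report$metrics[1, ]
    rng <- range(c(pm$y, pm$y_hat))
    graphics::plot(pm$y, pm$y_hat, pch = 16, xlim = rng, ylim = rng,
                   xlab = "measured SSC (%)", ylab = "predicted SSC (%)",
                   main = sprintf("Full spectrum: Rp=%.3f RMSEP=%.3f%%",
                                  m$Rp, m$RMSEP))
    graphics::abline(0, 1, col = "grey")
  })
  invisible(NULL)
}

#' Serialize a PLS model to JSON
#'
#' @param model a `pls_model`.
#' @param path output file.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(x_mean = model$x_mean, y_mean = model$y_mean,
         weights = model$weights, x_loadings = model$x_loadings,
         y_loadings = model$y_loadings,
         regression_vector = model$regression_vector,
         n_lv = model$n_lv, meta = model$meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Compare acquisition orientations via matched pipeline runs
#'
#' Runs the full pipeline once per orientation on matched seeds; the
#' orientations differ only in the path-length factor (and optionally noise),
#' emulating fruit presented with its stem-calyx axis perpendicular vs
#' parallel to the conveyor.
#'
#' @param config a [pipeline_config()] whose data source is a simulate block.
#' @param orientations named list of per-orientation overrides, each a list of
#'   [sim_config()] fields drawn from `path_factor`, `path_sd`, `noise_sd`,
#'   `scatter_mult_sd`, `scatter_add_sd` (the optical-geometry and noise
#'   fields an orientation change can plausibly alter).
#' @param out_dir optional output directory (one subdirectory per orientation).
#' @return A list of class `orientation_comparison`: `table` (one metrics row
#'   per orientation, full-spectrum model) and `reports`.
#' @export
compare_orientations <- function(config,
                                 orientations = list(Z1 = list(path_factor = 0.6),
                                                     Z2 = list(path_factor = 1.0)),
                                 out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$simulate))
    stop("compare_orientations needs a simulate block")
  allowed <- c("path_factor", "path_sd", "noise_sd", "scatter_mult_sd",
               "scatter_add_sd")
  for (o in orientations) {
    bad <- setdiff(names(o), allowed)
    if (length(bad)) stop(sprintf("orientation override not permitted: %s",
                                  paste(bad, collapse = ", ")))
  }
  reports <- lapply(names(orientations), function(nm) {
    cfg <- config
    for (f in names(orientations[[nm]]))
      cfg$simulate[[f]] <- orientations[[nm]][[f]]
    validate_sim_config(cfg$simulate)
    run_pipeline(cfg, out_dir = if (is.null(out_dir)) NULL
                                else file.path(out_dir, nm))
  })
  names(reports) <- names(orientations)
  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]$metrics[1, ]
    data.frame(orientation = nm, LVs = r$LVs, Rc = r$Rc, RMSEC = r$RMSEC,
               Rp = r$Rp, RMSEP = r$RMSEP)
  }))
  structure(list(table = rows, reports = reports),
            class = "orientation_comparison")
}

#' @export
print.orientation_comparison <- function(x, ...) {
  cat("<orientation_comparison>\n")
  m <- x$table
  m[, -1] <- lapply(m[, -1], function(v) round(v, 4))
  print(m, row.names = FALSE)
  invisible(x)
}
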