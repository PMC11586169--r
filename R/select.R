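#' Bin a spectrum set into contiguous wavelength groups
#'
#' Partitions the wavelength axis into contiguous groups of `width` adjacent
#' points and represents each group by the sum of its intensities (2048
#' wavelengths at widths 32/16/8 give 64/128/256 variables). Total intensity
#' is conserved exactly.
#'
#' @param x a [spectrum_set()] or a numeric matrix (samples x wavelengths).
#' @param width group width in grid points; must divide the wavelength count.
#' @return A list with `set` (the binned `spectrum_set`, labelled by range
#'   midpoints, or matrix when `x` was a matrix) and `map` (a `grouping_map`
#'   with `w`, `n`, `m` and 1-based inclusive `ranges`).
#' @export
bin_spectra <- function(x, width) {
  is_set <- inherits(x, "spectrum_set")
  X <- if (is_set) x$intensities else as.matrix(x)
  w <- ncol(X)
  if (width < 1 || w %% width != 0) {
    div <- (1:w)[w %% (1:w) == 0]
    stop(sprintf("bin width %d does not divide %d wavelengths; valid widths: %s",
                 width, w, paste(utils::head(div[div > 1 & div < w], 12),
                                 collapse = ", ")))
  }
  width <- as.integer(width)
  m <- as.integer(w %/% width)
  grp <- rep(seq_len(m), each = width)
  Xb <- t(rowsum(t(X), grp))            # samples x m group sums
  ranges <- cbind(start = (seq_len(m) - 1L) * width + 1L,
                  end = seq_len(m) * width)
  map <- structure(list(w = w, n = width, m = m, ranges = ranges),
                   class = "grouping_map")
  if (is_set) {
    mid <- (x$wavelengths[ranges[, "start"]] + x$wavelengths[ranges[, "end"]]) / 2
    set <- spectrum_set(mid, Xb, x$sample_ids, meta = x$meta)
    set <- add_history(set, sprintf("bin(width=%d)", width))
    list(set = set, map = map)
  } else {
    list(set = Xb, map = map)
  }
}

#' @export
print.grouping_map <- function(x, ...) {
  cat(sprintf("<grouping_map> %d wavelengths = %d groups x %d points\n",
              x$w, x$m, x$n))
  invisible(x)
}

#' Original-grid indices covered by selected groups
#'
#' @param map a `grouping_map` from [bin_spectra()].
#' @param groups group indices.
#' @return Sorted integer vector of original wavelength indices.
#' @export
groups_to_indices <- function(map, groups) {
  stopifnot(inherits(map, "grouping_map"), all(groups >= 1 & groups <= map$m))
  sort(unlist(lapply(groups, function(g)
    seq(map$ranges[g, "start"], map$ranges[g, "end"]))))
}

new_selection_result <- function(selected, trace, order_or_moves, objective,
                                 method, params) {
  structure(list(selected = sort(unique(as.integer(selected))),
                 rmsecv_trace = trace,
                 elimination_order = if (method == "bvs") order_or_moves else NULL,
                 accepted_moves = if (method == "sa") order_or_moves else NULL,
                 objective_final = objective,
                 provenance = c(list(method = method), params)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d variables, final RMSECV %.4f\n",
              x$provenance$method, length(x$selected), x$objective_final))
  invisible(x)
}

# Shared objective: minimum RMSECV over LV counts for a variable subset,
# with the fold assignment held fixed across evaluations.
subset_objective <- function(X, y, cols, folds, max_lv) {
  Xs <- X[, cols, drop = FALSE]
  cap <- min(max_lv, ncol(Xs), nrow(Xs) - max(tabulate(folds)) - 1)
  cv <- pls_rmsecv(Xs, y, max_lv = cap, folds = folds)
  min(cv$rmsecv_by_lv)
}

#' Backward variable selection PLS (BVS-PLS)
#'
#' Greedy backward elimination over grouped spectral variables: at each
#' iteration every remaining group's removal is evaluated by cross-validated
#' RMSECV (latent variables re-selected each time, capped at `max_lv`) and the
#' group whose removal decreases RMSECV the most is discarded; elimination
#' stops when no removal decreases RMSECV or `min_groups` is reached. Ties are
#' broken toward the lowest group index.
#'
#' @param X matrix of grouped variables (samples x groups), e.g. the binned
#'   set from [bin_spectra()].
#' @param y response vector (% SSC).
#' @param cv `"loo"` (default) or `"kfold"` for the objective.
#' @param k folds for `cv = "kfold"`.
#' @param min_groups stop when this many groups remain.
#' @param max_lv latent-variable cap for every evaluation.
#' @param seed seed for the k-fold assignment (fixed across all evaluations).
#' @return A `selection_result`: surviving group indices, the RMSECV trace
#'   (initial value then one entry per removal), `elimination_order`, and the
#'   final objective.
#' @export
bvs_pls <- function(X, y, cv = c("loo", "kfold"), k = 5, min_groups = 1,
                    max_lv = 20, seed = 1) {
  if (inherits(X, "spectrum_set")) X <- X$intensities
  X <- as.matrix(X); y <- as.numeric(y)
  cv <- match.arg(cv)
  m <- ncol(X)
  params <- list(cv = cv, k = k, min_groups = min_groups, max_lv = max_lv,
                 seed = seed)
  if (min_groups >= m)
    return(new_selection_result(seq_len(m), numeric(0), integer(0),
                                NA_real_, "bvs", params))
  if (m < 2) stop("need at least 2 groups")
  if (sd(y) == 0) stop("constant response")
  folds <- cv_folds(nrow(X), cv, k, seed)
  current <- seq_len(m)
  obj <- subset_objective(X, y, current, folds, max_lv)
  trace <- obj
  order_removed <- integer(0)
  while (length(current) > min_groups) {
    cand <- vapply(seq_along(current), function(j)
      subset_objective(X, y, current[-j], folds, max_lv), numeric(1))
    best <- which.min(cand)                     # first minimum: lowest index
    if (cand[best] >= obj) break                # RMSECV no longer decreasing
    order_removed <- c(order_removed, current[best])
    current <- current[-best]
    obj <- cand[best]
    trace <- c(trace, obj)
  }
  new_selection_result(current, trace, order_removed, obj, "bvs", params)
}

#' Simulated-annealing configuration
#'
#' @param T0 initial temperature in objective units; defaults to the RMSECV of
#'   the initial random subset.
#' @param cooling `"adaptive_decrement"` (default): after each iteration
#'   `T <- T - decrement_fraction * best RMSECV so far`, so the cooling step
#'   shrinks as the error improves; or `"geometric"`: `T <- alpha * T`.
#' @param alpha geometric cooling factor (0 < alpha < 1).
#' @param decrement_fraction fraction of the best RMSECV subtracted per
#'   iteration under adaptive cooling (default 0.005, i.e. 0.5%).
#' @param L total iteration budget.
#' @param Te termination temperature; defaults to `1e-8 * T0` under geometric
#'   cooling. Under adaptive decrement the temperature is clamped at zero once
#'   the decrements exhaust it and the remaining iteration budget is spent in
#'   pure downhill refinement, so `Te` defaults to 0.
#' @param seed integer seed.
#' @return A list of class `sa_config`.
#' @export
sa_config <- function(T0 = NULL, cooling = c("adaptive_decrement", "geometric"),
                      alpha = 0.95, decrement_fraction = 0.005,
                      L = 500, Te = NULL, seed = 1) {
  cooling <- match.arg(cooling)
  if (!is.null(T0) && T0 <= 0) stop_field("T0", "must be > 0")
  if (alpha <= 0 || alpha >= 1) stop_field("alpha", "must be in (0, 1)")
  if (decrement_fraction <= 0) stop_field("decrement_fraction", "must be > 0")
  if (L < 1) stop_field("L", "must be >= 1")
  if (!is.null(Te) && Te < 0) stop_field("Te", "must be >= 0")
  structure(list(T0 = T0, cooling = cooling, alpha = alpha,
                 decrement_fraction = decrement_fraction, L = L, Te = Te,
                 seed = seed),
            class = "sa_config")
}

#' Simulated-annealing subset selection
#'
#' Searches for the size-`subset_size` variable subset minimizing
#' cross-validated RMSECV. Starting from a random subset, each iteration
#' proposes swapping one selected variable for one unselected variable
#' (discrete neighborhood move); improvements are always accepted and
#' deteriorations with Metropolis probability `exp(-dC/T)`. The temperature
#' starts at the initial subset's RMSECV and is updated after every iteration
#' by the configured cooling rule; the search stops at the termination
#' temperature or when the iteration budget is exhausted. The best subset
#' ever visited is returned.
#'
#' @param X predictor matrix (samples x variables) or [spectrum_set()].
#' @param y response vector (% SSC).
#' @param subset_size number of variables to select (`k`).
#' @param config an [sa_config()].
#' @param cv,k_folds,max_lv objective definition: cross-validation scheme,
#'   fold count and latent-variable cap for [pls_rmsecv()].
#' @return A `selection_result`: selected indices, best-objective trace per
#'   iteration, the accepted-moves log, and the final objective (re-evaluated
#'   on the returned subset).
#' @export
sa_select <- function(X, y, subset_size, config = sa_config(),
                      cv = c("loo", "kfold"), k_folds = 5, max_lv = 20) {
  if (inherits(X, "spectrum_set")) X <- X$intensities
  X <- as.matrix(X); y <- as.numeric(y)
  cv <- match.arg(cv)
  p <- ncol(X)
  if (subset_size < 1 || subset_size > p)
    stop(sprintf("subset_size must be in [1, %d]", p))
  params <- list(config = unclass(config), cv = cv, k_folds = k_folds,
                 max_lv = max_lv, subset_size = subset_size)
  folds <- cv_folds(nrow(X), cv, k_folds, config$seed)
  objective <- function(cols) subset_objective(X, y, cols, folds, max_lv)
  if (subset_size == p) {
    obj <- objective(seq_len(p))
    return(new_selection_result(seq_len(p), obj, list(), obj, "sa", params))
  }
  with_seed(config$seed, {
    current <- sort(sample(p, subset_size))
    cur_obj <- objective(current)
    if (!is.finite(cur_obj)) stop("non-finite objective on initial subset")
    Tt <- config$T0 %||% cur_obj
    Te <- config$Te %||%
      (if (config$cooling == "geometric") 1e-8 * Tt else 0)
    best <- current; best_obj <- cur_obj
    trace <- numeric(config$L)
    moves <- vector("list", config$L)
    it <- 0L
    while (it < config$L && (Tt > Te || Te == 0)) {
      it <- it + 1L
      drop_i <- current[sample.int(subset_size, 1)]
      add_i <- setdiff(seq_len(p), current)[sample.int(p - subset_size, 1)]
      proposal <- sort(c(setdiff(current, drop_i), add_i))
      prop_obj <- objective(proposal)
      if (!is.finite(prop_obj)) stop("non-finite objective")
      delta <- prop_obj - cur_obj
      accept <- delta < 0 ||
        (Tt > 0 && runif(1) < exp(-delta / Tt))
      if (accept) {
        current <- proposal; cur_obj <- prop_obj
        if (cur_obj < best_obj) { best <- current; best_obj <- cur_obj }
      }
      trace[it] <- best_obj
      moves[[it]] <- list(iter = it, out = drop_i, `in` = add_i,
                          objective = prop_obj, temperature = Tt,
                          accepted = accept)
      Tt <- switch(config$cooling,
                   adaptive_decrement = max(Tt - config$decrement_fraction * best_obj, 0),
                   geometric = config$alpha * Tt)
    }
    final_obj <- objective(best)   # self-consistency: reported = re-evaluated
    new_selection_result(best, trace[seq_len(it)], moves[seq_len(it)],
                         final_obj, "sa", params)
  })
}

#' Combined BVS-PLS then simulated-annealing wavelength selection
#'
#' The full selection chain: bin the spectrum into groups of `bin_width`
#' points, run backward variable selection over the binned variables, then
#' refine the survivors to a fixed-size subset by simulated annealing, and map
#' the final binned variables back to original-grid wavelength index ranges.
#' When `subset_size` equals the number of BVS survivors the annealing stage
#' is the identity.
#'
#' @param set a [spectrum_set()] (calibration samples only, to avoid leakage).
#' @param y response vector (% SSC).
#' @param bin_width group width in grid points.
#' @param subset_size final number of binned variables to retain.
#' @param cv,k_folds,max_lv objective definition shared by both stages.
#' @param bvs_min_groups floor for the elimination stage.
#' @param sa a [sa_config()].
#' @return A list of class `combined_selection`: `groups` (selected group
#'   indices on the binned axis), `original_indices`, `original_ranges`
#'   (list of start/end index pairs), `wavelength_ranges_nm`, and the stage
#'   results `binning`, `bvs`, `sa`.
#' @export
combined_select <- function(set, y, bin_width = 16, subset_size = 20,
                            cv = c("loo", "kfold"), k_folds = 5, max_lv = 20,
                            bvs_min_groups = 2, sa = sa_config()) {
  stopifnot(inherits(set, "spectrum_set"))
  cv <- match.arg(cv)
  binned <- bin_spectra(set, bin_width)
  bvs <- bvs_pls(binned$set$intensities, y, cv = cv, k = k_folds,
                 min_groups = max(bvs_min_groups, subset_size),
                 max_lv = max_lv, seed = sa$seed)
  survivors <- bvs$selected
  if (subset_size > length(survivors))
    stop(sprintf("subset_size %d exceeds the %d BVS survivors",
                 subset_size, length(survivors)))
  if (subset_size == length(survivors)) {
    sa_res <- new_selection_result(seq_along(survivors), bvs$objective_final,
                                   list(), bvs$objective_final, "sa",
                                   list(note = "identity: subset_size equals survivor count"))
  } else {
    sa_res <- sa_select(binned$set$intensities[, survivors, drop = FALSE], y,
                        subset_size = subset_size, config = sa,
                        cv = cv, k_folds = k_folds, max_lv = max_lv)
  }
  groups <- sort(survivors[sa_res$selected])
  idx <- groups_to_indices(binned$map, groups)
  ranges <- lapply(groups, function(g)
    c(start = unname(binned$map$ranges[g, "start"]),
      end = unname(binned$map$ranges[g, "end"])))
  wl_ranges <- lapply(ranges, function(r)
    c(from_nm = set$wavelengths[r[["start"]]], to_nm = set$wavelengths[r[["end"]]]))
  structure(list(groups = groups, original_indices = idx,
                 original_ranges = ranges, wavelength_ranges_nm = wl_ranges,
                 binning = binned$map, bvs = bvs, sa = sa_res,
                 objective_final = sa_res$objective_final),
            class = "combined_selection")
}

#' @export
print.combined_selection <- function(x, ...) {
  cat(sprintf("<combined_selection> %d groups (%d original wavelengths), RMSECV %.4f\n",
              length(x$groups), length(x$original_indices), x$objective_final))
  invisible(x)
}
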