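test_that("binning sums contiguous groups and conserves total intensity", {
  expect_equal(unname(bin_spectra(matrix(c(1, 2, 3, 4), 1), 2)$set),
               matrix(c(3, 7), 1))
  ones <- matrix(1, 2, 64)
  expect_true(all(bin_spectra(ones, 16)$set == 16))
  g <- simulate_spectra(sim_config(n_samples = 4, n_wavelengths = 256, seed = 2))
  b <- bin_spectra(g$spectra, 16)
  expect_equal(rowSums(b$set$intensities), rowSums(g$spectra$intensities))
  expect_equal(b$map$m, 16)
  expect_equal(b$map$w, 256)
  # labels are range midpoints
  expect_equal(b$set$wavelengths[1],
               (g$spectra$wavelengths[1] + g$spectra$wavelengths[16]) / 2)
  expect_error(bin_spectra(g$spectra, 24), "valid widths")
  expect_equal(groups_to_indices(b$map, 2), 17:32)
})

test_that("backward elimination drops a pure-noise group first", {
  set.seed(44)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- drop(X[, 1:5] %*% c(1, 0.8, -0.6, 0.5, 0.9))   # column 6 is pure noise
  res <- bvs_pls(X, y, cv = "loo", max_lv = 5)
  expect_equal(res$elimination_order[1], 6L)
  # exhaustive check: removing column 6 gives the smallest RMSECV of all removals
  single <- vapply(1:6, function(j)
    min(r_rmsecv(X[, -j, drop = FALSE], y, 5)), numeric(1))
  expect_equal(which.min(single), 6L)
})

test_that("the elimination path matches a brute-force greedy oracle", {
  for (s in 1:3) {
    set.seed(800 + s)
    m <- c(6, 8, 10)[s]
    X <- matrix(rnorm(24 * m), 24, m)
    beta <- rnorm(m) * rbinom(m, 1, 0.5)
    y <- drop(X %*% beta) + rnorm(24, 0, 0.3)
    res <- bvs_pls(X, y, cv = "loo", max_lv = 4)
    oracle <- r_bvs_oracle(X, y, max_lv = 4)
    expect_identical(res$selected, sort(oracle$selected))
    expect_identical(res$elimination_order, oracle$order)
    expect_equal(res$objective_final, oracle$objective, tolerance = 1e-8)
  }
})

test_that("elimination trace is strictly decreasing and provenance is coherent", {
  set.seed(47)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- drop(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(30, 0, 0.5)
  res <- bvs_pls(X, y, cv = "loo", max_lv = 4)
  expect_true(all(diff(res$rmsecv_trace) < 0))
  expect_equal(length(res$rmsecv_trace), length(res$elimination_order) + 1)
  expect_setequal(c(res$selected, res$elimination_order), 1:8)
})

test_that("degenerate elimination inputs are handled per contract", {
  X <- matrix(rnorm(40), 20, 2); y <- rnorm(20)
  res <- bvs_pls(X, y, min_groups = 5)
  expect_identical(res$selected, 1:2)
  expect_length(res$rmsecv_trace, 0)
  single <- bvs_pls(matrix(rnorm(20), 20, 1), y)
  expect_identical(single$selected, 1L)
  expect_length(single$rmsecv_trace, 0)
})

test_that("annealing returns the whole set when the subset is the whole space", {
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3); y <- rnorm(20)
  res <- sa_select(X, y, subset_size = 3, config = sa_config(seed = 1))
  expect_identical(res$selected, 1:3)
  expect_error(sa_select(X, y, subset_size = 5), "subset_size")
})

test_that("at zero temperature the accepted objective trace is non-increasing", {
  set.seed(19)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- drop(X[, c(2, 7)] %*% c(1, -1)) + rnorm(30, 0.1)
  res <- sa_select(X, y, subset_size = 3,
                   config = sa_config(T0 = 1e-12, Te = 0, L = 150, seed = 4),
                   cv = "loo", max_lv = 3)
  acc <- Filter(function(m) m$accepted, res$accepted_moves)
  objs <- vapply(acc, function(m) m$objective, numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("the best-ever objective trace is non-increasing and self-consistent", {
  set.seed(23)
  X <- matrix(rnorm(30 * 12), 30, 12)
  y <- drop(X[, 1:4] %*% rnorm(4)) + rnorm(30, 0, 0.4)
  res <- sa_select(X, y, subset_size = 4, config = sa_config(L = 200, seed = 6),
                   cv = "loo", max_lv = 4)
  expect_true(all(diff(res$rmsecv_trace) <= 1e-12))
  refit <- pls_rmsecv(X[, res$selected, drop = FALSE], y, max_lv = 4)
  expect_equal(res$objective_final, min(refit$rmsecv_by_lv), tolerance = 1e-10)
})

test_that("annealing finds the exhaustive-search optimum on a small problem", {
  set.seed(29)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- drop(X[, c(3, 8)] %*% c(1.2, -0.9)) + rnorm(30, 0, 0.3)
  combos <- utils::combn(10, 2)
  all_obj <- apply(combos, 2, function(cols)
    min(pls_rmsecv(X[, cols, drop = FALSE], y, max_lv = 2)$rmsecv_by_lv))
  best <- sort(combos[, which.min(all_obj)])
  res <- sa_select(X, y, subset_size = 2, config = sa_config(L = 500, seed = 11),
                   cv = "loo", max_lv = 2)
  expect_identical(res$selected, best)
})

test_that("combined selection returns subset_size groups mapped to index ranges", {
  g <- simulate_spectra(sim_config(n_samples = 48, n_wavelengths = 512, seed = 31))
  calp <- preprocess(g$spectra, preprocess_config("gf+msc"))
  y <- g$reference$ssc_percent
  sel <- combined_select(calp, y, bin_width = 16, subset_size = 5,
                         cv = "kfold", k_folds = 5, max_lv = 10,
                         sa = sa_config(L = 120, seed = 3))
  expect_length(sel$groups, 5)
  expect_length(sel$original_indices, 80)
  expect_length(sel$original_ranges, 5)
  for (i in seq_along(sel$original_ranges)) {
    r <- sel$original_ranges[[i]]
    expect_equal(r[["end"]] - r[["start"]] + 1, 16)
    expect_equal(groups_to_indices(sel$binning, sel$groups[i]),
                 r[["start"]]:r[["end"]])
  }
  expect_true(all(diff(sel$groups) > 0))
})

test_that("annealing stage is the identity when subset size equals the survivor count", {
  set.seed(37)
  g <- simulate_spectra(sim_config(n_samples = 30, n_wavelengths = 128, seed = 37))
  calp <- preprocess(g$spectra, preprocess_config("gf"))
  y <- g$reference$ssc_percent
  binned <- bin_spectra(calp, 16)
  bvs <- bvs_pls(binned$set$intensities, y, cv = "kfold", k = 5,
                 min_groups = 2, max_lv = 8, seed = 3)
  sel <- combined_select(calp, y, bin_width = 16,
                         subset_size = length(bvs$selected),
                         cv = "kfold", k_folds = 5, max_lv = 8,
                         bvs_min_groups = 2, sa = sa_config(seed = 3))
  expect_identical(sel$groups, sort(bvs$selected))
  # more groups than exist on the binned axis cannot be selected
  expect_error(combined_select(calp, y, bin_width = 16, subset_size = 9,
                               cv = "kfold", k_folds = 5, max_lv = 8,
                               bvs_min_groups = 2, sa = sa_config(seed = 3)),
               "survivors")
})
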