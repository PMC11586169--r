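# Shared fixtures built in code: small simulated problems and an R-native
# reference PLS/RMSECV implementation used as an independent oracle for the
# compiled kernels.

small_problem <- function(seed = 1, n = 24, m = 64) {
  simulate_spectra(sim_config(n_samples = n, n_wavelengths = m, seed = seed))
}

# Plain-R NIPALS PLS1 (no shared code with the package kernel): returns
# fitted values for a given component count.
r_pls1_fitted <- function(X, y, ncomp, newdata = X) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- P <- NULL; q <- numeric(0)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc)); w <- w / sqrt(sum(w^2))
    t <- drop(Xc %*% w); tt <- sum(t^2)
    p <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    W <- cbind(W, w); P <- cbind(P, p); q <- c(q, qa)
    Xc <- Xc - tcrossprod(t, p); yc <- yc - qa * t
  }
  b <- W %*% solve(crossprod(P, W), q)
  drop(sweep(newdata, 2, xm) %*% b) + ym
}

# Explicit cross-validation loop over the R-native PLS: independent oracle
# for the compiled RMSECV kernel.
r_rmsecv <- function(X, y, max_lv, folds = seq_len(nrow(X))) {
  sse <- numeric(max_lv)
  for (k in unique(folds)) {
    test <- which(folds == k); train <- which(folds != k)
    for (a in seq_len(max_lv)) {
      pred <- r_pls1_fitted(X[train, , drop = FALSE], y[train], a,
                            newdata = X[test, , drop = FALSE])
      sse[a] <- sse[a] + sum((pred - y[test])^2)
    }
  }
  sqrt(sse / length(y))
}

# R-level greedy backward-elimination oracle, independent of bvs_pls: at each
# step it evaluates every single-group removal with the R-native RMSECV.
r_bvs_oracle <- function(X, y, max_lv, min_groups = 1) {
  current <- seq_len(ncol(X))
  obj <- function(cols) {
    cap <- min(max_lv, length(cols), nrow(X) - 2)
    min(r_rmsecv(X[, cols, drop = FALSE], y, cap))
  }
  cur <- obj(current)
  order_removed <- integer(0)
  while (length(current) > min_groups) {
    cand <- vapply(seq_along(current), function(j) obj(current[-j]), numeric(1))
    best <- which.min(cand)
    if (cand[best] >= cur) break
    order_removed <- c(order_removed, current[best])
    current <- current[-best]
    cur <- cand[best]
  }
  list(selected = current, order = order_removed, objective = cur)
}

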