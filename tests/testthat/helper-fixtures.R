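# shared fixtures, built once per test run

fx <- new.env()

# small multispectral scene with separable classes
fx_scene <- function(seed = 7, frac = 0.6, size = c(64, 64)) {
  key <- sprintf("scene_%d_%s", seed, paste(size, collapse = "x"))
  if (is.null(fx[[key]]))
    fx[[key]] <- generate_scene(frac, size_px = size, seed = seed)
  fx[[key]]
}

# benchmark feature table: 2 causal + n_noise noise features, SNR 2
fx_table <- function(seed = 3, n = 200, n_noise = 10) {
  key <- sprintf("tab_%d_%d_%d", seed, n, n_noise)
  if (is.null(fx[[key]]))
    fx[[key]] <- generate_feature_table(n, n_noise, fixture_truth(2),
                                        seed = seed)
  fx[[key]]
}

fx_features <- function(tab) {
  tab[, grep("^(NDVI|NDRE|noise)", names(tab)), drop = FALSE]
}

# independent greedy oracle for the MRMR objective: evaluates relevance minus
# mean redundancy from scratch at every step (no shared selection code)
oracle_mrmr_order <- function(X, y, bins) {
  p <- ncol(X)
  pool <- seq_len(p)
  sel <- integer(0)
  while (length(pool) > 0) {
    obj <- sapply(pool, function(j) {
      relev <- mutual_information(X[[j]], y, bins = bins)
      if (length(sel) == 0) return(relev)
      redund <- mean(sapply(sel, function(i)
        mutual_information(X[[j]], X[[i]], bins = bins)))
      relev - redund
    })
    pick <- pool[which.max(obj)]
    sel <- c(sel, pick)
    pool <- setdiff(pool, pick)
  }
  names(X)[sel]
}

# exhaustive between-class-variance maximiser over splits of sorted distinct
# values; recomputes class statistics directly per candidate
oracle_otsu <- function(values) {
  u <- sort(unique(values))
  cand <- (u[-1] + u[-length(u)]) / 2
  bcv <- sapply(cand, function(t) {
    lo <- values[values <= t]; hi <- values[values > t]
    w0 <- length(lo) / length(values)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  })
  mean(cand[bcv == max(bcv)])
}

# small grids so grid search stays fast in tests
grid_small <- list(
  LR = list(alpha = c(0, 0.01, 0.1)),
  RR = list(alpha = c(0, 0.01, 0.1)),
  DTR = list(max_depth = c(5, 10), min_samples_split = c(5, 10)),
  RFR = list(n_estimators = 50, max_depth = 10, min_samples_split = 5),
  XGBoost = list(max_depth = c(3, 6), learning_rate = c(0.05, 0.1),
                 n_estimators = 100),
  LightGBM = list(num_leaves = 50, learning_rate = 0.1, n_estimators = 100))
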