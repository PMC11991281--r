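test_that("evaluation metrics reproduce hand-computed cases and identities", {
  y <- c(0.3, 1.2, 2.5, 4.1)
  perf <- eval_metrics(y, y)
  expect_equal(perf$R2, 1); expect_equal(perf$RMSE, 0); expect_equal(perf$MAE, 0)

  m <- eval_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$R2, 0)
  expect_equal(m$RMSE, sqrt(2 / 3))
  expect_equal(m$MAE, 2 / 3)

  # predicting the mean is the null baseline
  expect_equal(eval_metrics(y, rep(mean(y), 4))$R2, 0)
  expect_warning(eval_metrics(rep(1, 3), c(1, 2, 3)), "constant")
})

test_that("RMSE >= MAE for random prediction pairs", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    m <- eval_metrics(rnorm(n), rnorm(n))
    expect_gte(m$RMSE, m$MAE)
  }
})

test_that("a noiseless planted linear relation is fit perfectly", {
  truth <- truth_model(coef = list(LAI = c(intercept = 1, NDVI = 6, NDRE = 2.5)),
                       noise_sd = c(LAI = 0), ranges = list(LAI = NULL))
  tab <- generate_feature_table(60, 0, truth, seed = 2)
  X <- tab[, c("NDVI", "NDRE")]
  fit <- fit_model(X, tab$LAI, model_spec("LR", grid = grid_small$LR), seed = 1)
  expect_gte(fit$cv_metrics$R2, 0.999)
})

test_that("deterministic models give identical folds and choices under one seed", {
  tab <- fx_table()
  X <- fx_features(tab)[, 1:5]
  for (m in c("PR", "PLSR", "LR", "RR", "DTR")) {
    sp <- model_spec(m, grid = grid_small[[m]])
    a <- fit_model(X, tab$LAI, sp, seed = 21)
    b <- fit_model(X, tab$LAI, sp, seed = 21)
    expect_identical(a$folds, b$folds, label = m)
    expect_identical(a$best_params, b$best_params, label = m)
    expect_identical(a$cv_metrics, b$cv_metrics, label = m)
  }
})

test_that("stochastic learners are reproducible given their recorded seed", {
  tab <- fx_table()
  X <- fx_features(tab)[, 1:5]
  for (m in c("RFR", "XGBoost", "LightGBM")) {
    sp <- model_spec(m, grid = grid_small[[m]], seed = 31)
    a <- fit_model(X, tab$LAI, sp, seed = 21)
    b <- fit_model(X, tab$LAI, sp, seed = 21)
    expect_identical(a$cv_metrics, b$cv_metrics, label = m)
  }
})

test_that("infeasible grid entries are skipped and logged, not fatal", {
  tab <- fx_table()
  X <- fx_features(tab)[, 1, drop = FALSE]  # single feature
  sp <- model_spec("PLSR", grid = list(n_components = c(1, 5)))
  fit <- fit_model(X, tab$LAI, sp, seed = 1)
  expect_true(is.finite(fit$cv_metrics$R2))
})

test_that("ridge beats unregularised polynomial regression on collinear designs", {
  wins <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    base <- rnorm(n)
    X <- data.frame(f1 = base,
                    f2 = base + rnorm(n, 0, 0.01),
                    f3 = base + rnorm(n, 0, 0.01),
                    f4 = rnorm(n))
    y <- 2 * base + 0.5 * X$f4 + rnorm(n, 0, 0.3)
    rr <- fit_model(X, y, model_spec("RR", grid = list(alpha = c(0.01, 0.1, 1))),
                    seed = s)
    pr <- fit_model(X, y, model_spec("PR"), seed = s)
    rr$cv_metrics$R2 >= pr$cv_metrics$R2
  })
  expect_gte(mean(wins), 0.5)  # 20-seed median: RR at least matches PR
})

test_that("incremental sweep walks ranked features without gaps", {
  tab <- fx_table(seed = 5, n = 150, n_noise = 4)
  X <- fx_features(tab)
  rk <- rank_features(X, tab$LAI, "PCA")
  curve <- incremental_sweep(X, tab$LAI, rk,
                             model_spec("LR", grid = grid_small$LR), seed = 2)
  expect_equal(curve$k, seq_len(ncol(X)))
  expect_identical(curve$feature_added, rk$feature)
  expect_equal(attr(curve, "model"), "LR")
})

test_that("a single dominant causal feature saturates the curve at k = 1", {
  ok <- sapply(1:5, function(s) {
    truth <- truth_model(coef = list(LAI = c(intercept = 1, NDVI = 6)),
                         snr = c(LAI = 3), ranges = list(LAI = NULL))
    tab <- generate_feature_table(200, 5, truth, seed = s)
    X <- fx_features(tab)
    rk <- rank_features(X, tab$LAI, "PCA")
    curve <- incremental_sweep(X, tab$LAI, rk,
                               model_spec("LR", grid = grid_small$LR),
                               seed = s)
    max(curve$R2) - curve$R2[1] <= 0.02
  })
  expect_true(all(ok))
})

test_that("appending noise features cannot collapse the best-so-far accuracy", {
  drops <- sapply(1:10, function(s) {
    tab <- generate_feature_table(150, 8, fixture_truth(2), seed = s)
    X <- fx_features(tab)
    rk <- rank_features(X, tab$LAI, "PCA")
    curve <- incremental_sweep(X, tab$LAI, rk,
                               model_spec("RR", grid = grid_small$RR),
                               seed = s)
    max(cummax(curve$R2) - curve$R2)
  })
  expect_lte(median(drops), 0.05)
})

test_that("parsimony selection implements the 95%-of-best rule", {
  curve <- data.frame(k = 1:3, R2 = c(0.50, 0.69, 0.716))
  sel <- parsimony_select(curve)
  expect_equal(sel$n_best, 3)
  expect_equal(sel$threshold, 0.6802)
  expect_equal(sel$n_reduced, 2)
  expect_equal(sel$reduced_R2, 0.69)

  mono <- data.frame(k = 1:4, R2 = c(0.8, 0.7, 0.6, 0.5))
  sel2 <- parsimony_select(mono)
  expect_equal(sel2$n_best, 1)
  expect_equal(sel2$n_reduced, 1)

  expect_equal(round(parsimony_threshold(0.716), 3), 0.680)
})

test_that("parsimony invariants hold on random curves", {
  set.seed(12)
  for (i in 1:50) {
    curve <- data.frame(k = 1:10, R2 = runif(10, 0.1, 0.9))
    sel <- parsimony_select(curve)
    expect_lte(sel$n_reduced, sel$n_best)
    expect_gte(sel$reduced_R2, sel$threshold)
  }
})

test_that("family comparison computes gains and variable reductions", {
  s <- data.frame(parameter = c("A", "A"), family = c("CI", "MI"),
                  best_R2 = c(0.3, 0.65), n_best = c(10, 40),
                  n_reduced = c(8, 12))
  out <- compare_families(s)
  expect_equal(out$family_gain$gain, 0.35)
  expect_equal(out$reduction$n_removed, c(2, 28))
})
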