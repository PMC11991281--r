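#' Evaluation metrics for predictions
#'
#' R2 = 1 - SS_res/SS_tot, RMSE = sqrt(mean squared error), MAE = mean
#' absolute error, with SS_tot taken about the mean of the measured values.
#'
#' @param y_measured,y_predicted numeric vectors of equal length >= 2.
#' @return list with `R2` (NA with a warning when `y_measured` is constant),
#'   `RMSE`, `MAE`, `n`.
#' @export
eval_metrics <- function(y_measured, y_predicted) {
  n <- length(y_measured)
  stopifnot(n == length(y_predicted), n >= 2)
  err <- y_measured - y_predicted
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  ss_tot <- sum((y_measured - mean(y_measured))^2)
  r2 <- if (ss_tot == 0) {
    warning("R2 undefined: constant y_measured")
    NA_real_
  } else 1 - sum(err^2) / ss_tot
  list(R2 = r2, RMSE = rmse, MAE = mae, n = n)
}

#' Hyperparameter grids for the eight regressors
#'
#' The tuned grids: polynomial regression (PR) fixes a 2nd-degree expansion;
#' PLSR tries 2..N components; lasso (LR) and ridge (RR) share the
#' regularisation strengths 0, 0.01, 0.1, 1, 10, 100; decision tree (DTR)
#' spans max_depth 4..100 with min_samples_split 5..50 by 5; random forest
#' (RFR) adds n_estimators 50..150 by 25 over max_depth 3..50; XGBoost spans
#' max_depth 3..25, learning_rate {0.001, 0.005, 0.01, 0.05, 0.1},
#' n_estimators 50..150 by 25; LightGBM-style leaf-wise boosting spans
#' num_leaves 50..150 by 10 with the same learning rates and tree counts.
#' Integer ranges without a stated increment are enumerated at step 1.
#'
#' @param model model name.
#' @return named list of grid vectors (empty for PR).
#' @export
default_grid <- function(model = c("PR", "PLSR", "LR", "RR", "DTR", "RFR",
                                   "XGBoost", "LightGBM")) {
  model <- match.arg(model)
  switch(model,
    PR = list(),
    PLSR = list(n_components = NA),  # resolved to 2:N at fit time
    LR = list(alpha = c(0, 0.01, 0.1, 1, 10, 100)),
    RR = list(alpha = c(0, 0.01, 0.1, 1, 10, 100)),
    DTR = list(max_depth = 4:100, min_samples_split = seq(5, 50, 5)),
    RFR = list(n_estimators = seq(50, 150, 25), max_depth = 3:50,
               min_samples_split = seq(5, 50, 5)),
    XGBoost = list(max_depth = 3:25,
                   learning_rate = c(0.001, 0.005, 0.01, 0.05, 0.1),
                   n_estimators = seq(50, 150, 25)),
    LightGBM = list(num_leaves = seq(50, 150, 10),
                    learning_rate = c(0.001, 0.005, 0.01, 0.05, 0.1),
                    n_estimators = seq(50, 150, 25)))
}

#' Model specification
#'
#' @param model one of PR, PLSR, LR (lasso), RR (ridge), DTR, RFR, XGBoost,
#'   LightGBM.
#' @param grid hyperparameter grid (named list of vectors); defaults to
#'   [default_grid()]. Pass a reduced grid to trade search breadth for time.
#' @param seed integer seed for the stochastic learners.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model, grid = NULL, seed = 1) {
  model <- match.arg(model, c("PR", "PLSR", "LR", "RR", "DTR", "RFR",
                              "XGBoost", "LightGBM"))
  if (is.null(grid)) grid <- default_grid(model)
  structure(list(model = model, grid = grid, seed = seed),
            class = "model_spec")
}

# degree-2 polynomial expansion: columns, squares, pairwise interactions
.poly2 <- function(X) {
  X <- as.matrix(X)
  p <- ncol(X)
  out <- cbind(X, X^2)
  colnames(out) <- c(colnames(X), paste0(colnames(X), "^2"))
  if (p >= 2) {
    pairs <- utils::combn(p, 2)
    inter <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
    colnames(inter) <- paste0(colnames(X)[pairs[1, ]], ":",
                              colnames(X)[pairs[2, ]])
    out <- cbind(out, inter)
  }
  out
}

# pseudoinverse least squares; returns fitted coefficients (rank-deficient
# designs are solved in the minimum-norm sense with a conditioning warning)
.pinv_lm <- function(X, y) {
  Xi <- cbind(`(Intercept)` = 1, X)
  sv <- svd(Xi)
  tol <- max(dim(Xi)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  if (sum(pos) < length(sv$d))
    warning("rank-deficient polynomial design; minimum-norm solution used",
            call. = FALSE)
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  drop(coef)
}

# fit one model configuration on train, predict on test
.fit_predict <- function(model, X_tr, y_tr, X_te, params, seed) {
  X_tr <- as.matrix(X_tr); X_te <- as.matrix(X_te)
  if (is.null(colnames(X_tr)))
    colnames(X_tr) <- colnames(X_te) <- paste0("f", seq_len(ncol(X_tr)))
  switch(model,
    PR = {
      P_tr <- .poly2(X_tr); P_te <- .poly2(X_te)
      beta <- suppressWarnings(.pinv_lm(P_tr, y_tr))
      drop(cbind(1, P_te) %*% beta)
    },
    PLSR = {
      keep <- apply(X_tr, 2, stats::sd) > 0
      if (sum(keep) == 0) return(rep(mean(y_tr), nrow(X_te)))
      if (sum(keep) == 1) {
        # single-predictor PLS1 collapses to simple least squares
        xtr <- X_tr[, keep]; b <- stats::cov(xtr, y_tr) / stats::var(xtr)
        return(mean(y_tr) + b * (X_te[, keep] - mean(xtr)))
      }
      ncomp <- min(params$n_components, sum(keep))
      fit <- mixOmics::pls(X_tr[, keep, drop = FALSE], y_tr,
                           ncomp = ncomp, mode = "regression")
      pr <- stats::predict(fit, X_te[, keep, drop = FALSE])$predict
      drop(pr[, 1, ncomp])
    },
    LR = ,
    RR = {
      a <- if (model == "LR") 1 else 0
      Xg_tr <- X_tr; Xg_te <- X_te
      if (ncol(Xg_tr) == 1) {  # glmnet requires >= 2 columns
        Xg_tr <- cbind(Xg_tr, .const = 0)
        Xg_te <- cbind(Xg_te, .const = 0)
      }
      fit <- glmnet::glmnet(Xg_tr, y_tr, alpha = a, lambda = params$alpha)
      drop(stats::predict(fit, Xg_te, s = params$alpha))
    },
    DTR = {
      df_tr <- data.frame(y = y_tr, X_tr, check.names = FALSE)
      fit <- rpart::rpart(y ~ ., data = df_tr, method = "anova",
                          control = rpart::rpart.control(
                            maxdepth = min(30, params$max_depth),
                            minsplit = params$min_samples_split,
                            cp = 0, xval = 0))
      unname(stats::predict(fit, data.frame(X_te, check.names = FALSE)))
    },
    RFR = {
      fit <- ranger::ranger(y = y_tr, x = data.frame(X_tr, check.names = FALSE),
                            num.trees = params$n_estimators,
                            max.depth = params$max_depth,
                            min.node.size = params$min_samples_split,
                            seed = seed, num.threads = 1)
      stats::predict(fit, data.frame(X_te, check.names = FALSE),
                     num.threads = 1)$predictions
    },
    XGBoost = {
      set.seed(seed)
      fit <- xgboost::xgb.train(
        params = list(max_depth = params$max_depth, eta = params$learning_rate,
                      objective = "reg:squarederror", nthread = 1,
                      seed = seed),
        data = xgboost::xgb.DMatrix(X_tr, label = y_tr),
        nrounds = params$n_estimators, verbose = 0)
      stats::predict(fit, xgboost::xgb.DMatrix(X_te))
    },
    LightGBM = {
      # leaf-wise histogram gradient boosting (LightGBM growth strategy)
      set.seed(seed)
      fit <- xgboost::xgb.train(
        params = list(tree_method = "hist", grow_policy = "lossguide",
                      max_leaves = params$num_leaves, max_depth = 0,
                      eta = params$learning_rate,
                      objective = "reg:squarederror", nthread = 1,
                      seed = seed),
        data = xgboost::xgb.DMatrix(X_tr, label = y_tr),
        nrounds = params$n_estimators, verbose = 0)
      stats::predict(fit, xgboost::xgb.DMatrix(X_te))
    })
}

# expand a grid list into a data frame of configurations; resolve the PLSR
# component range and deduplicate DTR depths capped at rpart's limit
.expand_grid <- function(spec, n_features) {
  g <- spec$grid
  if (spec$model == "PR" || length(g) == 0)
    return(data.frame(.config = 1))
  if (spec$model == "PLSR") {
    if (length(g$n_components) == 1 && is.na(g$n_components))
      g$n_components <- if (n_features >= 2) 2:n_features else 1
  }
  if (spec$model == "DTR" && !is.null(g$max_depth))
    g$max_depth <- unique(pmin(30, g$max_depth))
  expand.grid(g, KEEP.OUT.ATTRS = FALSE)
}

#' Grid-search cross-validated model fit
#'
#' Exhaustive search over the specification's hyperparameter grid with k-fold
#' cross-validation (shuffled, seeded, unstratified folds). The selection
#' criterion is the mean cross-validated R2; reported metrics are the fold
#' means for the winning configuration. Grid entries infeasible for the data
#' (e.g. more PLSR components than features) are skipped and logged.
#'
#' @param features data frame or matrix of predictors.
#' @param y numeric target.
#' @param spec a [model_spec()].
#' @param cv_folds fold count (default 3).
#' @param seed integer fold-assignment seed.
#' @return list with `model`, `best_params`, `cv_metrics` (mean R2/RMSE/MAE),
#'   `fold_metrics`, `folds`, `oof_predictions` (out-of-fold predictions of
#'   the winning configuration), `skipped`.
#' @export
fit_model <- function(features, y, spec, cv_folds = 3, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.data.frame(features)
  n <- length(y)
  stopifnot(nrow(X) == n, n >= 3 * cv_folds)
  set.seed(seed)
  folds <- sample(rep(seq_len(cv_folds), length.out = n))
  grid <- .expand_grid(spec, ncol(X))
  results <- vector("list", nrow(grid))
  skipped <- character(0)
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    fm <- matrix(NA_real_, cv_folds, 3,
                 dimnames = list(NULL, c("R2", "RMSE", "MAE")))
    ok <- TRUE
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      pred <- tryCatch(
        .fit_predict(spec$model, X[tr, , drop = FALSE], y[tr],
                     X[!tr, , drop = FALSE], params, seed = spec$seed),
        error = function(e) e)
      if (inherits(pred, "error")) {
        skipped <- c(skipped, sprintf("%s: %s",
                                      paste(names(params), unlist(params),
                                            sep = "=", collapse = ","),
                                      conditionMessage(pred)))
        ok <- FALSE
        break
      }
      m <- eval_metrics(y[!tr], pred)
      fm[f, ] <- c(m$R2, m$RMSE, m$MAE)
    }
    if (ok) results[[gi]] <- fm
  }
  scores <- vapply(results, function(fm)
    if (is.null(fm)) -Inf else mean(fm[, "R2"]), numeric(1))
  if (all(scores == -Inf)) stop("no feasible grid entry for ", spec$model)
  best <- which.max(scores)
  fm <- results[[best]]
  best_params <- as.list(grid[best, , drop = FALSE])
  oof <- rep(NA_real_, n)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    oof[!tr] <- .fit_predict(spec$model, X[tr, , drop = FALSE], y[tr],
                             X[!tr, , drop = FALSE], best_params,
                             seed = spec$seed)
  }
  list(model = spec$model,
       best_params = best_params,
       cv_metrics = list(R2 = mean(fm[, "R2"]), RMSE = mean(fm[, "RMSE"]),
                         MAE = mean(fm[, "MAE"])),
       fold_metrics = fm,
       folds = folds,
       oof_predictions = oof,
       skipped = skipped)
}

#' Incremental-feature accuracy curve
#'
#' Refits the model with the top-k ranked features for k = 1..K (full grid
#' search at every k) and records the cross-validated metrics, reproducing the
#' accuracy-vs-feature-count curves used to study how accuracy grows as ranked
#' variables are added.
#'
#' @param table data frame of features.
#' @param y numeric target.
#' @param ranking a `ranking_result` from [rank_features()] covering the
#'   table's features.
#' @param spec a [model_spec()].
#' @param cv_folds,seed passed to [fit_model()].
#' @param k_max optional cap on the feature count (default: all ranked
#'   features).
#' @return an `accuracy_curve` data frame: `k`, `feature_added`, `R2`,
#'   `RMSE`, `MAE`, `params` (JSON), with attributes `model` and `method`.
#' @export
incremental_sweep <- function(table, y, ranking, spec, cv_folds = 3, seed = 1,
                              k_max = NULL) {
  X <- as.data.frame(table)
  feats <- ranking$feature
  stopifnot(all(feats %in% names(X)))
  K <- if (is.null(k_max)) length(feats) else min(k_max, length(feats))
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    fit <- fit_model(X[, feats[seq_len(k)], drop = FALSE], y, spec,
                     cv_folds = cv_folds, seed = seed)
    rows[[k]] <- data.frame(
      k = k, feature_added = feats[k],
      R2 = fit$cv_metrics$R2, RMSE = fit$cv_metrics$RMSE,
      MAE = fit$cv_metrics$MAE,
      params = as.character(jsonlite::toJSON(fit$best_params,
                                             auto_unbox = TRUE)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "model") <- spec$model
  attr(out, "method") <- ranking$method[1]
  class(out) <- c("accuracy_curve", "data.frame")
  out
}

#' Parsimony threshold from a best accuracy
#'
#' The reduced-variable criterion: 95 percent (by default) of the best
#' cross-validated R2.
#' @param best_r2 best accuracy.
#' @param fraction threshold fraction (default 0.95).
#' @return numeric threshold.
#' @export
parsimony_threshold <- function(best_r2, fraction = 0.95) fraction * best_r2

#' Parsimonious feature-count selection
#'
#' Takes the best accuracy on an accuracy curve as reference, sets
#' `fraction` x best as the threshold, and returns the smallest feature count
#' whose R2 meets it.
#'
#' @param curve an `accuracy_curve` (or data frame with columns `k`, `R2`).
#' @param fraction threshold fraction (default 0.95).
#' @return list with `n_best`, `best_R2`, `threshold`, `n_reduced`,
#'   `reduced_R2`.
#' @export
parsimony_select <- function(curve, fraction = 0.95) {
  stopifnot(nrow(curve) >= 1, all(c("k", "R2") %in% names(curve)))
  best_i <- which.max(curve$R2)
  best_r2 <- curve$R2[best_i]
  thr <- parsimony_threshold(best_r2, fraction)
  red_i <- which(curve$R2 >= thr)[1]
  # a non-positive best accuracy makes the fractional threshold ill-defined;
  # no reduction is attempted in that case
  if (is.na(red_i)) red_i <- best_i
  list(n_best = curve$k[best_i], best_R2 = best_r2, threshold = thr,
       n_reduced = curve$k[red_i], reduced_R2 = curve$R2[red_i])
}

#' Family comparison and variable-reduction summary
#'
#' Operates on a best-combination summary table (one row per parameter x
#' index family with columns `parameter`, `family`, `best_R2`, `n_best`,
#' `n_reduced`): for each parameter it reports the multispectral-minus-colour
#' best-accuracy difference and, for each row, the variable reduction
#' `n_best - n_reduced`.
#'
#' @param summary_df the summary table.
#' @return list with `family_gain` (data frame `parameter`, `gain`) and
#'   `reduction` (input rows plus `n_removed`).
#' @export
compare_families <- function(summary_df) {
  stopifnot(all(c("parameter", "family", "best_R2") %in% names(summary_df)))
  params <- unique(summary_df$parameter)
  gain <- data.frame(parameter = params, gain = NA_real_)
  for (i in seq_along(params)) {
    s <- summary_df[summary_df$parameter == params[i], ]
    mi <- s$best_R2[s$family == "MI"]; ci <- s$best_R2[s$family == "CI"]
    if (length(mi) == 1 && length(ci) == 1) gain$gain[i] <- mi - ci
  }
  red <- summary_df
  if (all(c("n_best", "n_reduced") %in% names(summary_df)))
    red$n_removed <- summary_df$n_best - summary_df$n_reduced
  list(family_gain = gain, reduction = red)
}
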