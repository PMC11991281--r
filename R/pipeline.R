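#' Season from calendar month
#'
#' Northern-hemisphere meteorological seasons: Mar-May spring, Jun-Aug
#' summer, Sep-Nov autumn, Dec-Feb winter.
#' @param month integer 1..12 (vectorised).
#' @return character season.
#' @export
derive_season <- function(month) {
  stopifnot(all(month %in% 1:12))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "autumn", "autumn", "autumn", "winter")[month]
}

#' Pipeline run configuration
#'
#' @param out_dir output directory for CSV tables and the JSON manifest.
#' @param seed global seed; every stage derives its seeds from it.
#' @param n_sites,n_dsz_per_site,months synthetic survey layout (sites cycle
#'   through elevation classes and farming methods).
#' @param size_px scene size in pixels.
#' @param family scene band family.
#' @param truth planted forward model (default [default_truth_model()]).
#' @param ranking_methods subset of PCA/MRMR/GRA.
#' @param model,model_grid regressor for the incremental sweep and its grid
#'   (`NULL` = the model's full default grid).
#' @param cv_folds,k_max,parsimony_fraction sweep settings.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("teacanopy_run_"),
                            seed = 1, n_sites = 3, n_dsz_per_site = 4,
                            months = c(2, 5, 8, 11), size_px = c(64, 64),
                            family = "multispectral",
                            truth = default_truth_model(),
                            ranking_methods = c("PCA", "MRMR", "GRA"),
                            model = "XGBoost",
                            model_grid = list(max_depth = c(3, 6),
                                              learning_rate = c(0.05, 0.1),
                                              n_estimators = 100),
                            cv_folds = 3, k_max = 8,
                            parsimony_fraction = 0.95) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Wires the stages end to end: simulate scenes, segment the canopy, compute
#' index features, generate physiology from the planted truth model, rank
#' features, sweep the regressor over incrementally added features, apply the
#' parsimony rule, and emit field-style statistics. Every output table is
#' written to `config$out_dir` together with a JSON manifest carrying the
#' configuration hash and seed; reruns with the same configuration are
#' byte-identical for the deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the DSZ table, rankings, curves, parsimony
#'   selections, statistics, and file paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  elevs <- rep_len(c("low", "mid", "high"), config$n_sites)
  fms <- rep_len(c("CFM", "AFM"), config$n_sites)
  registry <- index_definitions(if (config$family == "rgb") "CI" else "MI")

  # stage 1-2: simulate + segment + features
  rows <- list()
  dsz_i <- 0
  for (s in seq_len(config$n_sites)) for (d in seq_len(config$n_dsz_per_site))
    for (mo in config$months) {
      dsz_i <- dsz_i + 1
      sc_seed <- config$seed * 10000 + dsz_i
      set.seed(sc_seed)
      cf <- stats::runif(1, 0.45, 0.75)
      vig <- stats::runif(1)
      scene <- generate_scene(cf, vigor_spectra(vig, config$family),
                              size_px = config$size_px, seed = sc_seed,
                              family = config$family)
      mask <- segment_canopy(scene,
                             segmentation_config(seed = sc_seed))
      fv <- compute_feature_vector(scene, mask, registry)
      rows[[dsz_i]] <- data.frame(
        site_id = sprintf("site%02d", s),
        elevation_class = elevs[s], farming_method = fms[s],
        month = mo, season = derive_season(mo),
        canopy_fraction = cf, vigor = vig,
        mask_iou = iou(mask, scene$truth_mask),
        t(fv), check.names = FALSE, stringsAsFactors = FALSE)
    }
  feats <- do.call(rbind, rows)

  # stage 3: physiology from the planted model
  feat_cols <- registry$name
  phys <- generate_physiology(feats[, feat_cols, drop = FALSE], config$truth,
                              nrow(feats), seed = config$seed + 1)
  dsz <- cbind(feats[, setdiff(names(feats), feat_cols), drop = FALSE],
               phys[, names(config$truth$coef), drop = FALSE],
               feats[, feat_cols, drop = FALSE])
  utils::write.csv(dsz, file.path(config$out_dir, "dsz_table.csv"),
                   row.names = FALSE)

  # stage 4: ranking (against the first truth parameter)
  target <- names(config$truth$coef)[1]
  y <- dsz[[target]]
  X <- dsz[, feat_cols, drop = FALSE]
  X <- X[, vapply(X, function(v) !anyNA(v) && stats::sd(v) > 0, TRUE),
         drop = FALSE]
  rankings <- lapply(config$ranking_methods, function(m)
    rank_features(X, y, m))
  names(rankings) <- config$ranking_methods
  rank_tab <- do.call(rbind, rankings)
  utils::write.csv(rank_tab, file.path(config$out_dir, "rankings.csv"),
                   row.names = FALSE)

  # stage 5: incremental sweep + parsimony
  spec <- model_spec(config$model, grid = config$model_grid,
                     seed = config$seed)
  curves <- lapply(rankings, function(rk)
    incremental_sweep(X, y, rk, spec, cv_folds = config$cv_folds,
                      seed = config$seed, k_max = config$k_max))
  curve_tab <- do.call(rbind, Map(function(cv, m)
    cbind(method = m, as.data.frame(cv)), curves, names(curves)))
  utils::write.csv(curve_tab, file.path(config$out_dir, "accuracy_curves.csv"),
                   row.names = FALSE)
  pars <- lapply(curves, parsimony_select, fraction = config$parsimony_fraction)
  pars_tab <- do.call(rbind, Map(function(p, m)
    data.frame(method = m, n_best = p$n_best, best_R2 = p$best_R2,
               threshold = p$threshold, n_reduced = p$n_reduced,
               reduced_R2 = p$reduced_R2), pars, names(pars)))
  utils::write.csv(pars_tab, file.path(config$out_dir, "parsimony.csv"),
                   row.names = FALSE)

  # stage 6: field statistics + grouped errors of the best ranking's model
  desc <- do.call(rbind, lapply(names(config$truth$coef), function(p)
    describe_physiology(dsz, p)))
  utils::write.csv(desc, file.path(config$out_dir, "descriptives.csv"),
                   row.names = FALSE)
  best_m <- names(which.max(vapply(pars, `[[`, numeric(1), "best_R2")))
  k_star <- pars[[best_m]]$n_reduced
  fit <- fit_model(X[, rankings[[best_m]]$feature[seq_len(k_star)],
                     drop = FALSE],
                   y, spec, cv_folds = config$cv_folds, seed = config$seed)
  res <- cbind(dsz[c("elevation_class", "season", "farming_method")],
               residual = fit$oof_predictions - y)
  err_tab <- grouped_error_report(res)
  utils::write.csv(err_tab, file.path(config$out_dir, "grouped_errors.csv"),
                   row.names = FALSE)

  cfg_for_hash <- config[setdiff(names(config), c("out_dir", "truth"))]
  tf <- tempfile()
  writeLines(jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, force = TRUE), tf)
  manifest <- list(config_hash = unname(tools::md5sum(tf)), seed = config$seed,
                   n_dsz = nrow(dsz), target = target, model = config$model,
                   best_ranking = best_m,
                   mean_mask_iou = mean(dsz$mask_iou))
  unlink(tf)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(config$out_dir, "manifest.json"))
  invisible(list(dsz = dsz, rankings = rankings, curves = curves,
                 parsimony = pars, descriptives = desc,
                 grouped_errors = err_tab, manifest = manifest,
                 out_dir = config$out_dir))
}

#' Published field-campaign summary statistics
#'
#' Descriptive statistics (count, min, mean, max, sample sd and printed CV)
#' for LAI, PRI and PhiPSII under conventional (CFM) and agroecological (AFM)
#' management, as released with the field campaign this package emulates.
#' Used as reference envelopes for the synthetic generator and as input to
#' the summary-audit operations.
#'
#' @return data frame with columns `parameter`, `farming_method`, `Number`,
#'   `Min`, `Mean`, `Max`, `StDev`, `CV_printed`.
#' @export
field_summary_stats <- function() {
  utils::read.csv(system.file("extdata", "field_summary_stats.csv",
                              package = "teacanopy"),
                  stringsAsFactors = FALSE)
}

#' Published best-combination model summary
#'
#' Best cross-validated accuracy, the winning model, and the
#' feature counts at best and at the 95-percent parsimony threshold for each
#' physiological parameter and index family, as released with the field
#' campaign this package emulates.
#'
#' @return data frame with columns `parameter`, `family`, `ranking`, `model`,
#'   `best_R2`, `reduced_R2`, `n_best`, `n_reduced`.
#' @export
model_summary <- function() {
  utils::read.csv(system.file("extdata", "model_summary.csv",
                              package = "teacanopy"),
                  stringsAsFactors = FALSE)
}
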