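#' Segmentation configuration
#'
#' Settings for the superpixel canopy workflow. Defaults are resolved against
#' the scene at segmentation time: RGB scenes use the RGBVI and VARI indices
#' with SLIC compactness 20 (Lab colour space); multispectral scenes use EVI
#' and RVI with compactness 0.05 (raw reflectance space). The default
#' superpixel count is one per 400 pixels (about 16 cm patches at 0.8 cm/px).
#'
#' @param n_superpixels target number of superpixels (`NULL` = pixels / 400).
#' @param compactness SLIC compactness factor (`NULL` = family default).
#' @param seg_indices character vector of registry index names used for
#'   thresholding (`NULL` = family default).
#' @param lower_limit,upper_limit optional named numeric vectors (per
#'   seg_index) restricting the canopy class to a mean-value window.
#' @param manual_overrides optional named vector/list mapping superpixel label
#'   to class (1 canopy, 0 background), applied after thresholding.
#' @param n_iter SLIC iterations.
#' @param seed integer, recorded in the run manifest.
#' @return object of class `seg_config`.
#' @export
segmentation_config <- function(n_superpixels = NULL, compactness = NULL,
                                seg_indices = NULL, lower_limit = NULL,
                                upper_limit = NULL, manual_overrides = NULL,
                                n_iter = 10, seed = 1) {
  if (!is.null(seg_indices)) stopifnot(length(seg_indices) >= 1)
  if (!is.null(lower_limit) && !is.null(upper_limit)) {
    common <- intersect(names(lower_limit), names(upper_limit))
    if (any(lower_limit[common] >= upper_limit[common]))
      stop("lower_limit must be < upper_limit for every index")
  }
  structure(list(n_superpixels = n_superpixels, compactness = compactness,
                 seg_indices = seg_indices, lower_limit = lower_limit,
                 upper_limit = upper_limit, manual_overrides = manual_overrides,
                 n_iter = n_iter, seed = seed),
            class = "seg_config")
}

.resolve_config <- function(scene, config) {
  if (is.null(config)) config <- segmentation_config()
  npx <- prod(dim(scene))
  if (is.null(config$n_superpixels))
    config$n_superpixels <- max(2L, floor(npx / 400))
  if (is.null(config$compactness))
    config$compactness <- if (scene$family == "rgb") 20 else 0.05
  if (is.null(config$seg_indices))
    config$seg_indices <- if (scene$family == "rgb")
      c("RGBVI", "VARI") else c("EVI", "RVI")
  config
}

# pixel feature space for SLIC: Lab for RGB (sRGB -> Lab), raw reflectance
# stack for multispectral
.slic_features <- function(scene) {
  if (scene$family == "rgb") {
    rgb <- cbind(as.vector(scene$bands$R), as.vector(scene$bands$G),
                 as.vector(scene$bands$B)) / 255
    grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  } else {
    do.call(cbind, lapply(scene$bands, as.vector))
  }
}

# connectivity postprocessing: connected components of each label are found;
# components at least min_size pixels become superpixels in their own right,
# while smaller fragments are absorbed into the adjacent region whose mean
# pixel feature is closest (ties broken by region size)
.enforce_connectivity <- function(labels, feats, min_size) {
  nr <- nrow(labels); nc <- ncol(labels)
  comp <- matrix(seq_along(labels), nr, nc)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  same_mask <- lapply(shifts, function(sh) {
    shl <- .shift_mat(labels, sh[1], sh[2])
    !is.na(shl) & shl == labels
  })
  repeat {
    old <- comp
    for (si in seq_along(shifts)) {
      sh <- shifts[[si]]
      shc <- .shift_mat(comp, sh[1], sh[2])
      ok <- same_mask[[si]]
      comp[ok] <- pmin(comp[ok], shc[ok])
    }
    if (identical(old, comp)) break
  }
  comp_id <- match(comp, sort(unique(as.vector(comp))))
  ncomp <- max(comp_id)
  sizes <- tabulate(comp_id, ncomp)
  means <- rowsum(feats, comp_id) / sizes
  # adjacency between components (4-neighbourhood)
  cid <- matrix(comp_id, nr, nc)
  pairs <- rbind(cbind(as.vector(cid[-1, ]), as.vector(cid[-nr, ])),
                 cbind(as.vector(cid[, -1]), as.vector(cid[, -nc])))
  pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  adj <- lapply(seq_len(ncomp), function(i)
    unique(c(pairs[pairs[, 1] == i, 2], pairs[pairs[, 2] == i, 1])))
  map <- seq_len(ncomp)
  resolve <- function(i) { while (map[i] != i) i <- map[i]; i }
  small <- which(sizes < min_size)
  for (sc_ in small[order(sizes[small])]) {
    nb <- unique(vapply(adj[[sc_]], resolve, integer(1)))
    nb <- setdiff(nb, sc_)
    if (length(nb) == 0) next
    d <- rowSums((means[nb, , drop = FALSE] -
                  matrix(means[sc_, ], length(nb), ncol(means),
                         byrow = TRUE))^2)
    tgt <- nb[order(d, -sizes[nb])][1]
    map[sc_] <- tgt
    means[tgt, ] <- (means[tgt, ] * sizes[tgt] + means[sc_, ] * sizes[sc_]) /
      (sizes[tgt] + sizes[sc_])
    sizes[tgt] <- sizes[tgt] + sizes[sc_]
    adj[[tgt]] <- unique(c(adj[[tgt]], adj[[sc_]]))
  }
  final <- vapply(comp_id, resolve, integer(1))
  matrix(final, nr, nc)
}

.shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

#' SLIC superpixel segmentation
#'
#' Local k-means over colour + spatial coordinates. Cluster centres start on a
#' regular grid with spacing `S = sqrt(pixels / k)`; each iteration assigns
#' pixels within a 2S x 2S window of each centre by the normalised distance
#' `sqrt((d_colour / compactness)^2 + (d_space / S)^2)` and recomputes
#' centres. Smaller compactness values give colour more weight, so the
#' 0.05 multispectral default is read on the reflectance scale and the 20
#' RGB default on the Lab scale.
#' Connectivity is enforced afterwards: fragments detached from their
#' superpixel's main body are merged into adjacent superpixels. The algorithm
#' is deterministic for a given scene and configuration.
#'
#' @param scene a [tea_scene()] of at least 16 x 16 pixels.
#' @param config a [segmentation_config()]; `NULL` for defaults.
#' @return object of class `superpixel_map`: list with `labels` (integer
#'   matrix, labels 1..K), `sizes` (pixel count per label), and `index_means`
#'   (matrix of per-label means, one column per seg index).
#' @export
slic_segment <- function(scene, config = NULL) {
  stopifnot(inherits(scene, "tea_scene"), all(dim(scene) >= 16))
  config <- .resolve_config(scene, config)
  nr <- dim(scene)[1]; nc <- dim(scene)[2]; npx <- nr * nc
  k <- config$n_superpixels
  if (k < 2 || k > npx) stop("n_superpixels must be in [2, pixel count]")
  feats <- .slic_features(scene)
  S <- sqrt(npx / k)
  gr <- max(1L, round(nr / S)); gc <- max(1L, ceiling(k / gr))
  cr <- (seq_len(gr) - 0.5) * nr / gr
  cc <- (seq_len(gc) - 0.5) * nc / gc
  centers_xy <- as.matrix(expand.grid(r = cr, c = cc))[seq_len(min(k, gr * gc)), , drop = FALSE]
  kk <- nrow(centers_xy)
  px_r <- rep(seq_len(nr), times = nc)
  px_c <- rep(seq_len(nc), each = nr)
  idx_at <- function(r, c) (c - 1L) * nr + r
  centers_f <- feats[idx_at(round(centers_xy[, 1]), round(centers_xy[, 2])), , drop = FALSE]
  m <- config$compactness
  label <- integer(npx)
  for (it in seq_len(config$n_iter)) {
    dist <- rep(Inf, npx)
    for (j in seq_len(kk)) {
      r0 <- max(1L, floor(centers_xy[j, 1] - S)); r1 <- min(nr, ceiling(centers_xy[j, 1] + S))
      c0 <- max(1L, floor(centers_xy[j, 2] - S)); c1 <- min(nc, ceiling(centers_xy[j, 2] + S))
      rows <- r0:r1; cols <- c0:c1
      id <- as.vector(outer(rows, (cols - 1L) * nr, `+`))
      dc2 <- rowSums((feats[id, , drop = FALSE] -
                      matrix(centers_f[j, ], length(id), ncol(feats), byrow = TRUE))^2)
      ds2 <- (px_r[id] - centers_xy[j, 1])^2 + (px_c[id] - centers_xy[j, 2])^2
      D <- dc2 / m^2 + ds2 / S^2
      upd <- D < dist[id]
      dist[id[upd]] <- D[upd]
      label[id[upd]] <- j
    }
    # unassigned pixels (outside every window) go to the nearest centre
    un <- which(label == 0L)
    if (length(un) > 0) {
      d2 <- outer(px_r[un], centers_xy[, 1], `-`)^2 +
            outer(px_c[un], centers_xy[, 2], `-`)^2
      label[un] <- max.col(-d2)
    }
    for (j in seq_len(kk)) {
      sel <- label == j
      if (!any(sel)) next
      centers_xy[j, ] <- c(mean(px_r[sel]), mean(px_c[sel]))
      centers_f[j, ] <- colMeans(feats[sel, , drop = FALSE])
    }
  }
  labels <- .enforce_connectivity(matrix(label, nr, nc), feats,
                                  min_size = npx / kk / 4)
  labels <- matrix(match(labels, sort(unique(as.vector(labels)))), nr, nc)
  sizes <- tabulate(labels)
  means <- vapply(config$seg_indices, function(ix) {
    map <- compute_index_map(scene, ix)
    as.numeric(tapply(as.vector(map), as.vector(labels),
                      function(v) mean(v, na.rm = TRUE)))
  }, numeric(max(labels)))
  means <- matrix(means, ncol = length(config$seg_indices),
                  dimnames = list(NULL, config$seg_indices))
  structure(list(labels = labels, sizes = sizes, index_means = means,
                 config = config),
            class = "superpixel_map")
}

#' Otsu threshold of a value vector
#'
#' Returns the threshold maximising the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. For inputs with up to 1000 distinct values
#' (the superpixel-mean regime this workflow thresholds) the search is exact
#' over the midpoints between consecutive sorted distinct values; larger
#' (pixel-scale) inputs are binned into a histogram first. Ties are resolved
#' by the mean of all maximising candidate thresholds.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param bins histogram bin count for large inputs.
#' @return scalar threshold; values > threshold form the upper class.
#' @export
otsu_threshold <- function(values, bins = 256) {
  values <- values[!is.na(values)]
  u <- sort(unique(values))
  if (length(u) < 2)
    stop("degenerate input: Otsu threshold requires >= 2 distinct values")
  if (length(u) <= 1000) {
    h <- tabulate(match(values, u))
    cand <- (u[-1] + u[-length(u)]) / 2
    v <- u
  } else {
    rng <- range(values)
    edges <- seq(rng[1], rng[2], length.out = bins + 1)
    h <- tabulate(findInterval(values, edges, rightmost.closed = TRUE), bins)
    v <- (edges[-1] + edges[-(bins + 1)]) / 2
    cand <- edges[2:bins]
    keep <- h > 0
    # collapse empty bins so candidates always split two non-empty classes
    v <- v[keep]; h <- h[keep]
    cand <- (v[-1] + v[-length(v)]) / 2
  }
  k <- length(v)
  w <- cumsum(h)
  mu <- cumsum(h * v)
  n <- w[k]; mu_t <- mu[k]
  w0 <- w[-k] / n
  w1 <- 1 - w0
  mu0 <- mu[-k] / w[-k]
  mu1 <- (mu_t - mu[-k]) / (n - w[-k])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  best <- which(bcv == max(bcv))
  mean(cand[best])
}

#' Classify superpixels into canopy and background
#'
#' A superpixel is canopy iff, for every segmentation index, its mean exceeds
#' that index's Otsu threshold and lies within the configured
#' `[lower_limit, upper_limit]` window (where set). Manual overrides are
#' applied last and logged in the `overrides` attribute.
#'
#' @param spx a `superpixel_map` from [slic_segment()].
#' @param config a [segmentation_config()] (thresholding settings are taken
#'   from here; defaults to the configuration stored in `spx`).
#' @return binary matrix mask (1 = canopy) with attributes `thresholds` and
#'   `overrides`.
#' @export
classify_canopy <- function(spx, config = NULL) {
  stopifnot(inherits(spx, "superpixel_map"))
  if (is.null(config)) config <- spx$config
  means <- spx$index_means
  idx <- colnames(means)
  canopy <- rep(TRUE, nrow(means))
  thresholds <- numeric(0)
  for (ix in idx) {
    thr <- otsu_threshold(means[, ix])
    thresholds[ix] <- thr
    pass <- means[, ix] > thr
    lo <- config$lower_limit[ix]; hi <- config$upper_limit[ix]
    if (!is.null(lo) && !is.na(lo)) pass <- pass & means[, ix] >= lo
    if (!is.null(hi) && !is.na(hi)) pass <- pass & means[, ix] <= hi
    canopy <- canopy & pass
  }
  ov <- config$manual_overrides
  if (!is.null(ov)) {
    labs <- as.integer(names(ov))
    if (any(is.na(labs)) || any(labs < 1 | labs > nrow(means)))
      stop("manual override references a nonexistent superpixel label")
    canopy[labs] <- as.logical(unlist(ov))
    message("classify_canopy: applied ", length(ov), " manual override(s)")
  }
  if (!any(canopy)) warning("classify_canopy: empty canopy mask")
  mask <- matrix(as.numeric(canopy[spx$labels]), nrow(spx$labels), ncol(spx$labels))
  attr(mask, "thresholds") <- thresholds
  attr(mask, "overrides") <- ov
  mask
}

#' End-to-end canopy segmentation
#'
#' SLIC superpixels, per-superpixel index means, Otsu thresholds with optional
#' dual limits and manual overrides. The returned mask carries a manifest
#' (configuration hash, seed, class pixel counts) so that runs sharing
#' hyperparameters across time periods are auditable.
#'
#' @inheritParams slic_segment
#' @return binary matrix mask with attribute `manifest`.
#' @export
segment_canopy <- function(scene, config = NULL) {
  config <- .resolve_config(scene, config)
  spx <- slic_segment(scene, config)
  mask <- classify_canopy(spx, config)
  cfg_json <- jsonlite::toJSON(config[!vapply(config, is.null, TRUE)],
                               auto_unbox = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(config_hash = unname(tools::md5sum(tf)),
                   seed = config$seed,
                   seg_indices = config$seg_indices,
                   compactness = config$compactness,
                   n_superpixels_requested = config$n_superpixels,
                   n_superpixels = length(spx$sizes),
                   canopy_px = sum(mask == 1),
                   background_px = sum(mask == 0))
  unlink(tf)
  attr(mask, "manifest") <- manifest
  attr(mask, "superpixels") <- spx
  mask
}

#' Intersection-over-union of two binary masks
#' @param a,b binary matrices of identical dimensions.
#' @return IoU in \[0, 1\] (1 when both masks are empty).
#' @export
iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  inter <- sum(a == 1 & b == 1)
  un <- sum(a == 1 | b == 1)
  if (un == 0) return(1)
  inter / un
}
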