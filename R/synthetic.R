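#' Default class spectra for synthetic scenes
#'
#' Band means and standard deviations for the canopy and background
#' (soil/weed) classes. The multispectral defaults give a strong
#' vegetation/soil NDVI contrast (canopy NIR 0.45 vs red 0.05; background NIR
#' 0.20 vs red 0.15); the RGB defaults make the canopy greener and darker
#' than the background.
#'
#' @param family `"multispectral"` or `"rgb"`.
#' @return list with `canopy` and `background`, each a list of `mean` and `sd`
#'   named by band.
#' @export
default_spectra <- function(family = c("multispectral", "rgb")) {
  family <- match.arg(family)
  if (family == "multispectral") {
    list(
      canopy = list(
        mean = c(blue = 0.04, green = 0.10, red = 0.05, red_edge = 0.28, nir = 0.45),
        sd   = c(blue = 0.01, green = 0.02, red = 0.01, red_edge = 0.03, nir = 0.04)),
      background = list(
        mean = c(blue = 0.08, green = 0.12, red = 0.15, red_edge = 0.18, nir = 0.20),
        sd   = c(blue = 0.01, green = 0.02, red = 0.02, red_edge = 0.02, nir = 0.03)))
  } else {
    list(
      canopy = list(
        mean = c(R = 55, G = 95, B = 45),
        sd   = c(R = 6, G = 8, B = 5)),
      background = list(
        mean = c(R = 135, G = 115, B = 95),
        sd   = c(R = 8, G = 8, B = 7)))
  }
}

# Grow a contiguous canopy mask by multi-source Eden-style wave growth:
# n_blobs seed pixels expand into their 4-neighbourhoods in random waves until
# the exact target pixel count is reached (the final wave is trimmed at
# random). Returns a binary matrix.
.grow_blobs <- function(size_px, target_n, n_blobs) {
  nr <- size_px[1]; nc <- size_px[2]; npx <- nr * nc
  mask <- logical(npx)
  seeds <- sample.int(npx, n_blobs)
  mask[seeds] <- TRUE
  neighbours <- function(idx) {
    r <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    out <- c(idx[r > 1L] - 1L, idx[r < nr] + 1L,
             idx[cc > 1L] - nr, idx[cc < nc] + nr)
    unique(out)
  }
  frontier <- setdiff(neighbours(seeds), seeds)
  n_on <- n_blobs
  while (n_on < target_n && length(frontier) > 0L) {
    # admit a random subset of the frontier each wave; roughens blob edges
    take <- frontier[stats::runif(length(frontier)) < 0.6]
    if (length(take) == 0L) take <- frontier[sample.int(length(frontier), 1L)]
    if (n_on + length(take) > target_n)
      take <- take[sample.int(length(take), target_n - n_on)]
    mask[take] <- TRUE
    n_on <- n_on + length(take)
    frontier <- setdiff(unique(c(frontier, neighbours(take))), which(mask))
  }
  .smooth_mask(matrix(as.numeric(mask), nr, nc), target_n)
}

# 3x3 majority smoothing followed by exact-count restoration: pixels are
# added at the best-supported boundary locations (most canopy neighbours)
# or removed at the least-supported ones until the target count is restored
.smooth_mask <- function(mask, target_n) {
  nr <- nrow(mask); nc <- ncol(mask)
  nb_sum <- function(m) {
    p <- matrix(0, nr + 2, nc + 2)
    p[2:(nr + 1), 2:(nc + 1)] <- m
    p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1)] + p[1:nr, 3:(nc + 2)] +
      p[2:(nr + 1), 1:nc] + p[2:(nr + 1), 3:(nc + 2)] +
      p[3:(nr + 2), 1:nc] + p[3:(nr + 2), 2:(nc + 1)] + p[3:(nr + 2), 3:(nc + 2)]
  }
  for (pass in 1:3) mask <- (nb_sum(mask) + 4 * mask >= 6) * 1
  repeat {
    diff_n <- sum(mask) - target_n
    if (diff_n == 0) break
    s <- nb_sum(mask)
    if (diff_n < 0) {
      cand <- which(mask == 0 & s > 0)
      cand <- cand[order(-s[cand], stats::runif(length(cand)))]
      mask[cand[seq_len(min(-diff_n, length(cand)))]] <- 1
    } else {
      cand <- which(mask == 1)
      cand <- cand[order(s[cand], stats::runif(length(cand)))]
      mask[cand[seq_len(diff_n)]] <- 0
    }
  }
  mask
}

#' Generate a synthetic DSZ scene with known canopy mask
#'
#' Builds a seeded plantation scene: contiguous canopy blobs grown from random
#' seed pixels over a soil/weed background, with per-class Gaussian band
#' reflectance. The returned scene carries the exact ground-truth mask, so
#' segmentation quality can be scored against it.
#'
#' @param canopy_fraction target canopy cover in (0, 1\]; the generated mask
#'   hits this fraction exactly (up to one pixel).
#' @param spectra_config per-class band means/sds as from [default_spectra()].
#' @param size_px integer vector `c(rows, cols)`, at least 32 x 32.
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @param family band family of the scene to generate.
#' @param n_blobs number of canopy seed points (plant crowns).
#' @param resolution_cm_per_px ground resolution.
#' @return a [tea_scene()] with `truth_mask`.
#' @export
generate_scene <- function(canopy_fraction, spectra_config = NULL,
                           size_px = c(128, 128), seed = 1,
                           family = c("multispectral", "rgb"),
                           n_blobs = 6, resolution_cm_per_px = 0.8) {
  family <- match.arg(family)
  stopifnot(canopy_fraction > 0, canopy_fraction <= 1,
            length(size_px) == 2, all(size_px >= 32))
  if (is.null(spectra_config)) spectra_config <- default_spectra(family)
  set.seed(seed)
  nr <- size_px[1]; nc <- size_px[2]; npx <- nr * nc
  target_n <- round(canopy_fraction * npx)
  mask <- if (target_n >= npx) matrix(1, nr, nc)
          else .grow_blobs(size_px, target_n, n_blobs)

  hi <- if (family == "rgb") 255 else 1
  mu_c <- spectra_config$canopy$mean; sd_c <- spectra_config$canopy$sd
  mu_b <- spectra_config$background$mean; sd_b <- spectra_config$background$sd
  # warn (not fail) if the classes are not separable in the contrast the
  # segmentation indices rely on: NIR - red (multispectral) or G - R (RGB)
  key <- if (family == "multispectral") c("nir", "red") else c("G", "R")
  gap <- abs((mu_c[[key[1]]] - mu_c[[key[2]]]) -
             (mu_b[[key[1]]] - mu_b[[key[2]]]))
  spread <- sqrt(sd_c[[key[1]]]^2 + sd_c[[key[2]]]^2) +
    sqrt(sd_b[[key[1]]]^2 + sd_b[[key[2]]]^2)
  if (gap < 2 * spread)
    warning("class spectra overlap in the ", paste(key, collapse = "-"),
            " contrast; segmentation indices may not be separable")
  bands <- lapply(names(mu_c), function(b) {
    v <- ifelse(mask == 1,
                stats::rnorm(npx, mu_c[[b]], sd_c[[b]]),
                stats::rnorm(npx, mu_b[[b]], sd_b[[b]]))
    matrix(pmin(pmax(v, 0), hi), nr, nc)
  })
  names(bands) <- names(mu_c)
  tea_scene(bands, resolution_cm_per_px, truth_mask = mask)
}

#' Class spectra for a given canopy vigor
#'
#' Linearly interpolates the canopy class between a low-vigor endpoint
#' (sparse, stressed foliage: low NIR, higher red) and a high-vigor endpoint
#' (dense healthy foliage: high NIR/red-edge, low red), leaving the
#' soil/weed background fixed. Scenes generated across a spread of vigor
#' values exhibit the between-plot reflectance variation that physiological
#' parameters track in the field.
#'
#' @param vigor canopy vigor in \[0, 1\].
#' @param family band family.
#' @return a spectra configuration as for [generate_scene()].
#' @export
vigor_spectra <- function(vigor, family = c("multispectral", "rgb")) {
  family <- match.arg(family)
  stopifnot(vigor >= 0, vigor <= 1)
  sp <- default_spectra(family)
  if (family == "multispectral") {
    lo <- c(blue = 0.055, green = 0.095, red = 0.10, red_edge = 0.20, nir = 0.25)
    hi <- c(blue = 0.035, green = 0.110, red = 0.04, red_edge = 0.30, nir = 0.50)
  } else {
    lo <- c(R = 80, G = 88, B = 55)
    hi <- c(R = 45, G = 100, B = 40)
  }
  sp$canopy$mean <- lo + vigor * (hi - lo)
  sp
}

#' Photochemical reflectance index from leaf reflectance
#'
#' PRI = (R531 - R570) / (R531 + R570), the normalised difference between
#' green reflectance at 531 nm (xanthophyll-cycle sensitive) and the 570 nm
#' reference. Bounded in \[-1, 1\].
#'
#' @param R531,R570 reflectance in (0, 1).
#' @return numeric PRI (vectorised).
#' @export
pri_from_reflectance <- function(R531, R570) {
  stopifnot(all(R531 > 0 & R531 < 1), all(R570 > 0 & R570 < 1))
  den <- R531 + R570
  if (any(den == 0)) stop("undefined PRI: R531 + R570 is zero")
  (R531 - R570) / den
}

#' Quantum yield of photosystem II from fluorescence
#'
#' PhiPSII = (Fm' - Fs) / Fm', the fraction of absorbed light used for PSII
#' photochemistry under ambient light: Fm' is the light-adapted maximum
#' fluorescence yield, Fs the steady-state yield. Bounded in \[0, 1\]; inputs
#' violating 0 <= Fs <= Fm' are an error, never clipped.
#'
#' @param Fm_prime maximum fluorescence yield under light (> 0).
#' @param Fs steady-state fluorescence yield (>= 0).
#' @return numeric PhiPSII (vectorised).
#' @export
phipsii_from_fluorescence <- function(Fm_prime, Fs) {
  if (any(Fm_prime <= 0)) stop("Fm_prime must be > 0")
  if (any(Fs < 0)) stop("Fs must be >= 0")
  if (any(Fs > Fm_prime)) stop("Fs exceeds Fm_prime; fluorescence yields inconsistent")
  (Fm_prime - Fs) / Fm_prime
}

#' Planted forward model linking indices to physiology
#'
#' A truth model maps named image indices to each physiological parameter via
#' an intercept, linear weights and an optional monotone saturating link
#' (`1 - exp(-rate * x)` applied to the first causal feature), plus additive
#' Gaussian noise. Generated values are clipped to physically plausible
#' envelopes (defaults follow field ranges: LAI 0.13-10.37, PRI -0.077-0.0766,
#' PhiPSII 0.0729-0.8648) and every clip event is logged.
#'
#' @param coef named list, one entry per parameter; each entry a named numeric
#'   vector whose first element is `intercept` and remaining names are feature
#'   names.
#' @param noise_sd named numeric, additive Gaussian sd per parameter (>= 0).
#'   Alternatively supply `snr` to calibrate noise from the planted signal.
#' @param nonlinearity named character, `"saturating"` or `NA` per parameter.
#' @param snr optional named numeric: target ratio sd(signal)/sd(noise); when
#'   set it overrides `noise_sd` at generation time.
#' @param ranges named list of length-2 numeric clip envelopes.
#' @return object of class `truth_model`.
#' @export
truth_model <- function(coef,
                        noise_sd = NULL,
                        nonlinearity = NULL,
                        snr = NULL,
                        ranges = list(LAI = c(0.13, 10.37),
                                      PRI = c(-0.077, 0.0766),
                                      PhiPSII = c(0.0729, 0.8648))) {
  stopifnot(is.list(coef), !is.null(names(coef)))
  for (p in names(coef))
    stopifnot(names(coef[[p]])[1] == "intercept")
  if (!is.null(noise_sd)) stopifnot(all(noise_sd >= 0))
  structure(list(coef = coef, noise_sd = noise_sd,
                 nonlinearity = nonlinearity, snr = snr, ranges = ranges),
            class = "truth_model")
}

#' Default truth model for the synthetic study
#'
#' LAI tracks NDVI (canopy density), PRI tracks the red-edge chlorophyll
#' index, and PhiPSII tracks GNDVI. Coefficients are scaled to the canopy
#' zonal-mean index ranges produced by [vigor_spectra()] scenes, so that
#' generated parameters span their field envelopes (to which they are
#' clipped, with logging).
#' @return a [truth_model()].
#' @export
default_truth_model <- function() {
  truth_model(
    coef = list(
      LAI = c(intercept = -5.5, NDVI = 16),
      PRI = c(intercept = -0.10, RECI = 0.20),
      PhiPSII = c(intercept = -0.55, GNDVI = 2.0)),
    noise_sd = c(LAI = 0.45, PRI = 0.006, PhiPSII = 0.045))
}

# planted signal (pre-noise) for one parameter given a feature table
.truth_signal <- function(truth, param, features) {
  cf <- truth$coef[[param]]
  feats <- names(cf)[-1]
  missing <- setdiff(feats, colnames(features))
  if (length(missing) > 0)
    stop("truth model references features absent from input: ",
         paste(missing, collapse = ", "))
  X <- as.matrix(features[, feats, drop = FALSE])
  nl <- if (!is.null(truth$nonlinearity)) truth$nonlinearity[[param]] else NA
  if (!is.na(nl) && nl == "saturating")
    X[, 1] <- 1 - exp(-3 * X[, 1])
  drop(cf[1] + X %*% cf[-1])
}

.clip_log <- function(x, range, param) {
  n_clip <- sum(x < range[1] | x > range[2])
  if (n_clip > 0)
    message(sprintf("truth model: clipped %d %s value(s) to [%g, %g]",
                    n_clip, param, range[1], range[2]))
  pmin(pmax(x, range[1]), range[2])
}

#' Generate per-DSZ physiological measurements from a planted model
#'
#' Applies the truth model to a table of per-DSZ feature values and emulates
#' the field protocol: PRI and PhiPSII are derived from 10 simulated leaf
#' readings per DSZ (reflectance pairs and fluorescence yields respectively),
#' averaged; LAI is a single canopy-level draw. With `noise_sd = 0` the
#' outputs equal the planted relation exactly.
#'
#' @param scene_features data frame of per-DSZ index values (one row per DSZ).
#' @param truth a [truth_model()].
#' @param n_dsz number of DSZs; must equal `nrow(scene_features)` and be >= 3.
#' @param seed integer seed.
#' @param n_readings leaf readings averaged per DSZ (field protocol: 10).
#' @return data frame of DSZ records: site metadata, LAI/PRI/PhiPSII (as
#'   present in the truth model) and the feature columns.
#' @export
generate_physiology <- function(scene_features, truth, n_dsz = nrow(scene_features),
                                seed = 1, n_readings = 10) {
  stopifnot(inherits(truth, "truth_model"))
  if (n_dsz < 3) stop("n_dsz must be >= 3 (minimum DSZ count per site)")
  stopifnot(n_dsz == nrow(scene_features))
  set.seed(seed)
  out <- data.frame(
    site_id = sprintf("S%02d", seq_len(n_dsz)),
    elevation_class = rep_len(c("low", "mid", "high"), n_dsz),
    farming_method = rep_len(c("CFM", "AFM"), n_dsz),
    season = rep_len(c("spring", "summer", "autumn", "winter"), n_dsz),
    stringsAsFactors = FALSE)
  for (param in names(truth$coef)) {
    mu <- .truth_signal(truth, param, scene_features)
    sdp <- if (!is.null(truth$noise_sd)) truth$noise_sd[[param]] else 0
    rng <- truth$ranges[[param]]
    if (param == "PRI") {
      # 10 leaf-clip readings: reflectance pair constructed per reading so the
      # forward formula returns the per-reading PRI, then averaged
      vals <- vapply(seq_len(n_dsz), function(i) {
        p_k <- .clip_log(mu[i] + stats::rnorm(n_readings, 0, sdp), c(-0.9, 0.9), "PRI reading")
        mean(pri_from_reflectance(0.05 * (1 + p_k), 0.05 * (1 - p_k)))
      }, numeric(1))
    } else if (param == "PhiPSII") {
      vals <- vapply(seq_len(n_dsz), function(i) {
        phi_k <- .clip_log(mu[i] + stats::rnorm(n_readings, 0, sdp), c(0, 1), "PhiPSII reading")
        fm <- 0.6
        mean(phipsii_from_fluorescence(fm, fm * (1 - phi_k)))
      }, numeric(1))
    } else {
      vals <- mu + if (sdp > 0) stats::rnorm(n_dsz, 0, sdp) else 0
    }
    if (!is.null(rng)) vals <- .clip_log(vals, rng, param)
    out[[param]] <- vals
  }
  cbind(out, scene_features)
}

#' Tabular synthetic fixture: planted effects plus noise features
#'
#' Bypasses imagery and generates a per-DSZ feature table directly: the causal
#' features named in the truth model carry planted effects on each parameter;
#' `n_noise_features` additional features are independent draws. The realised
#' truth (including any SNR-calibrated noise sd) is attached as attribute
#' `"truth"` for recovery tests.
#'
#' @param n_rows number of DSZs (>= 30).
#' @param n_noise_features count of independent nuisance features.
#' @param truth a [truth_model()]; when its `snr` field is set, `noise_sd` is
#'   derived at generation time as `sd(signal)/snr`.
#' @param seed integer seed.
#' @return data frame as from [generate_physiology()], with attribute `truth`.
#' @export
generate_feature_table <- function(n_rows, n_noise_features, truth = default_truth_model(),
                                   seed = 1) {
  if (n_rows < 30) stop("n_rows must be >= 30")
  set.seed(seed)
  causal <- unique(unlist(lapply(truth$coef, function(cf) names(cf)[-1])))
  feats <- as.data.frame(lapply(causal, function(f)
    stats::runif(n_rows, 0.05, 0.95)))
  names(feats) <- causal
  if (n_noise_features > 0) {
    noise <- as.data.frame(lapply(seq_len(n_noise_features), function(j)
      stats::runif(n_rows, 0.05, 0.95)))
    names(noise) <- sprintf("noise%02d", seq_len(n_noise_features))
    feats <- cbind(feats, noise)
  }
  if (!is.null(truth$snr)) {
    nsd <- vapply(names(truth$coef), function(p)
      stats::sd(.truth_signal(truth, p, feats)) / truth$snr[[p]], numeric(1))
    truth$noise_sd <- nsd
  }
  out <- generate_physiology(feats, truth, n_rows, seed = seed + 1)
  attr(out, "truth") <- truth
  out
}

#' Truth model for ranking/regression benchmarks
#'
#' Two causal features with a saturating + linear planted relation on a single
#' target (stored under `LAI`), noise calibrated to a target signal-to-noise
#' ratio (default 2), and no clipping so that recovery tests see the planted
#' relation unmodified.
#'
#' @param snr target sd(signal)/sd(noise).
#' @return a [truth_model()].
#' @export
fixture_truth <- function(snr = 2) {
  truth_model(
    coef = list(LAI = c(intercept = 1, NDVI = 6, NDRE = 2.5)),
    nonlinearity = c(LAI = "saturating"),
    snr = c(LAI = snr),
    ranges = list(LAI = NULL))
}
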