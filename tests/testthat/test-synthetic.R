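test_that("scene generation is seeded, hits the canopy fraction, and handles full cover", {
  a <- generate_scene(0.6, size_px = c(64, 64), seed = 7)
  b <- generate_scene(0.6, size_px = c(64, 64), seed = 7)
  expect_identical(a$bands, b$bands)
  expect_identical(a$truth_mask, b$truth_mask)

  big <- generate_scene(0.6, size_px = c(256, 256), seed = 11)
  expect_gte(mean(big$truth_mask), 0.55)
  expect_lte(mean(big$truth_mask), 0.65)

  full <- generate_scene(1.0, size_px = c(32, 32), seed = 1)
  expect_true(all(full$truth_mask == 1))
})

test_that("canopy blobs are contiguous regions, not pixel noise", {
  sc <- fx_scene()
  m <- sc$truth_mask
  # a blob-grown mask has far higher neighbour agreement than an iid mask
  agree <- mean(m[-1, ] == m[-nrow(m), ])
  p <- mean(m)
  iid_agree <- p^2 + (1 - p)^2
  expect_gt(agree, iid_agree + 0.2)
})

test_that("overlapping class spectra warn rather than fail", {
  sp <- default_spectra()
  sp$background$mean <- sp$canopy$mean
  expect_warning(generate_scene(0.5, sp, size_px = c(32, 32), seed = 1),
                 "separable")
})

test_that("scene invariants are validated", {
  sc <- fx_scene()
  expect_error(tea_scene(sc$bands[1:4]), "band names")
  bad <- sc$bands; bad$nir <- bad$nir[1:10, 1:10]
  expect_error(tea_scene(bad), "identical dimensions")
  bad <- sc$bands; bad$nir[1] <- 1.5
  expect_error(tea_scene(bad), "\\[0, 1\\]")
})

test_that("scene IO round-trips bands, mask, and metadata", {
  sc <- generate_scene(0.5, size_px = c(32, 32), seed = 3)
  d <- withr::local_tempdir()
  write_scene(sc, d)
  rt <- read_scene(d)
  expect_equal(rt$family, "multispectral")
  expect_equal(rt$resolution_cm_per_px, sc$resolution_cm_per_px)
  expect_identical(rt$truth_mask, sc$truth_mask)
  expect_lt(max(abs(rt$bands$nir - sc$bands$nir)), 1e-4)  # 16-bit storage
})

test_that("PRI forward formula matches the reflectance contrast", {
  expect_equal(pri_from_reflectance(0.05, 0.05), 0)
  expect_equal(pri_from_reflectance(0.06, 0.04), 0.2)
  expect_equal(pri_from_reflectance(0.04, 0.06), -0.2)
  expect_error(pri_from_reflectance(0, 0.5))
})

test_that("PhiPSII forward formula respects fluorescence bounds", {
  expect_equal(phipsii_from_fluorescence(0.6, 0.3), 0.5)
  expect_equal(phipsii_from_fluorescence(0.7, 0.7), 0)
  expect_equal(phipsii_from_fluorescence(0.7, 0), 1)
  expect_error(phipsii_from_fluorescence(0, 0), "Fm_prime")
  expect_error(phipsii_from_fluorescence(0.5, 0.6), "exceeds")
})

test_that("noiseless physiology equals the planted relation exactly", {
  truth <- truth_model(
    coef = list(LAI = c(intercept = 2, NDVI = 5),
                PRI = c(intercept = -0.02, NDVI = 0.05),
                PhiPSII = c(intercept = 0.2, NDVI = 0.4)),
    noise_sd = c(LAI = 0, PRI = 0, PhiPSII = 0),
    ranges = list(LAI = NULL, PRI = NULL, PhiPSII = NULL))
  feats <- data.frame(NDVI = c(0.2, 0.5, 0.8))
  rec <- generate_physiology(feats, truth, seed = 1)
  expect_equal(rec$LAI, 2 + 5 * feats$NDVI)
  expect_equal(rec$PRI, -0.02 + 0.05 * feats$NDVI, tolerance = 1e-12)
  expect_equal(rec$PhiPSII, 0.2 + 0.4 * feats$NDVI, tolerance = 1e-12)
})

test_that("OLS refit recovers a planted slope from noisy physiology", {
  truth <- truth_model(coef = list(LAI = c(intercept = 2, NDVI = 5)),
                       noise_sd = c(LAI = 0.1),
                       ranges = list(LAI = NULL))
  set.seed(9)
  feats <- data.frame(NDVI = runif(500, 0.05, 0.95))
  rec <- generate_physiology(feats, truth, seed = 9)
  slope <- unname(coef(lm(LAI ~ NDVI, data = rec))["NDVI"])
  expect_lt(abs(slope - 5), 0.1)
})

test_that("physiology generation enforces the minimum DSZ count and seeding", {
  truth <- default_truth_model()
  feats <- data.frame(NDVI = runif(5), RECI = runif(5), GNDVI = runif(5))
  expect_error(generate_physiology(feats[1:2, ], truth, 2, seed = 1), "n_dsz")
  a <- suppressMessages(generate_physiology(feats, truth, seed = 4))
  b <- suppressMessages(generate_physiology(feats, truth, seed = 4))
  expect_identical(a, b)
})

test_that("feature table plants detectable causal signal over noise features", {
  tab <- fx_table(seed = 3, n = 500, n_noise = 20)
  r <- sapply(fx_features(tab), function(v) abs(cor(v, tab$LAI)))
  causal <- r[c("NDVI", "NDRE")]
  noise_max <- max(r[grep("noise", names(r))])
  expect_true(all(causal > noise_max))
  expect_identical(fx_table(seed = 3, n = 500, n_noise = 20), tab)
  expect_error(generate_feature_table(10, 2), ">= 30")
})

test_that("default truth model keeps generated parameters in field envelopes", {
  set.seed(2)
  feats <- data.frame(NDVI = runif(200, 0.3, 0.95),
                      RECI = runif(200, 0.1, 0.9),
                      GNDVI = runif(200, 0.3, 0.7))
  rec <- suppressMessages(generate_physiology(feats, default_truth_model(),
                                              seed = 2))
  expect_true(all(rec$LAI >= 0.13 & rec$LAI <= 10.37))
  expect_true(all(rec$PRI >= -0.077 & rec$PRI <= 0.0766))
  expect_true(all(rec$PhiPSII >= 0.0729 & rec$PhiPSII <= 0.8648))
})

test_that("vigor interpolates canopy spectra monotonically", {
  lo <- vigor_spectra(0)$canopy$mean
  hi <- vigor_spectra(1)$canopy$mean
  mid <- vigor_spectra(0.5)$canopy$mean
  expect_true(all(abs(mid - (lo + hi) / 2) < 1e-12))
  expect_gt(hi[["nir"]], lo[["nir"]])
  expect_lt(hi[["red"]], lo[["red"]])
})
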