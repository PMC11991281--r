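#' Multiband plantation scene
#'
#' A `tea_scene` bundles co-registered band grids for one designed square zone
#' (DSZ), the ground resolution, and (for synthetic scenes) the ground-truth
#' canopy mask. Two band families are supported: 5-band multispectral
#' reflectance (`blue`, `green`, `red`, `red_edge`, `nir`; values in \[0, 1\])
#' and 3-band RGB digital numbers (`R`, `G`, `B`; values in \[0, 255\]).
#'
#' @param bands named list of numeric matrices, all with identical dimensions.
#'   Names must be exactly the multispectral set or the RGB set.
#' @param resolution_cm_per_px positive ground sampling distance; the default
#'   0.8 cm/px matches centimetre-level UAV orthomosaics flown low over the
#'   canopy.
#' @param truth_mask optional binary matrix (1 = canopy) with the same
#'   dimensions as the bands.
#' @return an object of class `tea_scene`.
#' @export
tea_scene <- function(bands, resolution_cm_per_px = 0.8, truth_mask = NULL) {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)))
  ms_bands <- c("blue", "green", "red", "red_edge", "nir")
  rgb_bands <- c("R", "G", "B")
  nm <- names(bands)
  if (setequal(nm, ms_bands)) {
    family <- "multispectral"
  } else if (setequal(nm, rgb_bands)) {
    family <- "rgb"
  } else {
    stop("band names must be {", paste(ms_bands, collapse = ", "),
         "} or {", paste(rgb_bands, collapse = ", "), "}")
  }
  dims <- lapply(bands, dim)
  if (length(unique(vapply(dims, paste, collapse = "x", FUN.VALUE = ""))) != 1L)
    stop("all band grids must share identical dimensions")
  rng <- range(unlist(bands, use.names = FALSE))
  if (family == "multispectral" && (rng[1] < 0 || rng[2] > 1))
    stop("multispectral reflectance must lie in [0, 1]")
  if (family == "rgb" && (rng[1] < 0 || rng[2] > 255))
    stop("RGB digital numbers must lie in [0, 255]")
  if (!is.null(truth_mask)) {
    if (!identical(dim(truth_mask), dims[[1]]))
      stop("truth_mask dimensions must equal band dimensions")
    if (!all(truth_mask %in% c(0, 1)))
      stop("truth_mask must be binary (0/1)")
  }
  stopifnot(is.numeric(resolution_cm_per_px), resolution_cm_per_px > 0)
  structure(
    list(bands = bands, resolution_cm_per_px = resolution_cm_per_px,
         truth_mask = truth_mask, family = family),
    class = "tea_scene")
}

#' @export
print.tea_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<tea_scene> %s, %d x %d px @ %.2f cm/px, bands: %s%s\n",
              x$family, d[1], d[2], x$resolution_cm_per_px,
              paste(names(x$bands), collapse = ", "),
              if (is.null(x$truth_mask)) "" else ", with truth mask"))
  invisible(x)
}

#' @export
dim.tea_scene <- function(x) dim(x$bands[[1]])

#' Write / read a scene on disk
#'
#' Bands are stored as one single-band TIFF per band next to a JSON sidecar
#' holding band order, family and resolution; the truth mask (when present) is
#' a single-band PNG with canopy = 255.
#'
#' @param scene a [tea_scene()].
#' @param path directory to create/use.
#' @return `write_scene` returns `path` invisibly; `read_scene` a `tea_scene`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "tea_scene"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  scale <- if (scene$family == "rgb") 255 else 1
  for (b in names(scene$bands))
    tiff::writeTIFF(scene$bands[[b]] / scale,
                    file.path(path, paste0(b, ".tif")),
                    bits.per.sample = 16L)
  if (!is.null(scene$truth_mask))
    png::writePNG(scene$truth_mask, file.path(path, "truth_mask.png"))
  meta <- list(family = scene$family, bands = names(scene$bands),
               resolution_cm_per_px = scene$resolution_cm_per_px,
               scale = scale)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(path, "scene.json"))
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  meta <- jsonlite::fromJSON(file.path(path, "scene.json"))
  bands <- lapply(meta$bands, function(b)
    unclass(tiff::readTIFF(file.path(path, paste0(b, ".tif")))) * meta$scale)
  names(bands) <- meta$bands
  mask_file <- file.path(path, "truth_mask.png")
  mask <- if (file.exists(mask_file))
    round(unclass(png::readPNG(mask_file))) else NULL
  tea_scene(bands, meta$resolution_cm_per_px, truth_mask = mask)
}
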