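#' Spectral index registry
#'
#' The registry holds 19 colour indices (CIs, computed from 3-band RGB
#' imagery) and 50 multispectral indices (MIs, computed from 5-band
#' blue/green/red/red-edge/NIR reflectance). Each definition is a row with the
#' index name, family, required bands and an arithmetic formula string.
#'
#' CI formulas are evaluated on digital numbers normalised to \[0, 1\]
#' (`R`, `G`, `B`) and on chromatic coordinates
#' (`r = R/(R+G+B)`, `g`, `b`) where the published formula requires them.
#' MI formulas are evaluated on reflectances `B`, `G`, `R`, `RE`, `N`
#' (blue, green, red, red edge, NIR). EVI uses the canonical constants
#' G = 2.5, C1 = 6, C2 = 7.5, L = 1.
#'
#' @param family optional filter, `"CI"` or `"MI"`.
#' @return data frame with columns `name`, `family`, `bands`
#'   (comma-separated), `formula`.
#' @export
index_definitions <- function(family = NULL) {
  ci <- data.frame(
    name = c("ExG", "ExR", "ExGR", "ExB", "NGRDI", "NGBDI", "RGBVI", "VARI",
             "GLI", "MGRVI", "RGRI", "GRRI", "GBRI", "RBRI", "VEG", "CIVE",
             "WI", "IKAW", "INT"),
    formula = c(
      "2*g - r - b",
      "1.4*r - g",
      "(2*g - r - b) - (1.4*r - g)",
      "1.4*b - g",
      "(G - R)/(G + R)",
      "(G - B)/(G + B)",
      "(G^2 - R*B)/(G^2 + R*B)",
      "(G - R)/(G + R - B)",
      "(2*G - R - B)/(2*G + R + B)",
      "(G^2 - R^2)/(G^2 + R^2)",
      "R/G",
      "G/R",
      "G/B",
      "R/B",
      "g/(r^0.667 * b^0.333)",
      "0.441*r - 0.811*g + 0.385*b + 18.78745",
      "(g - b)/(r - g)",
      "(R - B)/(R + B)",
      "(R + G + B)/3"),
    stringsAsFactors = FALSE)
  ci$family <- "CI"
  ci$bands <- "R,G,B"
  mi <- data.frame(
    name = c("NDVI", "GNDVI", "BNDVI", "NDRE", "RVI", "GRVI", "GCI", "RECI",
             "RERVI", "EVI", "EVI2", "SAVI", "OSAVI", "MSAVI", "GSAVI",
             "GOSAVI", "RESAVI", "REOSAVI", "DVI", "GDVI", "REDVI", "RDVI",
             "GRDVI", "RERDVI", "WDRVI", "MSR", "NLI", "MNLI", "TVI", "MTVI1",
             "MTVI2", "MCARI1", "MCARI2", "MCARI", "TCARI", "ARVI", "GARI",
             "SIPI", "PSRI", "NPCI", "CVI", "MTCI", "LCI", "NDWI", "ARI",
             "GBNDVI", "GRNDVI", "RBNDVI", "PNDVI", "REGNDVI"),
    formula = c(
      "(N - R)/(N + R)",
      "(N - G)/(N + G)",
      "(N - B)/(N + B)",
      "(N - RE)/(N + RE)",
      "N/R",
      "N/G",
      "N/G - 1",
      "N/RE - 1",
      "N/RE",
      "2.5*(N - R)/(N + 6*R - 7.5*B + 1)",
      "2.5*(N - R)/(N + 2.4*R + 1)",
      "1.5*(N - R)/(N + R + 0.5)",
      "1.16*(N - R)/(N + R + 0.16)",
      "(2*N + 1 - sqrt((2*N + 1)^2 - 8*(N - R)))/2",
      "1.5*(N - G)/(N + G + 0.5)",
      "1.16*(N - G)/(N + G + 0.16)",
      "1.5*(N - RE)/(N + RE + 0.5)",
      "1.16*(N - RE)/(N + RE + 0.16)",
      "N - R",
      "N - G",
      "N - RE",
      "(N - R)/sqrt(N + R)",
      "(N - G)/sqrt(N + G)",
      "(N - RE)/sqrt(N + RE)",
      "(0.12*N - R)/(0.12*N + R)",
      "(N/R - 1)/sqrt(N/R + 1)",
      "(N^2 - R)/(N^2 + R)",
      "1.5*(N^2 - R)/(N^2 + R + 0.5)",
      "0.5*(120*(N - G) - 200*(R - G))",
      "1.2*(1.2*(N - G) - 2.5*(R - G))",
      "1.5*(1.2*(N - G) - 2.5*(R - G))/sqrt((2*N + 1)^2 - (6*N - 5*sqrt(R)) - 0.5)",
      "1.2*(2.5*(N - R) - 1.3*(N - G))",
      "1.5*(2.5*(N - R) - 1.3*(N - G))/sqrt((2*N + 1)^2 - (6*N - 5*sqrt(R)) - 0.5)",
      "((RE - R) - 0.2*(RE - G))*(RE/R)",
      "3*((RE - R) - 0.2*(RE - G)*(RE/R))",
      "(N - (2*R - B))/(N + (2*R - B))",
      "(N - (G - 1.7*(B - R)))/(N + (G - 1.7*(B - R)))",
      "(N - B)/(N - R)",
      "(R - G)/RE",
      "(R - B)/(R + B)",
      "N*R/G^2",
      "(N - RE)/(RE - R)",
      "(N - RE)/(N + R)",
      "(G - N)/(G + N)",
      "1/G - 1/RE",
      "(N - (G + B))/(N + (G + B))",
      "(N - (G + R))/(N + (G + R))",
      "(N - (R + B))/(N + (R + B))",
      "(N - (G + R + B))/(N + (G + R + B))",
      "(RE - G)/(RE + G)"),
    stringsAsFactors = FALSE)
  mi$family <- "MI"
  mi$bands <- vapply(mi$formula, function(f) {
    v <- all.vars(str2lang(f))
    paste(intersect(c("B", "G", "R", "RE", "N"), v), collapse = ",")
  }, "", USE.NAMES = FALSE)
  ci$bands <- vapply(ci$formula, function(f) {
    v <- all.vars(str2lang(f))
    has <- unique(c(intersect(c("R", "G", "B"), v),
                    if (any(c("r", "g", "b") %in% v)) c("R", "G", "B")))
    paste(intersect(c("R", "G", "B"), has), collapse = ",")
  }, "", USE.NAMES = FALSE)
  reg <- rbind(ci[c("name", "family", "bands", "formula")],
               mi[c("name", "family", "bands", "formula")])
  rownames(reg) <- NULL
  if (!is.null(family)) reg <- reg[reg$family == family, , drop = FALSE]
  reg
}

#' Read an index registry from CSV
#'
#' The registry can be versioned on disk as a CSV with columns
#' `name,family,bands,formula`; this loads and validates it.
#' @param path CSV path.
#' @return registry data frame as from [index_definitions()].
#' @export
read_index_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "family", "bands", "formula") %in% names(reg)))
  if (anyDuplicated(reg$name)) stop("duplicate index names in registry")
  reg
}

# band environment for formula evaluation; errors name any missing band
.band_env <- function(scene, def) {
  need <- strsplit(def$bands, ",")[[1]]
  if (def$family == "MI") {
    map <- c(B = "blue", G = "green", R = "red", RE = "red_edge", N = "nir")
    missing <- setdiff(unname(map[need]), names(scene$bands))
    if (length(missing) > 0)
      stop("scene is missing band(s) required by ", def$name, ": ",
           paste(missing, collapse = ", "))
    env <- lapply(map, function(b) scene$bands[[b]])
    names(env) <- names(map)
  } else {
    missing <- setdiff(need, names(scene$bands))
    if (length(missing) > 0)
      stop("scene is missing band(s) required by ", def$name, ": ",
           paste(missing, collapse = ", "))
    R <- scene$bands$R / 255; G <- scene$bands$G / 255; B <- scene$bands$B / 255
    s <- R + G + B
    env <- list(R = R, G = G, B = B, r = R / s, g = G / s, b = B / s)
  }
  list2env(env, parent = baseenv())
}

#' Per-pixel index map
#'
#' Evaluates one index formula over a scene's band grids. Pixels where the
#' formula is undefined (zero denominator, negative square-root argument) are
#' marked `NA` rather than substituted.
#'
#' @param scene a [tea_scene()].
#' @param index a single-row registry entry (data frame row or list with
#'   `name`, `family`, `bands`, `formula`), or an index name looked up in
#'   [index_definitions()].
#' @return numeric matrix of index values with `NA` at invalid pixels.
#' @export
compute_index_map <- function(scene, index) {
  stopifnot(inherits(scene, "tea_scene"))
  if (is.character(index)) {
    reg <- index_definitions()
    hit <- reg[reg$name == index, , drop = FALSE]
    if (nrow(hit) != 1) stop("unknown index: ", index)
    index <- hit
  }
  def <- as.list(index)
  env <- .band_env(scene, def)
  old <- options(warn = -1); on.exit(options(old))
  vals <- eval(str2lang(def$formula), env)
  vals[!is.finite(vals)] <- NA_real_
  matrix(vals, nrow = dim(scene)[1])
}

#' Zonal mean of an index over a canopy mask
#'
#' Arithmetic mean of valid (non-`NA`) index values over mask pixels; invalid
#' pixels are excluded from both the numerator and the pixel count.
#'
#' @param index_map numeric matrix from [compute_index_map()].
#' @param mask binary matrix, 1 = canopy.
#' @return list with `value` (mean, `NA` if no valid canopy pixel) and
#'   `n_pixels` (count of contributing pixels).
#' @export
zonal_mean_index <- function(index_map, mask) {
  stopifnot(identical(dim(index_map), dim(mask)))
  v <- index_map[mask == 1]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    message("zonal_mean_index: no valid canopy pixel; feature flagged missing")
    return(list(value = NA_real_, n_pixels = 0L))
  }
  list(value = mean(v), n_pixels = length(v))
}

#' Per-DSZ feature vector over a registry subset
#'
#' Computes the canopy zonal mean of each index in the subset. Per-index
#' failures other than missing bands degrade to flagged `NA` values; a missing
#' band is a hard error naming the band.
#'
#' @param scene a [tea_scene()].
#' @param mask binary canopy mask.
#' @param registry registry data frame (defaults to the scene family's full
#'   set: 19 CIs for RGB, 50 MIs for multispectral).
#' @return named numeric vector of index values with attribute `n_pixels`
#'   (named integer vector of contributing pixel counts).
#' @export
compute_feature_vector <- function(scene, mask, registry = NULL) {
  stopifnot(inherits(scene, "tea_scene"))
  if (is.null(registry))
    registry <- index_definitions(
      if (scene$family == "rgb") "CI" else "MI")
  fam_ok <- if (scene$family == "rgb") "CI" else "MI"
  bad <- registry$family != fam_ok
  if (any(bad)) {
    # surface the contract error with the missing bands named
    compute_index_map(scene, registry[which(bad)[1], ])
  }
  vals <- numeric(nrow(registry)); counts <- integer(nrow(registry))
  for (i in seq_len(nrow(registry))) {
    zm <- tryCatch(
      zonal_mean_index(compute_index_map(scene, registry[i, ]), mask),
      error = function(e) {
        if (grepl("missing band", conditionMessage(e))) stop(e)
        message("index ", registry$name[i], " failed: ", conditionMessage(e))
        list(value = NA_real_, n_pixels = 0L)
      })
    vals[i] <- zm$value; counts[i] <- zm$n_pixels
  }
  names(vals) <- registry$name; names(counts) <- registry$name
  attr(vals, "n_pixels") <- counts
  vals
}
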