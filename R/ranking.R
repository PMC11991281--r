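#' Pearson correlation of a paired series
#'
#' r = sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2)).
#' Feature ranking uses |r|.
#'
#' @param x,y numeric vectors of equal length >= 3, no missing values.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            !anyNA(x), !anyNA(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance input")
  stats::cor(x, y)
}

#' Mutual information of two discretised variables
#'
#' Plug-in estimate in nats on an equal-frequency discretisation of each
#' variable. Equal-frequency binning is robust to the skewed distributions
#' typical of vegetation indices. A constant vector carries no information
#' (MI = 0).
#'
#' @param x,y numeric vectors, length >= 10.
#' @param bins bin count (default `ceiling(sqrt(n))`).
#' @return mutual information >= 0, symmetric in its arguments.
#' @export
mutual_information <- function(x, y, bins = ceiling(sqrt(length(x)))) {
  n <- length(x)
  stopifnot(n == length(y), n >= 10, bins >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  disc <- function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    if (length(br) < 3) br <- unique(c(min(v), stats::median(v), max(v)))
    cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  joint <- table(disc(x), disc(y)) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  max(0, sum(joint[nz] * log(joint[nz] / outer(px, py)[nz])))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy selection: the first feature maximises relevance I(x_j, y); each
#' subsequent feature maximises relevance minus the mean mutual information
#' with the already-selected set (the 1/(m-1) normalisation). Negative
#' objectives are allowed; selection proceeds over the full feature set so the
#' result is a complete ranking. Ties keep input-column order.
#'
#' @param table data frame or matrix of features (columns).
#' @param y numeric target.
#' @param bins passed to [mutual_information()].
#' @return a `ranking_result` data frame: `method`, `rank`, `feature`,
#'   `score` (the objective value at the feature's selection step).
#' @export
mrmr_rank <- function(table, y, bins = ceiling(sqrt(length(y)))) {
  X <- as.data.frame(table)
  p <- ncol(X)
  stopifnot(p >= 2)
  rel <- vapply(X, mutual_information, numeric(1), y = y, bins = bins)
  red <- matrix(0, p, p, dimnames = list(names(X), names(X)))
  for (i in seq_len(p - 1)) for (j in (i + 1):p)
    red[i, j] <- red[j, i] <- mutual_information(X[[i]], X[[j]], bins = bins)
  selected <- integer(0)
  scores <- numeric(0)
  pool <- seq_len(p)
  while (length(pool) > 0) {
    obj <- if (length(selected) == 0) rel[pool]
           else rel[pool] - rowMeans(red[pool, selected, drop = FALSE])
    best <- pool[which.max(obj)]
    selected <- c(selected, best)
    scores <- c(scores, max(obj))
    pool <- setdiff(pool, best)
  }
  structure(data.frame(method = "MRMR", rank = seq_len(p),
                       feature = names(X)[selected], score = scores,
                       stringsAsFactors = FALSE),
            class = c("ranking_result", "data.frame"))
}

#' Gray relational analysis feature ranking
#'
#' Each sequence (features and target) is min-max normalised to \[0, 1\]. The
#' gray relational coefficient of feature i at point k is
#' `(Dmin + rho * Dmax) / (D_i(k) + rho * Dmax)` where `D_i(k)` is the
#' absolute feature-target difference and `Dmin`/`Dmax` are global extrema
#' over all sequences and points; the gray correlation degree is the mean
#' coefficient over points. Features are ranked by descending degree.
#'
#' @param table data frame or matrix of features.
#' @param y numeric target.
#' @param rho distinguishing coefficient (default 0.5).
#' @return a `ranking_result` data frame with the gray correlation degree as
#'   score.
#' @export
gra_rank <- function(table, y, rho = 0.5) {
  X <- as.data.frame(table)
  stopifnot(ncol(X) >= 1, length(y) >= 2, nrow(X) == length(y))
  norm01 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(0, length(v)))
    (v - r[1]) / (r[2] - r[1])
  }
  if (max(y) == min(y))
    stop("degenerate input: constant target after normalisation")
  yn <- norm01(y)
  D <- vapply(X, function(v) abs(norm01(v) - yn), numeric(length(y)))
  D <- matrix(D, ncol = ncol(X), dimnames = list(NULL, names(X)))
  dmin <- min(D); dmax <- max(D)
  grc <- if (dmax == 0) D + 1  # exact normalised match everywhere
         else (dmin + rho * dmax) / (D + rho * dmax)
  gamma <- colMeans(grc)
  ord <- order(-gamma)
  structure(data.frame(method = "GRA", rank = seq_along(gamma),
                       feature = names(X)[ord], score = unname(gamma[ord]),
                       stringsAsFactors = FALSE),
            class = c("ranking_result", "data.frame"))
}

#' Rank features against a physiological target
#'
#' Dispatches to Pearson correlation ("PCA": ranked by |r|, stable ties),
#' minimum-redundancy maximum-relevance ("MRMR") or gray relational analysis
#' ("GRA"), and returns the full score table for all features.
#'
#' @param table data frame or matrix of features.
#' @param y numeric target.
#' @param method one of `"PCA"`, `"MRMR"`, `"GRA"`.
#' @param ... passed to the method (`bins` for MRMR, `rho` for GRA).
#' @return a `ranking_result` data frame (`method`, `rank`, `feature`,
#'   `score`) with one row per feature.
#' @export
rank_features <- function(table, y, method = c("PCA", "MRMR", "GRA"), ...) {
  method <- match.arg(method)
  switch(method,
    PCA = {
      X <- as.data.frame(table)
      r <- vapply(X, pearson_r, numeric(1), y = y)
      ord <- order(-abs(r))
      structure(data.frame(method = "PCA", rank = seq_along(r),
                           feature = names(X)[ord], score = abs(unname(r[ord])),
                           stringsAsFactors = FALSE),
                class = c("ranking_result", "data.frame"))
    },
    MRMR = mrmr_rank(table, y, ...),
    GRA = gra_rank(table, y, ...))
}
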