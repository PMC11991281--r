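#' Descriptive statistics by farming method
#'
#' Per-group count, min, mean, max, sample standard deviation (n - 1
#' denominator) and coefficient of variation CV = StDev/Mean for one
#' physiological parameter, ignoring missing values (which the field protocol
#' removes rather than imputes).
#'
#' @param table DSZ data frame with the parameter column and a grouping
#'   column.
#' @param parameter column name (e.g. `"LAI"`).
#' @param by grouping column (default `"farming_method"`).
#' @return data frame with one row per group: `parameter`, group, `Number`,
#'   `Min`, `Mean`, `Max`, `StDev`, `CV` (NA with a flag when Mean is 0).
#' @export
describe_physiology <- function(table, parameter, by = "farming_method") {
  stopifnot(parameter %in% names(table), by %in% names(table))
  groups <- split(table[[parameter]], table[[by]])
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]; v <- v[!is.na(v)]
    stopifnot(length(v) >= 2)
    m <- mean(v); s <- stats::sd(v)
    cv <- if (m == 0) NA_real_ else s / m
    if (m == 0) warning("CV undefined for ", g, ": zero mean")
    data.frame(parameter = parameter, group = g, Number = length(v),
               Min = min(v), Mean = m, Max = max(v), StDev = s, CV = cv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2] <- by
  out
}

#' Recompute CV from a printed summary table
#'
#' Adds/overwrites a `CV` column as `StDev / Mean` on a descriptive-summary
#' table (columns `Mean`, `StDev`), e.g. to audit published summaries.
#' @param summary_df summary table.
#' @return the table with a recomputed `CV` column.
#' @export
recompute_cv <- function(summary_df) {
  stopifnot(all(c("Mean", "StDev") %in% names(summary_df)))
  summary_df$CV <- summary_df$StDev / summary_df$Mean
  summary_df
}

# Levene's test on medians (Brown-Forsythe); returns p-value
.levene_p <- function(values, group) {
  df <- data.frame(v = values, g = factor(group))
  out <- car::leveneTest(v ~ g, data = df, center = stats::median)
  out[["Pr(>F)"]][1]
}

#' Compare farming methods at one elevation
#'
#' Two-sample t-test of a parameter between the two farming methods, with the
#' pooled (Student) form when a Levene pre-test (on medians, alpha = 0.05)
#' accepts variance homogeneity and the Welch form otherwise. Significance is
#' flagged at p < 0.05.
#'
#' @param table DSZ data frame with `farming_method`, `elevation_class` and
#'   the parameter.
#' @param parameter column name.
#' @param elevation optional elevation class to subset to.
#' @param alpha significance level.
#' @return list: `test` ("Student t" or "Welch t"), `levene_p`, `p`,
#'   `significant`, group means.
#' @export
compare_farming_methods <- function(table, parameter, elevation = NULL,
                                    alpha = 0.05) {
  df <- table
  if (!is.null(elevation)) df <- df[df$elevation_class == elevation, ]
  df <- df[!is.na(df[[parameter]]), ]
  groups <- split(df[[parameter]], df$farming_method)
  if (length(groups) < 2) stop("both farming methods must be present")
  stopifnot(all(lengths(groups) >= 2))
  lev_p <- .levene_p(df[[parameter]], df$farming_method)
  pooled <- !is.na(lev_p) && lev_p >= alpha
  tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = pooled)
  list(test = if (pooled) "Student t" else "Welch t",
       levene_p = lev_p, p = tt$p.value,
       significant = tt$p.value < alpha,
       means = vapply(groups, mean, numeric(1)))
}

# Games-Howell pairwise comparisons (unequal variances): studentized range
# statistic with Welch degrees of freedom
.games_howell <- function(groups) {
  k <- length(groups)
  nm <- names(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  out <- data.frame()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    q <- abs(m[i] - m[j]) / sqrt(se2 / 2)
    p <- stats::ptukey(q, k, df, lower.tail = FALSE)
    out <- rbind(out, data.frame(g1 = nm[i], g2 = nm[j], p = p))
  }
  out
}

#' Compact letter display from a pairwise significance matrix
#'
#' Groups are letters-compressed so that two groups share a letter iff they
#' are not significantly different: letters correspond to the maximal cliques
#' of the non-significance graph, ordered by descending group mean.
#'
#' @param pairs data frame with columns `g1`, `g2`, `p`.
#' @param means named numeric of group means (defines letter order).
#' @param alpha significance level.
#' @return named character vector of letter strings, one per group.
#' @export
letter_groups <- function(pairs, means, alpha = 0.05) {
  nm <- names(means)
  adj <- matrix(TRUE, length(nm), length(nm), dimnames = list(nm, nm))
  for (r in seq_len(nrow(pairs))) {
    sig <- pairs$p[r] < alpha
    adj[pairs$g1[r], pairs$g2[r]] <- adj[pairs$g2[r], pairs$g1[r]] <- !sig
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  # order cliques by the highest member mean so 'a' labels the top group
  cl <- cl[order(-vapply(cl, function(x) max(means[nm[as.integer(x)]]),
                         numeric(1)))]
  letters_out <- stats::setNames(rep("", length(nm)), nm)
  for (ci in seq_along(cl)) {
    members <- nm[as.integer(cl[[ci]])]
    letters_out[members] <- paste0(letters_out[members], letters[ci])
  }
  letters_out
}

#' Compare elevations within one farming method
#'
#' One-way ANOVA when a Levene pre-test accepts variance homogeneity, Welch
#' ANOVA otherwise; pairwise post-hoc comparisons (Tukey HSD under
#' homogeneity, Games-Howell otherwise) are compressed to letter groups.
#'
#' @param table DSZ data frame.
#' @param parameter column name.
#' @param farming_method optional method to subset to.
#' @param alpha significance level.
#' @return list: `test` ("ANOVA" or "Welch ANOVA"), `levene_p`, `p` (omnibus),
#'   `posthoc` ("Tukey HSD" or "Games-Howell"), `pairs`, `letters`, `means`.
#' @export
compare_elevations <- function(table, parameter, farming_method = NULL,
                               alpha = 0.05) {
  df <- table
  if (!is.null(farming_method)) df <- df[df$farming_method == farming_method, ]
  df <- df[!is.na(df[[parameter]]), ]
  df$elevation_class <- factor(df$elevation_class)
  groups <- split(df[[parameter]], df$elevation_class)
  if (length(groups) < 2) stop(">= 2 elevation groups required")
  stopifnot(all(lengths(groups) >= 3))
  lev_p <- .levene_p(df[[parameter]], df$elevation_class)
  homog <- !is.na(lev_p) && lev_p >= alpha
  y <- df[[parameter]]; g <- df$elevation_class
  if (homog) {
    fit <- stats::aov(y ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    cmp <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    pairs <- data.frame(g1 = cmp[, 1], g2 = cmp[, 2], p = tk[, "p adj"],
                        stringsAsFactors = FALSE)
    posthoc <- "Tukey HSD"
  } else {
    p <- stats::oneway.test(y ~ g, var.equal = FALSE)$p.value
    pairs <- .games_howell(groups)
    posthoc <- "Games-Howell"
  }
  means <- vapply(groups, mean, numeric(1))
  list(test = if (homog) "ANOVA" else "Welch ANOVA",
       levene_p = lev_p, p = p, posthoc = posthoc, pairs = pairs,
       letters = letter_groups(pairs, means, alpha), means = means)
}

#' Grouped prediction-error report
#'
#' RMSE and mean signed error (bias; positive = overestimation) per
#' elevation x season x farming-method cell of a residual table. Empty cells
#' are omitted with a log message.
#'
#' @param predictions data frame with a `residual` column
#'   (predicted - measured) and `elevation_class`, `season`,
#'   `farming_method` labels.
#' @return data frame with one row per non-empty cell: the labels, `n`,
#'   `RMSE`, `bias`, and a `direction` flag
#'   ("overestimated"/"underestimated"/"unbiased").
#' @export
grouped_error_report <- function(predictions) {
  need <- c("residual", "elevation_class", "season", "farming_method")
  stopifnot(all(need %in% names(predictions)))
  cells <- expand.grid(
    elevation_class = unique(predictions$elevation_class),
    season = unique(predictions$season),
    farming_method = unique(predictions$farming_method),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- predictions$elevation_class == cells$elevation_class[i] &
      predictions$season == cells$season[i] &
      predictions$farming_method == cells$farming_method[i]
    r <- predictions$residual[sel]
    r <- r[!is.na(r)]
    if (length(r) == 0) {
      message("grouped_error_report: empty cell ",
              paste(unlist(cells[i, ]), collapse = "/"), " omitted")
      next
    }
    bias <- mean(r)
    rows[[length(rows) + 1]] <- cbind(
      cells[i, , drop = FALSE],
      data.frame(n = length(r), RMSE = sqrt(mean(r^2)), bias = bias,
                 direction = if (bias > 0) "overestimated"
                             else if (bias < 0) "underestimated"
                             else "unbiased"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
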