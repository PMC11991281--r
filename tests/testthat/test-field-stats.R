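test_that("descriptive statistics use the sample convention and flag zero means", {
  df <- data.frame(farming_method = rep(c("CFM", "AFM"), each = 4),
                   LAI = c(2, 4, 6, 8, 5, 5, 5, 5))
  d <- describe_physiology(df, "LAI")
  cfm <- d[d$farming_method == "CFM", ]
  expect_equal(cfm$Mean, 5)
  expect_equal(cfm$StDev, sd(c(2, 4, 6, 8)))
  expect_equal(cfm$CV, sd(c(2, 4, 6, 8)) / 5)
  afm <- d[d$farming_method == "AFM", ]
  expect_equal(afm$StDev, 0)
  expect_equal(afm$CV, 0)
})

test_that("CV is invariant to positive unit rescaling", {
  set.seed(13)
  df <- data.frame(farming_method = "CFM", LAI = runif(30, 1, 5))
  df2 <- df; df2$LAI <- df2$LAI * 100
  expect_equal(describe_physiology(df, "LAI")$CV,
               describe_physiology(df2, "LAI")$CV)
})

test_that("published summary CVs reproduce from printed means and deviations", {
  s <- recompute_cv(field_summary_stats())
  expect_equal(round(s$CV, 3), s$CV_printed)
  # spot checks against the printed table
  lai_cfm <- s[s$parameter == "LAI" & s$farming_method == "CFM", ]
  expect_equal(round(lai_cfm$CV, 3), 0.349)
  pri_afm <- s[s$parameter == "PRI" & s$farming_method == "AFM", ]
  expect_equal(round(pri_afm$CV, 3), 1.249)
})

test_that("farming-method comparison picks the pooled or Welch branch by Levene", {
  # identical samples: no significance
  df <- data.frame(farming_method = rep(c("CFM", "AFM"), each = 5),
                   LAI = rep(c(1, 2, 3, 4, 5), 2))
  out <- compare_farming_methods(df, "LAI")
  expect_false(out$significant)

  # large separation: detected with near-certain power
  set.seed(14)
  df2 <- data.frame(farming_method = rep(c("CFM", "AFM"), each = 50),
                    LAI = c(rnorm(50, 0), rnorm(50, 3)))
  out2 <- compare_farming_methods(df2, "LAI")
  expect_true(out2$significant)
  expect_lt(out2$p, 0.001)

  # equal means, strongly unequal variances: Welch branch recorded
  set.seed(15)
  df3 <- data.frame(farming_method = rep(c("CFM", "AFM"), each = 60),
                    LAI = c(rnorm(60, 5, 0.1), rnorm(60, 5, 3)))
  out3 <- compare_farming_methods(df3, "LAI")
  expect_equal(out3$test, "Welch t")

  expect_error(compare_farming_methods(df3[df3$farming_method == "CFM", ],
                                       "LAI"), "both farming methods")
})

test_that("elevation comparison produces letter groups from pairwise tests", {
  # three identical-distribution groups share one letter
  set.seed(42)
  df <- data.frame(elevation_class = rep(c("low", "mid", "high"), each = 30),
                   LAI = rnorm(90))
  out <- compare_elevations(df, "LAI")
  expect_true(all(out$letters == out$letters[1]))

  # one shifted group earns its own letter
  set.seed(16)
  df2 <- data.frame(elevation_class = rep(c("low", "mid", "high"), each = 30),
                    LAI = c(rnorm(30, 0), rnorm(30, 0), rnorm(30, 5)))
  out2 <- compare_elevations(df2, "LAI")
  expect_equal(out2$letters[["low"]], out2$letters[["mid"]])
  expect_false(out2$letters[["high"]] == out2$letters[["low"]])

  expect_error(compare_elevations(df2[df2$elevation_class == "low", ], "LAI"),
               ">= 2")
})

test_that("two-group letter display agrees with the t-test", {
  set.seed(17)
  df <- data.frame(elevation_class = rep(c("low", "high"), each = 25),
                   farming_method = "CFM",
                   LAI = c(rnorm(25, 0), rnorm(25, 2)))
  ce <- compare_elevations(df, "LAI")
  tt <- t.test(LAI ~ elevation_class, df,
               var.equal = ce$test == "ANOVA")
  distinct <- ce$letters[["low"]] != ce$letters[["high"]]
  expect_equal(distinct, tt$p.value < 0.05)
})

test_that("the letter partition derives exactly from the significance matrix", {
  set.seed(18)
  df <- data.frame(elevation_class = rep(c("low", "mid", "high"), each = 40),
                   LAI = c(rnorm(40, 0), rnorm(40, 1), rnorm(40, 2)))
  out <- compare_elevations(df, "LAI")
  share <- function(a, b)
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
  for (r in seq_len(nrow(out$pairs))) {
    same_letter <- share(out$letters[[out$pairs$g1[r]]],
                         out$letters[[out$pairs$g2[r]]])
    expect_equal(same_letter, out$pairs$p[r] >= 0.05)
  }
})

test_that("grouped error report recovers planted per-cell error structure", {
  cells <- expand.grid(elevation_class = c("low", "mid"),
                       season = c("spring", "summer"),
                       farming_method = c("CFM", "AFM"),
                       stringsAsFactors = FALSE)
  zero <- cbind(cells[rep(1:8, each = 3), ], residual = 0)
  rep0 <- grouped_error_report(zero)
  expect_true(all(rep0$RMSE == 0))

  up <- cbind(cells[rep(1:8, each = 3), ], residual = 0.1)
  rep_up <- grouped_error_report(up)
  expect_true(all(rep_up$bias == 0.1))
  expect_true(all(rep_up$direction == "overestimated"))

  # per-cell RMSE within 15% of the planted sigma at n = 100 per cell
  set.seed(19)
  sig <- seq(0.5, 1.9, length.out = 8)
  noisy <- do.call(rbind, lapply(1:8, function(i)
    cbind(cells[rep(i, 100), ], residual = rnorm(100, 0, sig[i]))))
  rep_n <- grouped_error_report(noisy)
  rep_n <- rep_n[order(match(paste(rep_n$elevation_class, rep_n$season,
                                   rep_n$farming_method),
                             paste(cells$elevation_class, cells$season,
                                   cells$farming_method))), ]
  expect_true(all(abs(rep_n$RMSE - sig) / sig < 0.15))

  # an empty cell is omitted with a message
  expect_message(
    out <- grouped_error_report(zero[zero$season != "summer" |
                                       zero$farming_method != "AFM", ]),
    "empty cell")
  expect_lt(nrow(out), 8)
})
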