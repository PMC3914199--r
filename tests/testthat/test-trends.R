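test_that("DTW self-alignment has zero cost along the diagonal", {
  x <- c(100, 102, 99, 98, 97, 99, 101, 100)
  d <- dtw_align(x, x)
  expect_equal(d$cost, 0)
  expect_equal(d$path, cbind(trend = 1:8, reference = 1:8))
  expect_equal(d$aligned, x)
})

test_that("DTW absorbs a one-step circular phase shift", {
  x <- c(100, 104, 108, 110, 108, 104, 100, 98)
  sh <- c(x[-1], x[1])
  d <- dtw_align(sh, x)
  expect_lt(d$cost, sum((sh - x)^2))
})

test_that("DTW paths are monotone with pinned boundaries; cost is symmetric", {
  set.seed(6)
  for (rep in 1:10) {
    a <- rnorm(8, 100, 5)
    b <- rnorm(8, 100, 5)
    d <- dtw_align(a, b)
    expect_equal(d$path[1, ], c(trend = 1, reference = 1))
    expect_equal(d$path[nrow(d$path), ], c(trend = 8, reference = 8))
    expect_true(all(diff(d$path[, 1]) %in% c(0, 1)))
    expect_true(all(diff(d$path[, 2]) %in% c(0, 1)))
    expect_true(all(rowSums(abs(diff(d$path))) >= 1))
    expect_equal(d$cost, dtw_align(b, a)$cost)
  }
  expect_error(dtw_align(1:8, 1:7), class = "rp_invalid_argument")
})

test_that("trend averaging reduces to the elementwise mean when expected", {
  one <- tibble::tibble(subject = 1, vessel_id = 1,
                        vessel_class = "arteriole",
                        phase = 1:8, diameter_um = c(90, 92, 91, 90, 89, 90, 91, 90))
  avg1 <- average_trends(one)
  expect_equal(avg1$summary$mean_um, one$diameter_um)
  expect_equal(avg1$summary$sd_um, rep(0, 8))

  two <- dplyr::bind_rows(
    tibble::tibble(subject = 1, vessel_id = 1, vessel_class = "venule",
                   phase = 1:8, diameter_um = rep(100, 8)),
    tibble::tibble(subject = 1, vessel_id = 2, vessel_class = "venule",
                   phase = 1:8, diameter_um = rep(110, 8))
  )
  expect_equal(average_trends(two)$summary$mean_um, rep(105, 8))

  set.seed(12)
  rnd <- tidyr::expand_grid(vessel_id = 1:5, phase = 1:8)
  rnd$subject <- 1
  rnd$vessel_class <- "arteriole"
  rnd$diameter_um <- rnorm(40, 95, 4)
  raw <- average_trends(rnd, use_dtw = FALSE)
  oracle <- tapply(rnd$diameter_um[order(rnd$vessel_id, rnd$phase)],
                   rep(1:8, 5), mean)
  expect_equal(raw$summary$mean_um, as.numeric(oracle))

  mixed <- rnd
  mixed$vessel_class[1:8] <- "venule"
  expect_error(average_trends(mixed), class = "rp_invalid_argument")
  expect_error(average_trends(rnd[0, ]), class = "rp_invalid_argument")
})

test_that("trend summaries reproduce the published caliber-table arithmetic", {
  vis <- example_table("visualized")
  art <- vis[vis$vessel_class == "arteriole", ]
  ts <- trend_summary(art$mean_um, art$sd_um)
  expect_equal(ts$max_min, 3.3, tolerance = 1e-9)
  expect_equal(ts$peak_point, 2L)
  expect_equal(unname(ts$variations["point_2"]), 2.5, tolerance = 1e-9)
  ven <- vis[vis$vessel_class == "venule", ]
  tv <- trend_summary(ven$mean_um, ven$sd_um)
  expect_equal(tv$max_min, 6.6, tolerance = 1e-9)
  expect_equal(tv$peak_point, 6L)

  un <- example_table("unaided")
  expect_equal(trend_summary(un$mean_um[un$vessel_class == "arteriole"])$max_min,
               1.2, tolerance = 1e-9)
  expect_equal(trend_summary(un$mean_um[un$vessel_class == "venule"])$max_min,
               1.9, tolerance = 1e-9)

  cst <- trend_summary(rep(100, 8))
  expect_equal(unname(cst$variations), rep(0, 7))
  expect_equal(cst$max_min, 0)
  expect_error(trend_summary(rep(100, 5)), class = "rp_invalid_argument")
})

test_that("max-min dominates every variation from point 1", {
  set.seed(33)
  for (rep in 1:25) {
    m <- rnorm(8, 100, 5)
    ts <- trend_summary(m)
    expect_gte(ts$max_min, max(ts$variations))
    expect_gte(ts$max_min, 0)
    expect_true(ts$peak_point >= 1 && ts$peak_point <= 8)
  }
})

test_that("repeated-measures ANOVA partitions sums of squares correctly", {
  # degenerate: every subject constant across conditions
  flat <- matrix(rep(c(3, 5, 9, 2, 7), 4), 5, 4)
  r0 <- rm_anova(flat)
  expect_equal(r0$F, 0)
  expect_equal(r0$p_value, 1)

  # random matrices vs the aov() within-subject oracle
  set.seed(17)
  for (rep in 1:5) {
    mat <- matrix(rnorm(5 * 4, 100, 3), 5, 4)
    r <- rm_anova(mat)
    df <- data.frame(y = as.vector(mat),
                     subject = factor(rep(seq_len(5), 4)),
                     cond = factor(rep(seq_len(4), each = 5)))
    a <- summary(stats::aov(y ~ cond + Error(subject / cond), data = df))
    tab <- a[["Error: subject:cond"]][[1]]
    expect_lt(abs(r$F - tab["cond", "F value"]), 1e-9)
    expect_lt(abs(r$p_value - tab["cond", "Pr(>F)"]), 1e-9)
    expect_equal(r$df_condition, 3)
    expect_equal(r$df_error, 12)
  }

  expect_error(rm_anova(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "rp_invalid_argument")
  expect_error(rm_anova(matrix(1:4, 1, 4)), class = "rp_invalid_argument")
})

test_that("a one-condition shift of 5 SD is detected decisively", {
  set.seed(29)
  mat <- matrix(rnorm(12 * 8, 100, 1), 12, 8)
  mat[, 4] <- mat[, 4] + 5
  expect_lt(rm_anova(mat)$p_value, 0.001)
})

test_that("Greenhouse-Geisser correction scales both df by a bounded epsilon", {
  set.seed(61)
  mat <- matrix(rnorm(10 * 6, 100, 2), 10, 6)
  mat[, 1] <- mat[, 1] + rnorm(10, 2, 6) # break sphericity, add an effect
  r <- rm_anova(mat)
  g <- rm_anova(mat, gg_correction = TRUE)
  expect_equal(g$F, r$F) # the statistic is untouched; only df change
  expect_true(g$epsilon >= 1 / 5 && g$epsilon <= 1)
  expect_lt(g$epsilon, 1) # this design is clearly non-spherical
  expect_equal(g$p_value,
               stats::pf(g$F, g$df_condition * g$epsilon,
                         g$df_error * g$epsilon, lower.tail = FALSE))
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(2)
  mat <- matrix(rnorm(6 * 4, 50, 2), 6, 4)
  r <- rm_anova(mat)
  td <- tidy(r)
  expect_equal(td$term, c("condition", "subject", "error"))
  expect_equal(sum(td$sumsq), sum((mat - mean(mat))^2), tolerance = 1e-9)
  gl <- glance(r)
  expect_equal(gl$statistic, r$F)
  expect_equal(gl$df, 3)
})

test_that("post hoc comparisons are paired t-tests with Bonferroni scaling", {
  set.seed(8)
  mat <- matrix(rnorm(9 * 5, 100, 2), 9, 5)
  ph <- posthoc_vs_first(mat)
  expect_equal(nrow(ph), 4)
  tt <- stats::t.test(mat[, 3] - mat[, 1])
  expect_equal(ph$p.value[ph$phase == 3], tt$p.value)
  expect_equal(ph$p.adjusted, pmin(1, ph$p.value * 4))
})

test_that("grader table averages reproduce the published comparison", {
  tab <- example_table("grader_counts")
  gs <- grader_table_summary(tab)
  q <- gs[gs$feature == "QOF", ]
  expect_equal(q$mean[q$method == "proposed"], 6.9)
  expect_equal(q$mean_int[q$method == "pca"], 3)
  # per-feature averages over subjects and both graders, as printed
  printed <- tibble::tribble(
    ~feature, ~pca, ~proposed,
    "SVP", 2.4, 2.6,
    "VP_B", 1.6, 2.0,
    "VP_C", 1.6, 2.0,
    "AP_A", 1.2, 1.9,
    "AP_B", 1.1, 1.8,
    "AP_C", 0.5, 1.3,
    "SM", 1.3, 1.6
  )
  for (i in seq_len(nrow(printed))) {
    row <- gs[gs$feature == printed$feature[i], ]
    expect_equal(row$mean[row$method == "pca"], printed$pca[i])
    expect_equal(row$mean[row$method == "proposed"], printed$proposed[i])
  }

  # single subject, single grader: the average is the value itself
  single <- tibble::tibble(subject = 1, feature = "SVP", method = "pca",
                           grader = "G1", value = 4)
  expect_equal(grader_table_summary(single)$mean, 4)

  bad <- tab
  bad$value[1] <- NA
  expect_error(grader_table_summary(bad), class = "rp_invalid_argument")
})

test_that("trend tables round-trip through CSV", {
  tr <- tibble::tibble(subject = 1L, vessel_id = 1L,
                       vessel_class = "venule", phase = 1:8,
                       diameter_um = rnorm(8, 110, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trends_csv(tr, f)
  back <- read_trends_csv(f)
  expect_equal(back$diameter_um, tr$diameter_um)
  expect_equal(back$vessel_class, tr$vessel_class)
})
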