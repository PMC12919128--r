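test_that("anchored series construction adds onset/death anchors and sorts", {
  s <- build_anchored_series(12, 36, death_month = 30)
  expect_equal(s$points$month, c(0, 12, 30))
  expect_equal(s$points$score, c(48, 36, 0))
  s2 <- build_anchored_series(death_month = 24)
  expect_equal(s2$points$month, c(0, 24))
  expect_equal(s2$points$score, c(48, 0))
  # duplicate timestamps are averaged
  s3 <- build_anchored_series(c(6, 6), c(40, 44))
  expect_equal(s3$points$score, c(48, 42))
  expect_error(build_anchored_series(-2, 40), "before disease onset")
  expect_error(build_anchored_series(3, 50), "outside")
})

test_that("time to threshold interpolates the first descending crossing", {
  s <- build_anchored_series(12, 36, death_month = 30)
  expect_equal(time_to_threshold(s, 24)$t, 18)
  # exact hit at a visit returns the visit time
  hit <- build_anchored_series(10, 24, death_month = 40)
  expect_equal(time_to_threshold(hit, 24)$t, 10)
  expect_equal(time_to_threshold(hit, 24)$segment, 0L)
  # never crosses, no death anchor: undefined
  open <- build_anchored_series(12, 40)
  expect_true(is.na(time_to_threshold(open, 24)$t))
  expect_error(time_to_threshold(s, 49), "outside")
})

test_that("noiseless linear trajectories match the closed form survival*(48-i)/48", {
  set.seed(3)
  for (surv in c(18, 30.5, 64)) {
    months <- seq(3, surv - 1, by = 3)
    scores <- 48 * (1 - months / surv)
    s <- build_anchored_series(months, scores, death_month = surv)
    for (i in c(3, 12, 24, 40, 45)) {
      expect_equal(time_to_threshold(s, i)$t, surv * (48 - i) / 48,
                   tolerance = 1e-9)
    }
  }
})

test_that("threshold times are monotone in the threshold and in the death anchor", {
  set.seed(21)
  for (rep in 1:10) {
    surv <- stats::runif(1, 20, 50)
    months <- seq(3, surv - 1, by = 3)
    scores <- pmax(0, pmin(48, 48 * (1 - months / surv) + stats::rnorm(length(months), 0, 2)))
    scores <- rev(sort(scores))            # enforce a monotone trajectory
    s <- build_anchored_series(months, scores, death_month = surv)
    tt <- vapply(45:3, function(i) time_to_threshold(s, i)$t, numeric(1))
    expect_true(all(diff(tt[!is.na(tt)]) >= 0))  # lower threshold hit later
    # adding a death anchor never delays any crossing
    s_open <- build_anchored_series(months, scores)
    for (i in c(10, 24, 40)) {
      t_open <- time_to_threshold(s_open, i)$t
      t_anch <- time_to_threshold(s, i)$t
      if (!is.na(t_open)) expect_lte(t_anch, t_open)
    }
  }
})

test_that("threshold table drops undefined times before trimming", {
  series <- c(
    lapply(1:20, function(k) build_anchored_series(death_month = 2 * k, id = paste0("p", k))),
    list(build_anchored_series(6, 40, id = "open")))   # undefined at 24
  tab <- threshold_table(series, 24, trim_frac = 0.05)
  expect_equal(nrow(tab), 18)          # 20 defined, 1 trimmed per tail
  expect_false("open" %in% tab$id)
  expect_error(threshold_table(series[21], 24), "fewer than 3")
})

test_that("group trajectories order groups by planted decline speed", {
  set.seed(17)
  series <- list(); groups <- integer(0)
  for (code in 0:2) {
    for (j in 1:40) {
      surv <- 10^(stats::rnorm(1, log10(30) + 0.08 * code, 0.1))
      months <- seq(3, surv, by = 3); months <- months[months < surv]
      scores <- pmax(0, pmin(48, 48 * (1 - months / surv) + stats::rnorm(length(months), 0, 2)))
      series[[length(series) + 1]] <- build_anchored_series(months, scores,
                                                            death_month = surv)
      groups <- c(groups, code)
    }
  }
  gt <- group_trajectories(series, groups, thresholds = 24)
  expect_equal(gt$group, 0:2)
  expect_true(all(diff(gt$mean) > 0))  # slower decline for higher code
  expect_true(all(gt$se >= 0))
  expect_error(group_trajectories(series, groups, thresholds = 50), "outside")
})

test_that("identical patients give zero standard error at every threshold", {
  series <- lapply(1:5, function(k) build_anchored_series(death_month = 30))
  gt <- group_trajectories(series, rep(1, 5), thresholds = c(12, 24, 36),
                           trim_frac = 0)
  expect_true(all(gt$se == 0))
})

test_that("threshold scan detects a planted effect and rejects bad thresholds", {
  set.seed(29)
  series <- list(); codes <- integer(0)
  for (code in 0:3) {
    for (j in 1:50) {
      surv <- 10^(stats::rnorm(1, log10(30) + 0.06 * code, 0.15))
      months <- seq(3, surv, by = 3); months <- months[months < surv]
      scores <- pmax(0, pmin(48, 48 * (1 - months / surv) + stats::rnorm(length(months), 0, 2)))
      series[[length(series) + 1]] <- build_anchored_series(months, scores,
                                                            death_month = surv)
      codes <- c(codes, code)
    }
  }
  scan <- threshold_scan(series, codes, thresholds = seq(9, 45, by = 4))
  expect_true(mean(scan$p < 0.05, na.rm = TRUE) >= 0.8)
  expect_true(all(scan$slope[!is.na(scan$slope)] > 0))
  expect_error(threshold_scan(series, codes, thresholds = c(24, 48)), "within")
  expect_error(threshold_scan(series, rep(1, length(series))), "2 subgroups")
})
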