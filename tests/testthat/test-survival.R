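test_that("Turnbull intervals match the brute-force clique oracle", {
  # hand cases
  expect_equal(turnbull_intervals(data.frame(left = c(3, 3), right = c(6, 6))),
               data.frame(left = 3, right = 6))
  expect_equal(turnbull_intervals(data.frame(left = c(0, 3), right = c(3, 6))),
               data.frame(left = c(0, 3), right = c(3, 6)))
  # exact deaths + right-censoring: support sits on the exact times
  rec <- data.frame(left = c(5, 9, 2, 2), right = c(5, 9, Inf, Inf))
  expect_equal(turnbull_intervals(rec),
               data.frame(left = c(5, 9), right = c(5, 9)))
  # randomized cases against the independent oracle
  set.seed(42)
  for (k in 1:30) {
    rec <- random_records(sample(3:12, 1))
    got <- turnbull_intervals(rec)
    want <- brute_turnbull(rec)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = paste("case", k))
  }
})

test_that("NPMLE masses are a distribution and the EM ascends", {
  set.seed(7)
  for (k in 1:10) {
    rec <- random_records(sample(5:40, 1))
    fit <- npmle_fit(rec)
    expect_true(all(fit$masses >= -1e-12))
    expect_equal(sum(fit$masses), 1, tolerance = 1e-10)
    expect_true(all(diff(fit$loglik) >= -1e-10))
    s <- survival_at(fit, seq(0, 15, by = 0.5))
    expect_true(all(diff(s) <= 1e-12))  # non-increasing
    band <- survival_band(fit, seq(0, 15, by = 0.5))
    expect_true(all(band$lower <= band$upper + 1e-12))
  }
})

test_that("NPMLE equals the product-limit estimator without interval censoring", {
  skip_if_not_installed("survival")
  # exact deaths + right-censoring
  set.seed(11)
  t <- round(rexp(80, 1 / 20), 1)
  cens <- t > 35
  rec <- data.frame(left = ifelse(cens, 35, t), right = ifelse(cens, Inf, t))
  fit <- npmle_fit(rec)
  km <- survival::survfit(survival::Surv(pmin(t, 35), !cens) ~ 1)
  ts <- sort(unique(rec$left[!cens]))
  expect_equal(survival_at(fit, ts), summary(km, times = ts)$surv,
               tolerance = 1e-8)
  # non-overlapping grid intervals reduce to the grouped product-limit curve
  rec2 <- gen_interval_survival(median = 30, n = 150, study_end = 60, seed = 3)
  fit2 <- npmle_fit(rec2)
  dd <- is.finite(rec2$right)
  km2 <- survival::survfit(
    survival::Surv(ifelse(dd, rec2$right, rec2$left), dd) ~ 1)
  ts2 <- sort(unique(rec2$right[dd]))
  expect_equal(survival_at(fit2, ts2), summary(km2, times = ts2)$surv,
               tolerance = 1e-8)
})

test_that("degenerate record sets behave as stated", {
  # all deaths exactly at day 5: survival 1 before, 0 after
  rec <- data.frame(left = rep(5, 4), right = rep(5, 4))
  fit <- npmle_fit(rec)
  expect_equal(survival_at(fit, c(4.9, 5, 6)), c(1, 0, 0))
  med <- median_survival(rec, n_boot = 100, seed = 1)
  expect_equal(med$median, 5)
  expect_equal(med$sd, 0)
  # a single record carries all the mass on its interval
  fit1 <- npmle_fit(data.frame(left = 3, right = 6))
  expect_equal(fit1$masses, 1)
  expect_equal(fit1$intervals, data.frame(left = 3, right = 6))
  expect_error(npmle_fit(data.frame(left = numeric(0), right = numeric(0))),
               "empty")
  expect_error(validate_interval_records(data.frame(left = 5, right = 4)))
})

test_that("median recovery on a 3-day inspection grid", {
  rec <- gen_interval_survival(median = 30, n = 300, study_end = 120, seed = 1)
  expect_true(all(rec$left[is.finite(rec$right)] + 3 ==
                    rec$right[is.finite(rec$right)]))
  med <- median_survival(rec, n_boot = 200, seed = 2)
  expect_gte(med$median, 27)
  expect_lte(med$median, 33)
  expect_true(med$ci_low <= med$median && med$median <= med$ci_high)
  # heavy censoring: median unestimable
  rec_c <- gen_interval_survival(median = 300, n = 30, study_end = 30, seed = 4)
  expect_error(median_survival(rec_c, n_boot = 0), "unestimable")
  # n_boot = 0 gives the point estimate only
  med0 <- median_survival(rec, n_boot = 0)
  expect_null(med0$sd)
})

test_that("permutation curve comparison is calibrated and separates groups", {
  a <- gen_interval_survival(median = 30, n = 200, group = "wt", seed = 5)
  # identical groups: statistic 0, p = 1
  same <- curve_difference_test(a, a, n_perm = 19, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # well-separated groups: small p
  b <- gen_interval_survival(median = 53, n = 200, group = "pgsit", seed = 6)
  sep <- curve_difference_test(a, b, n_perm = 999, seed = 1)
  expect_gt(sep$statistic, 0)
  expect_lt(sep$p_value, 0.01)
  sep2 <- curve_difference_test(a, b, n_perm = 999, seed = 1)
  expect_identical(sep$p_value, sep2$p_value)
  expect_error(curve_difference_test(a, b, n_perm = 0), "n_perm")
})

test_that("interval records round-trip through CSV with censoring markers", {
  rec <- gen_interval_survival(median = 20, n = 25, study_end = 30, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- rec
  out$right <- ifelse(is.finite(out$right), out$right, "inf")
  utils::write.csv(out, path, row.names = FALSE)
  back <- read_interval_csv(path)
  expect_equal(back$left, rec$left)
  expect_equal(back$right, rec$right)
})
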