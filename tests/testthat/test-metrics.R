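test_that("accuracy formulas match their closed forms", {
  expect_equal(total_accuracy(21, 37, 12), 84)
  expect_equal(total_accuracy(24, 37, 0), 100 * 24 / 37, tolerance = 1e-12)
  expect_equal(total_accuracy(0, 10, 0), 0)
  expect_true(is.na(total_accuracy(0, 5, 5)))
  expect_error(total_accuracy(10, 5, 0), "n_correct")
  expect_error(total_accuracy(3, 5, 6), "n_missing")

  expect_equal(predictive_power(21, 37), 100 * 21 / 37, tolerance = 1e-12)
  expect_equal(predictive_power(37, 37), 100)
  expect_error(predictive_power(1, 0), "positive")
})

test_that("total accuracy never falls below predictive power", {
  set.seed(42)
  for (i in 1:50) {
    n_all <- sample(5:50, 1)
    n_missing <- sample(0:(n_all - 1), 1)
    n_correct <- sample(0:(n_all - n_missing), 1)
    ta <- total_accuracy(n_correct, n_all, n_missing)
    pp <- predictive_power(n_correct, n_all)
    expect_gte(ta, pp)
    if (n_missing == 0) expect_equal(ta, pp)
  }
})

test_that("fold error is the absolute log10 ratio", {
  expect_equal(fold_error(1.68, 1.88), abs(log10(1.88 / 1.68)))
  expect_lt(abs(fold_error(1.68, 1.88) - 0.0489), 1e-4)
  expect_equal(fold_error(0.154, 45.7), log10(45.7 / 0.154))
  expect_equal(fold_error(5, 5), 0)
  expect_equal(fold_error(1, -84), Inf)
  expect_true(is.na(fold_error(1, NA_real_)))
  expect_error(fold_error(0, 1), "positive")
})

test_that("fold accuracy counts non-positive predictions as failures", {
  pairs <- make_pairs(c(1, 1, 1, 1), c(1.5, 500, -2, NA))
  # of 3 non-missing: 1.5 within 10x, 500 not, -2 never
  expect_equal(fold_accuracy(pairs, 10), 100 / 3)
  expect_equal(fold_accuracy(pairs, 1000), 200 / 3)
  expect_true(is.na(fold_accuracy(make_pairs(1, NA_real_), 10)))
})

test_that("fold accuracy is non-decreasing in the factor", {
  set.seed(7)
  pairs <- make_pairs(10^runif(50, -2, 3),
                      10^runif(50, -3, 4))
  vals <- vapply(c(10, 100, 1000, 1e6), function(f) fold_accuracy(pairs, f),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[4], 100) # all predictions positive here
})

test_that("rmse matches closed forms and recovers a generating sigma", {
  expect_equal(rmse_log10(make_pairs(c(2, 5), c(2, 5))), 0)
  expect_equal(rmse_log10(make_pairs(c(1, 1), c(10, 0.1))), 1)
  set.seed(301)
  n <- 10000
  exp_lc50 <- 10^runif(n, -2, 3)
  pred <- 10^(log10(exp_lc50) + rnorm(n, 0, 0.5))
  est <- rmse_log10(make_pairs(exp_lc50, pred))
  expect_lt(abs(est - 0.5), 0.02)
})

test_that("r_squared is squared Pearson correlation with guard rails", {
  x <- 1:10
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_equal(r_squared(x, -x), 1)
  expect_true(is.na(r_squared(x, rep(3, 10))))
  expect_true(is.na(r_squared(c(1, 2), c(3, 4))))
  set.seed(99)
  expect_lt(r_squared(rnorm(10000), rnorm(10000)), 0.01)
})

test_that("error distribution recovers location and scale", {
  d0 <- error_distribution(make_pairs(c(1, 2), c(1, 2)))
  expect_equal(d0$mean, 0)
  expect_equal(d0$sd, 0)
  expect_equal(d0$n, 2L)
  d1 <- error_distribution(make_pairs(c(1, 1), c(10, 0.1)))
  expect_equal(d1$mean, 0)
  expect_equal(d1$sd, sqrt(2), tolerance = 1e-12)
  set.seed(17)
  n <- 5000
  exp_lc50 <- 10^runif(n, -1, 2)
  pred <- 10^(log10(exp_lc50) + 0.3 + rnorm(n, 0, 0.2))
  d2 <- error_distribution(make_pairs(exp_lc50, pred))
  expect_lt(abs(d2$mean - 0.3), 3 * 0.2 / sqrt(n))
  expect_lt(abs(d2$sd - 0.2), 0.015)
  expect_equal(d2$n, n)
})

test_that("evaluate_tool fills a coherent report", {
  pairs <- make_pairs(
    exp_lc50 = c(1.68, 0.154, 5, 20, 300),
    pred_lc50 = c(1.88, 45.7, NA, 15, 500),
    ad_status = c("inside", "inside", "unknown", "outside", "inside")
  )
  rep_all <- evaluate_tool(pairs, "entire")
  expect_equal(rep_all$n_all, 5L)
  expect_equal(rep_all$n_missing, 1L)
  expect_equal(rep_all$n_correct, 3L)
  expect_equal(rep_all$n_incorrect, 1L)
  expect_equal(rep_all$n_correct + rep_all$n_incorrect + rep_all$n_missing,
               rep_all$n_all)
  expect_equal(rep_all$total_accuracy_pct, 75)
  expect_equal(rep_all$predictive_power_pct, 60)

  rep_ad <- evaluate_tool(pairs, "inside_ad")
  expect_equal(rep_ad$n_inside_ad, 3L)
  expect_equal(rep_ad$n_used, 3L)
  expect_true(is.na(rep_ad$predictive_power_pct))
  expect_error(evaluate_tool(pairs[0, ], "entire"), "at least one")
})

test_that("inside-AD evaluation equals entire when everything is inside", {
  set.seed(5)
  pairs <- make_pairs(10^runif(30, -2, 3), 10^runif(30, -2, 3))
  a <- evaluate_tool(pairs, "entire")
  b <- evaluate_tool(pairs, "inside_ad")
  for (col in c("n_correct", "n_incorrect", "n_missing", "fold10_pct",
                "fold100_pct", "rmse_log10", "r2_log10", "error_mean",
                "total_accuracy_pct")) {
    expect_equal(a[[col]], b[[col]], info = col)
  }
})

test_that("fold-10 accuracy matches the analytic normal-error value", {
  # with log10 errors ~ N(0, s), P(|err| <= 1) = 2*pnorm(1/s) - 1
  set.seed(2024)
  n <- 10000
  for (s in c(0.5, 1)) {
    exp_lc50 <- 10^runif(n, -2, 3)
    pred <- 10^(log10(exp_lc50) + rnorm(n, 0, s))
    p <- 2 * pnorm(1 / s) - 1
    se <- sqrt(p * (1 - p) / n)
    got <- fold_accuracy(make_pairs(exp_lc50, pred), 10) / 100
    expect_lt(abs(got - p), 3 * se)
  }
})
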