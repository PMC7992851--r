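test_that("category building matches functional-group sets", {
  target <- make_target(functional_groups = "aryl;phenol")
  db <- make_analogues(
    log_kow = c(1, 2, 3),
    lc50 = c(5, 6, 7),
    groups = c("aryl;phenol", "aryl", "phenol;aryl")
  )
  got <- build_category(target, db)
  expect_equal(got$cas, c("A-001", "A-003")) # order-insensitive set equality
  # subset mode accepts supersets of the target's groups
  db2 <- make_analogues(log_kow = 1, lc50 = 2, groups = "aryl;ester;phenol",
                        cas = "A-009")
  expect_equal(nrow(build_category(target, db2, mode = "subset")), 1L)
  expect_equal(nrow(build_category(target, db2, mode = "strict")), 0L)
  # the target itself is excluded by CAS
  db3 <- make_analogues(log_kow = c(1, 2), lc50 = c(5, 6),
                        cas = c("T-1", "A-002"))
  expect_equal(build_category(make_target(cas = "T-1"), db3)$cas, "A-002")
  expect_equal(nrow(build_category(target, db[0, ])), 0L)
})

test_that("category AD requires Kow coverage and group inclusion", {
  analogues <- make_analogues(log_kow = c(1.5, 3.0), lc50 = c(1, 2),
                              groups = "aryl;phenol")
  expect_equal(category_ad_check(make_target(log_kow = 2), analogues),
               "inside")
  expect_equal(category_ad_check(make_target(log_kow = 5), analogues),
               "outside")
  tgt <- make_target(log_kow = 2, functional_groups = "aryl;nitrile")
  expect_equal(category_ad_check(tgt, analogues), "outside")
})

test_that("category AD is monotone under added analogues", {
  set.seed(23)
  for (i in 1:20) {
    a1 <- make_analogues(log_kow = runif(4, 0, 3), lc50 = 10^rnorm(4),
                         groups = sample(c("aryl", "aryl;phenol"), 4, TRUE))
    extra <- make_analogues(log_kow = runif(2, -2, 6), lc50 = 10^rnorm(2),
                            groups = sample(c("phenol", "nitrile;aryl"), 2,
                                            TRUE),
                            cas = c("X-1", "X-2"))
    tgt <- make_target(log_kow = runif(1, -1, 4),
                       functional_groups = "aryl;phenol")
    before <- category_ad_check(tgt, a1)
    after <- category_ad_check(tgt, dplyr::bind_rows(a1, extra))
    if (before == "inside") expect_equal(after, "inside")
  }
})

test_that("read-across averages the k nearest analogues by log Kow", {
  tgt <- make_target(log_kow = 2)
  flat <- make_analogues(log_kow = seq(1, 3, length.out = 5),
                         lc50 = rep(2, 5))
  expect_equal(read_across(tgt, flat)$lc50, 2)
  two <- make_analogues(log_kow = c(1.9, 2.1), lc50 = c(1, 100))
  expect_equal(read_across(tgt, two, k = 2)$lc50, 10) # geometric mean
  expect_equal(read_across(tgt, two, k = 2, averaging = "arithmetic")$lc50,
               50.5)
  expect_true(is.na(read_across(tgt, two[0, ])$lc50))
})

test_that("read-across agrees with a brute-force nearest-neighbour oracle", {
  set.seed(31)
  for (rep in 1:10) {
    db <- make_analogues(log_kow = runif(40, 0, 6),
                         lc50 = 10^(2 - 0.7 * runif(40, 0, 6)))
    tgt <- make_target(log_kow = runif(1, 1, 5))
    # oracle: sort by distance, take 5, geometric mean
    d <- abs(db$log_kow - tgt$log_kow)
    sel <- db[order(d, db$cas)[1:5], ]
    oracle <- 10^mean(log10(sel$lc50))
    got <- read_across(tgt, db)
    expect_equal(got$lc50, oracle)
    expect_equal(sort(got$analogue_ids[[1]]), sort(sel$cas))
    # prediction bounded by the selected analogues' values
    expect_gte(got$lc50, min(sel$lc50))
    expect_lte(got$lc50, max(sel$lc50))
  }
})

test_that("trend analysis recovers a noiseless line exactly", {
  db <- make_analogues(log_kow = c(0, 1, 2, 3, 4),
                       lc50 = 10^(2 - 0.8 * c(0, 1, 2, 3, 4)))
  got <- trend_analysis(make_target(log_kow = 2.5), db)
  expect_equal(got$slope, -0.8, tolerance = 1e-10)
  expect_equal(got$intercept, 2, tolerance = 1e-10)
  expect_equal(got$r2, 1, tolerance = 1e-10)
  expect_equal(got$lc50, 10^(2 - 0.8 * 2.5), tolerance = 1e-8)
  expect_equal(got$ad_status, "inside")
})

test_that("trend analysis requires three analogues with Kow spread", {
  two <- make_analogues(log_kow = c(1, 2), lc50 = c(5, 2))
  expect_true(is.na(trend_analysis(make_target(), two)$lc50))
  flatkow <- make_analogues(log_kow = rep(2, 5), lc50 = 1:5)
  expect_true(is.na(trend_analysis(make_target(), flatkow)$lc50))
})

test_that("linear-space trend can extrapolate below zero, log-space cannot", {
  db <- make_analogues(log_kow = 1:5, lc50 = c(100, 80, 55, 30, 10))
  far <- make_target(log_kow = 9)
  lin <- trend_analysis(far, db, space = "linear")
  expect_lt(lin$lc50, 0)
  expect_equal(lin$ad_status, "outside")
  logd <- trend_analysis(far, db)
  expect_gt(logd$lc50, 0)
})

test_that("outlier handling is explicit and suggestions find a planted outlier", {
  db <- make_analogues(log_kow = seq(0, 5, length.out = 12),
                       lc50 = 10^(2 - 0.7 * seq(0, 5, length.out = 12)))
  # plant an analogue 100-fold off the line
  db$lc50[6] <- db$lc50[6] * 100
  flagged <- flag_outliers(db)
  expect_equal(flagged, db$cas[6])
  kept <- remove_outliers(db, exclude = flagged)
  expect_equal(nrow(kept), 11L)
  expect_false(db$cas[6] %in% kept$cas)
  # empty exclusion is the identity
  expect_equal(remove_outliers(db), db)
})

test_that("solubility screen compares LC50 against water solubility", {
  expect_equal(solubility_check(68, 0.106), "implausible")
  expect_equal(solubility_check(0.0356, 0.047), "plausible")
  expect_equal(solubility_check(5, 5), "plausible") # strict inequality
  expect_equal(solubility_check(5, NA), "unknown")
  expect_error(solubility_check(-1, 2), "positive")
})

test_that("the packaged solubility table reproduces the screen's verdicts", {
  sol <- readr::read_csv(ecotox_fixture("solubility"),
                         show_col_types = FALSE)
  verdict <- solubility_check(sol$exp_lc50, sol$water_solubility)
  # strict rule: LC50 above solubility cannot be realised in test medium
  expect_equal(sol$name[verdict == "implausible"],
               c("Musk xylene",
                 "Heptadecafluorooctanesulfonic acid",
                 "Pentadecafluorooctanoic acid"))
  # the two perfluorinated acids exceed solubility by orders of magnitude
  ratio <- sol$exp_lc50 / sol$water_solubility
  expect_true(all(ratio[grepl("fluoro", sol$name)] > 100))
})
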