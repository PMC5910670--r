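test_that("pre-dose normalization rescales each animal to 100 at baseline", {
  recs <- data.frame(group = "g", animal = rep(c("m1", "m2"), each = 2),
                     day = c(0, 7, 0, 7), value = c(50, 25, 80, 80))
  out <- normalize_to_predose(recs)
  expect_equal(out$value, c(100, 50, 100, 100))

  const <- data.frame(group = "g", animal = "m1", day = c(0, 7, 14),
                      value = c(3.2, 3.2, 3.2))
  expect_equal(normalize_to_predose(const)$value, rep(100, 3))

  bad <- data.frame(group = "g", animal = "m1", day = c(0, 7), value = c(0, 10))
  expect_error(normalize_to_predose(bad), "m1", class = "chemmap_domain_error")
  expect_error(normalize_to_predose(recs[recs$day != 0, ]),
               class = "chemmap_domain_error")
})

test_that("semilog EC fits invert exactly on closed-form lines", {
  x <- c(1, 10, 100)
  fit <- fit_semilog_ec(x, 20 + 30 * log10(x))
  expect_equal(fit$ec50, 10, tolerance = 1e-10)
  expect_equal(fit$ec80, 100, tolerance = 1e-10)
  expect_equal(unname(coef(fit)), c(20, 30), tolerance = 1e-12)
  expect_false(any(fit$extrapolated))

  # EC beyond the observed loading range is flagged as extrapolated
  fit2 <- fit_semilog_ec(c(100, 1000, 10000), 20 + 30 * log10(c(100, 1000, 10000)))
  expect_true(fit2$extrapolated[["ec50"]])
})

test_that("EC fit inversion identity: refitting regenerated points reproduces a and b", {
  set.seed(12)
  x <- 10^runif(8, -2, 1)
  fit <- fit_semilog_ec(x, 40 + 25 * log10(x) + rnorm(8))
  refit <- fit_semilog_ec(x, predict(fit, x))
  expect_equal(refit$a, fit$a, tolerance = 1e-10)
  expect_equal(refit$b, fit$b, tolerance = 1e-10)
})

test_that("degenerate EC inputs are rejected", {
  expect_error(fit_semilog_ec(c(1, 1, 1), c(10, 20, 30)), class = "chemmap_domain_error")
  expect_error(fit_semilog_ec(c(1, 10), c(10, 20)), class = "chemmap_domain_error")
  expect_error(fit_semilog_ec(c(0, 1, 10), c(1, 2, 3)), class = "chemmap_domain_error")
  expect_error(fit_semilog_ec(c(1, 10, 100), c(5, 5, 5)), class = "chemmap_ec_undefined")
})

test_that("the extra-sum-of-squares F-test is degenerate on identical groups", {
  x <- c(1, 3, 10, 30, 100)
  y <- 10 + 20 * log10(x) + c(0.3, -0.2, 0.1, -0.3, 0.1)
  res <- ess_f_test(rep(x, 2), rep(y, 2), rep(c("a", "b"), each = 5))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
})

test_that("the F-test separates lines with different slopes and stays non-negative", {
  reject <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    x <- rep(10^seq(-1, 1, length.out = 10), 2)
    g <- rep(c("a", "b"), each = 10)
    y <- ifelse(g == "a", 10 + 30 * log10(x), 10 + 60 * log10(x)) + rnorm(20, 0, 2)
    res <- ess_f_test(x, y, g)
    expect_gte(res$statistic, 0)
    res$p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})

test_that("baseline AUC worked cases", {
  expect_equal(auc_vs_baseline(0:3, rep(100, 4)), 0)
  expect_equal(auc_vs_baseline(0:3, c(100, 50, 50, 100)), 100)
  # sub-threshold dip: depth 3 against a 40-unit range is ignored
  days <- c(0, 5, 10, 15, 20, 25)
  vals <- c(100, 60, 100, 97, 100, 100)
  with_dip <- auc_vs_baseline(days, vals)
  no_dip <- auc_vs_baseline(days[-4], vals[-4])
  expect_equal(with_dip, no_dip)
  # ... but a deep second dip does contribute
  vals2 <- c(100, 60, 100, 80, 100, 100)
  expect_gt(auc_vs_baseline(days, vals2), no_dip)
  # excursions above baseline also count positively
  expect_equal(auc_vs_baseline(0:2, c(100, 140, 100)), 40)
  expect_error(auc_vs_baseline(c(0, 2, 1), c(100, 90, 95)),
               class = "chemmap_domain_error")
})

test_that("AUC is invariant to piecewise-linear refinement and scales linearly", {
  days <- c(0, 2, 6, 10)
  vals <- c(100, 70, 70, 100)
  base <- auc_vs_baseline(days, vals)
  # insert points lying exactly on existing segments
  refined_days <- c(0, 1, 2, 4, 6, 8, 10)
  refined_vals <- c(100, 85, 70, 70, 70, 85, 100)
  expect_equal(auc_vs_baseline(refined_days, refined_vals), base)
  # doubling deviations doubles the area (single peak, no threshold change)
  expect_equal(auc_vs_baseline(days, 100 + 2 * (vals - 100)), 2 * base)
})

test_that("recovery slopes are exact on exact lines and compared correctly", {
  recs <- expand.grid(group = c("g1", "g2"), day = seq(29, 71, by = 7))
  recs$value <- ifelse(recs$group == "g1", 10 + 1 * recs$day, 5 + 2 * recs$day)
  out <- recovery_slope_compare(recs)
  expect_equal(unname(out$slopes["g1"]), 1, tolerance = 1e-10)
  expect_equal(unname(out$slopes["g2"]), 2, tolerance = 1e-10)
  expect_equal(out$difference, 1, tolerance = 1e-10)
  expect_lt(out$test$p, 0.05)

  same <- transform(recs, value = 10 + recs$day)
  out2 <- recovery_slope_compare(same)
  expect_equal(out2$difference, 0, tolerance = 1e-10)
  expect_equal(out2$test$p, 1)
})

test_that("the day window is inclusive and sparse groups are named in errors", {
  recs <- data.frame(group = rep(c("a", "b"), each = 3),
                     day = rep(c(29, 50, 71), 2), value = rnorm(6, 50, 1))
  out <- recovery_slope_compare(recs, day_window = c(29, 71))
  expect_equal(out$n, 6) # endpoints retained
  expect_error(recovery_slope_compare(recs, day_window = c(30, 70)), "fewer than 3")
})

test_that("slope-difference sign is recovered under realistic noise", {
  ok <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    grid <- expand.grid(group = c("parent", "dv"), day = seq(29, 71, by = 7),
                        animal = 1:3)
    grid$value <- ifelse(grid$group == "parent",
                         20 + 0.9 * grid$day, 10 + 0.6 * grid$day) +
      rnorm(nrow(grid), 0, 3)
    out <- recovery_slope_compare(grid)
    out$slopes[["parent"]] > out$slopes[["dv"]]
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("Sidak adjustment closed forms", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.01, 3), 0.029701)
  expect_equal(sidak_adjust(1, 5), 1)
})

test_that("two-way ANOVA decomposes effects and a single Dunnett comparison matches the t-test", {
  set.seed(55)
  grid <- expand.grid(design = c("ctrl", "dv"), time = c(7, 22), rep = 1:4)
  grid$value <- 60 + ifelse(grid$design == "dv", -15, 0) +
    ifelse(grid$time == 22, 10, 0) + rnorm(nrow(grid), 0, 8)
  out <- anova2_posttests(grid, control = "ctrl", post = "dunnett",
                          seed = 17, n_draws = 2e5)
  expect_setequal(out$anova$term, c("time", "design", "time:design", "Residuals"))
  expect_true(out$balanced)
  # with one comparison per time, Monte Carlo max-|t| is just |t|:
  # the adjusted p matches the pooled-variance two-sided t p
  expect_lt(max(abs(out$comparisons$p_adjusted - out$comparisons$p_unadjusted)),
            0.005)
})

test_that("Dunnett-adjusted p-values are never below unadjusted ones", {
  set.seed(56)
  grid <- expand.grid(design = c("ctrl", "dv18", "dv22", "ome"),
                      time = c(7, 22), rep = 1:3)
  grid$value <- 50 + ifelse(grid$design == "dv18", -12, 0) +
    rnorm(nrow(grid), 0, 10)
  out <- anova2_posttests(grid, control = "ctrl", post = "dunnett", seed = 18)
  expect_true(all(out$comparisons$p_adjusted >= out$comparisons$p_unadjusted))
  expect_true(all(out$comparisons$p_adjusted <= 1))
})

test_that("Sidak post-tests and input guards behave", {
  set.seed(57)
  grid <- expand.grid(group = c("parent", "dv"), day = c(8, 22, 43), rep = 1:3)
  grid$value <- 70 + ifelse(grid$group == "dv", -20, 0) + rnorm(nrow(grid), 0, 6)
  out <- anova2_posttests(grid, control = "parent", post = "sidak")
  m <- nrow(out$comparisons)
  expect_equal(out$comparisons$p_adjusted,
               pmax(sidak_adjust(out$comparisons$p_unadjusted, m),
                    out$comparisons$p_unadjusted))
  expect_error(anova2_posttests(grid, control = "missing"),
               class = "chemmap_config_error")
  unb <- grid[-1, ]
  expect_warning(anova2_posttests(unb, control = "parent", post = "sidak"),
                 "unbalanced")
})
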