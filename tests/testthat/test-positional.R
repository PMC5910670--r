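# local helper: one screen record from a chemistry pattern
rec_from_pattern <- function(pat, duplex_id, site_id = "s1", species = "mouse",
                             dose = 0.1, replicate = 1, frac = 0.5) {
  chem <- c(pat$sense, pat$antisense)
  names(chem) <- c(paste0("S", 1:21), paste0("AS", 1:23))
  cbind(data.frame(duplex_id = duplex_id, target = "t", site_id = site_id,
                   species = species, dose_nM = dose, replicate = replicate,
                   fraction_remaining = frac, stringsAsFactors = FALSE),
        as.data.frame(as.list(chem), stringsAsFactors = FALSE))
}

test_that("filter_sites keeps sites with enough distinct designs", {
  recs <- data.frame(
    site_id = rep(c("a", "b", "c"), times = c(12, 10, 9)),
    duplex_id = c(paste0("a", 1:12), paste0("b", 1:10), paste0("c", 1:9)))
  kept <- filter_sites(recs, min_designs = 10)
  expect_setequal(unique(kept$site_id), c("a", "b"))
  report <- attr(kept, "site_counts")
  expect_equal(report$n_designs[report$site_id == "c"], 9)
  expect_false(report$kept[report$site_id == "c"])

  expect_identical(nrow(filter_sites(recs, min_designs = 1)), nrow(recs))
  expect_error(filter_sites(recs, min_designs = 13), class = "chemmap_empty_result")
})

test_that("replicate rows of one duplex count as a single design", {
  recs <- data.frame(site_id = "a", duplex_id = rep("d1", 4), replicate = 1:4)
  expect_error(filter_sites(recs, min_designs = 2), class = "chemmap_empty_result")
  report <- tryCatch(filter_sites(recs, min_designs = 2),
                     error = function(e) conditionMessage(e))
  expect_match(report, "a=1")
})

test_that("the design matrix uses 2'-OMe reference coding and ln response", {
  ome <- all_ome_pattern()
  swapped <- ome
  swapped$antisense[5] <- "F"
  recs <- rbind(rec_from_pattern(ome, "d1", frac = 0.5),
                rec_from_pattern(chemistry_pattern(swapped$sense, swapped$antisense),
                                 "d2", frac = 0.25))
  dm <- build_design_matrix(recs)
  expect_equal(dm$y, log(c(0.5, 0.25)))
  # rows differ in exactly one column: the AS5 2'-F indicator
  diffs <- which(dm$X[1, ] != dm$X[2, ])
  expect_equal(colnames(dm$X)[diffs], "AS5")
  # all-OMe row has every chemistry indicator at 0
  chem_cols <- dm$col_map$column[dm$col_map$type == "chemistry"]
  expect_true(all(dm$X[1, chem_cols] == 0))
  # positions constant across records are reported inestimable, not encoded
  expect_setequal(dm$inestimable, setdiff(c(paste0("S", 1:21), paste0("AS", 1:23)), "AS5"))
  # no column encodes PS content
  expect_false(any(grepl("ps", tolower(colnames(dm$X)), fixed = TRUE)))
  expect_error(build_design_matrix(transform(recs, fraction_remaining = -1)),
               class = "chemmap_domain_error")
})

test_that("fit_ols matches exact interpolation and the normal-equations oracle", {
  fit <- suppressWarnings(fit_ols(cbind(a = c(1, 1), b = c(0, 1)), c(1, 3)))
  expect_equal(unname(fit$coefficients), c(1, 2))
  expect_equal(fit$residual_ss, 0)

  set.seed(123)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    p <- sample(1:min(10, n - 1), 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    expect_lt(max(abs(coef(fit_ols(X, y)) - oracle_ols(X, y))), 1e-8)
  }
})

test_that("duplicated columns are dropped with warning, fit unchanged", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- rnorm(20)
  base_fit <- fit_ols(X, y)
  Xd <- cbind(X, x2_copy = X[, 2])
  expect_warning(fit_d <- fit_ols(Xd, y), "rank-deficient")
  expect_equal(fit_d$coefficients[c("x1", "x2")], base_fit$coefficients)
  expect_true(is.na(fit_d$coefficients["x2_copy"]))
  expect_equal(fit_d$residual_ss, base_fit$residual_ss)
})

test_that("saturated fits return coefficients but flag inference unavailable", {
  X <- cbind(a = c(1, 1), b = c(0, 1))
  expect_warning(fit <- fit_ols(X, c(1, 3)), "inference unavailable")
  expect_equal(unname(fit$coefficients), c(1, 2))
  expect_false(fit$inference_available)
  expect_true(all(is.na(fit$se)))
})

test_that("a noise-free screen is recovered exactly with adjusted r-squared 1", {
  cfg <- small_screen_config(noise_sd = 0, seed = 21)
  scr <- gen_screen(cfg)
  pf <- fit_positional(scr, min_designs = 10)
  planted <- attr(scr, "planted")$gamma
  est <- coef(pf)
  expect_equal(est[names(planted)], planted, tolerance = 1e-8)
  expect_equal(pf$fit$adjusted_r2, 1, tolerance = 1e-10)
  expect_lt(pf$fit$residual_ss, 1e-16)
})

test_that("coefficients are invariant to record order and location-equivariant", {
  scr <- gen_screen(small_screen_config(seed = 22))
  pf1 <- fit_positional(scr)
  set.seed(1)
  pf2 <- fit_positional(scr[sample(nrow(scr)), ])
  expect_equal(coef(pf1), coef(pf2), tolerance = 1e-12)

  # scaling all fractions by c shifts only the intercept on the ln scale
  scr3 <- transform(scr, fraction_remaining = fraction_remaining * 2)
  pf3 <- fit_positional(scr3)
  expect_equal(coef(pf1), coef(pf3), tolerance = 1e-10)
  expect_equal(unname(pf3$fit$coefficients["(Intercept)"] -
                        pf1$fit$coefficients["(Intercept)"]),
               log(2), tolerance = 1e-10)
})

test_that("significance flags follow the p < 0.05 rule and sign convention", {
  scr <- gen_screen(screen_sim_config(duplexes_per_site = 40, seed = 23))
  pf <- fit_positional(scr, dose_nM = 0.1)
  m <- pf$map
  expect_identical(m$significant, m$estimable & !is.na(m$p) & m$p < 0.05)
  # planted 2'-F-preferring positions come out negative and significant
  crit <- m[m$label %in% c("AS2", "AS6", "AS14", "S11"), ]
  expect_true(all(crit$significant))
  expect_true(all(crit$delta_ln < 0))
})

test_that("positions with constant chemistry are flagged inestimable", {
  cfg <- small_screen_config(seed = 24)
  scr <- gen_screen(cfg)
  scr$AS23 <- "OMe" # overhang position never varied in this screen
  pf <- fit_positional(scr)
  row <- pf$map[pf$map$label == "AS23", ]
  expect_false(row$estimable)
  expect_true(is.na(row$delta_ln))
  expect_false(row$significant)
  expect_true("AS23" %in% pf$inestimable)
})
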