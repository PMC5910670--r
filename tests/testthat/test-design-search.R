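test_that("predicted activity differences are additive over swapped positions", {
  map <- make_map(c(AS5 = -0.3, S2 = 0.2))
  ref <- all_ome_pattern()
  expect_equal(predict_delta_ln(ref, map, ref), 0)

  one <- all_ome_pattern()
  one$antisense[5] <- "F"
  expect_equal(predict_delta_ln(one, map, ref), -0.3)
  # reverse direction flips the sign
  expect_equal(predict_delta_ln(ref, map, one), 0.3)

  two <- one
  two$sense[2] <- "F"
  expect_equal(predict_delta_ln(two, map, ref), -0.3 + 0.2)
})

test_that("differences at inestimable positions are an error naming the position", {
  map <- make_map(inestimable = "AS23")
  pat <- all_ome_pattern()
  pat$antisense[23] <- "F"
  expect_error(predict_delta_ln(pat, map, all_ome_pattern()), "AS23",
               class = "chemmap_inestimable")
})

test_that("uniformly harmful 2'-F drives the search to the all-OMe pattern", {
  map <- make_map(setNames(rep(0.1, 44), position_labels_vec()))
  parent <- chemistry_pattern(rep("F", 21), rep("F", 23))
  res <- propose_variants(map, design_constraints(), parent,
                          max_predicted_loss = 0)
  expect_equal(res$n_F_total[1], 0)
  # 43 free units exceed the exhaustive limit, so this ran the greedy
  expect_false(attr(res, "exhaustive"))
})

test_that("the search matches brute-force enumeration on eight free positions", {
  labels <- position_labels_vec()
  free <- paste0("S", 1:8)
  fixed_ome <- setdiff(labels, free)
  parent <- all_ome_pattern()
  set.seed(501)
  for (i in 1:20) {
    coefs <- setNames(rnorm(8, 0, 0.2), free)
    map <- make_map(coefs)
    budget <- runif(1, 0, 0.3)
    res <- propose_variants(map,
                            design_constraints(fixed_OMe = fixed_ome,
                                               paired = list()),
                            parent, max_predicted_loss = budget, top_k = 1)
    oracle <- brute_min_F(coefs, budget)
    expect_true(isTRUE(attr(res, "exhaustive")))
    expect_equal(res$n_F_total[1], oracle$n_F)
    expect_equal(res$predicted_delta_ln[1], oracle$delta, tolerance = 1e-10)
  }
})

test_that("every proposal satisfies the fixed and paired constraints", {
  set.seed(88)
  coefs <- setNames(rnorm(44, 0, 0.15), position_labels_vec())
  map <- make_map(coefs)
  parent <- as_chemistry_pattern(reference_designs()$parent)
  cons <- design_constraints(fixed_F = c("AS2", "AS6", "AS14", "S11"),
                             fixed_OMe = paste0("S", c(1, 3, 5)),
                             paired = list(c("AS8", "AS9")))
  res <- propose_variants(map, cons, parent, max_predicted_loss = 0.5,
                          top_k = 10, exhaustive_limit = 0) # greedy path
  # smaller free set for the exhaustive path: freeze most remaining positions
  cons_small <- design_constraints(
    fixed_F = c("AS2", "AS6", "AS14", "S11"),
    fixed_OMe = setdiff(position_labels_vec(),
                        c("AS2", "AS6", "AS8", "AS9", "AS14", "S11",
                          paste0("S", 6:10), "AS16", "AS18", "AS20")),
    paired = list(c("AS8", "AS9")))
  res_ex <- propose_variants(map, cons_small, parent, max_predicted_loss = 0.5,
                             top_k = 10, exhaustive_limit = 12)
  for (r in list(res, res_ex)) {
    for (i in seq_len(nrow(r))) {
      pat <- r$pattern[[i]]
      expect_true(all(pat$antisense[c(2, 6, 14)] == "F"))
      expect_true(all(pat$sense[11] == "F"))
      expect_true(all(pat$sense[c(1, 3, 5)] == "OMe"))
      expect_equal(pat$antisense[8], pat$antisense[9]) # pair rule
      nf <- sum(pat$sense == "F") + sum(pat$antisense == "F")
      expect_equal(nf, r$n_F_total[i])
    }
  }
  expect_false(attr(res, "exhaustive"))
  expect_true(attr(res_ex, "exhaustive"))
})

test_that("greedy search agrees with exhaustive on most random instances", {
  labels <- position_labels_vec()
  free <- c(paste0("S", 1:6), paste0("AS", 1:6))
  fixed_ome <- setdiff(labels, free)
  parent <- all_ome_pattern()
  agree <- vapply(1:100, function(i) {
    set.seed(700 + i)
    coefs <- setNames(rnorm(12, 0, 0.2), free)
    map <- make_map(coefs)
    cons <- design_constraints(fixed_OMe = fixed_ome, paired = list())
    ex <- propose_variants(map, cons, parent, max_predicted_loss = 0.15, top_k = 1)
    gr <- propose_variants(map, cons, parent, max_predicted_loss = 0.15, top_k = 1,
                           exhaustive_limit = 0)
    ex$n_F_total[1] == gr$n_F_total[1]
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("relaxing the loss budget never increases the minimal 2'-F count", {
  set.seed(91)
  coefs <- setNames(rnorm(44, 0, 0.2), position_labels_vec())
  map <- make_map(coefs)
  parent <- as_chemistry_pattern(reference_designs()$parent)
  cons <- design_constraints(fixed_F = c("AS2", "AS6", "AS14", "S11"))
  budgets <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  counts <- vapply(budgets, function(b) {
    propose_variants(map, cons, parent, max_predicted_loss = b, top_k = 1,
                     exhaustive_limit = 0)$n_F_total[1]
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("contradictory constraints raise an infeasibility error listing conflicts", {
  expect_error(design_constraints(fixed_F = "AS2", fixed_OMe = c("AS2", "S1")),
               "AS2", class = "chemmap_infeasible")
  expect_error(design_constraints(fixed_F = "AS8", fixed_OMe = "AS9"),
               class = "chemmap_infeasible")
  expect_error(design_constraints(fixed_F = "S22"), class = "chemmap_domain_error")
})
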