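# Shared fixtures and independent oracles for the test suite.

# Independent OLS oracle: normal equations via solve(), no QR.
oracle_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Random dialect-valid modified strand for round-trip properties.
random_strand <- function(n = sample(3:25, 1)) {
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  sugar <- sample(c("F", "OMe"), n, replace = TRUE)
  k <- sample(0:(n - 1), 1)
  ps <- if (k > 0) sample(seq_len(n - 1), k) else integer()
  conj <- if (stats::runif(1) < 0.3) "GalNAc" else NULL
  modified_strand(bases, sugar, ps_after = ps, conjugate = conj)
}

# Minimal positional map for design-search tests: named coefficient vector
# over the 44 duplex positions (missing names get coefficient 0).
make_map <- function(coefs = numeric(), inestimable = character()) {
  labels <- c(paste0("S", 1:21), paste0("AS", 1:23))
  delta <- stats::setNames(rep(0, 44), labels)
  delta[names(coefs)] <- coefs
  data.frame(strand = c(rep("sense", 21), rep("antisense", 23)),
             position = c(1:21, 1:23), label = labels,
             delta_ln = ifelse(labels %in% inestimable, NA_real_, delta),
             se = 0.01, p = 0.5,
             significant = FALSE,
             estimable = !labels %in% inestimable,
             stringsAsFactors = FALSE)
}

all_ome_pattern <- function() chemistry_pattern(rep("OMe", 21), rep("OMe", 23))

position_labels_vec <- function() c(paste0("S", 1:21), paste0("AS", 1:23))

# Exhaustive oracle for the minimal-2'-F search over m free positions with
# additive coefficients `coefs` (parent all-OMe, so predicted loss of a
# pattern is the sum of coefficients at its 2'-F positions).
brute_min_F <- function(coefs, budget) {
  m <- length(coefs)
  best_nF <- Inf
  best_delta <- Inf
  for (i in 0:(2^m - 1)) {
    bits <- as.logical(bitwAnd(i, 2^(seq_len(m) - 1)))
    d <- sum(coefs[bits])
    if (d <= budget + 1e-12) {
      nf <- sum(bits)
      if (nf < best_nF || (nf == best_nF && d < best_delta)) {
        best_nF <- nf
        best_delta <- d
      }
    }
  }
  list(n_F = best_nF, delta = best_delta)
}

# Small screen config for fast fits.
small_screen_config <- function(noise_sd = 0.3, ..., seed) {
  screen_sim_config(n_targets = 1L, sites_per_target = 2L,
                    duplexes_per_site = 40L, doses_nM = 0.1,
                    replicates = 1L, site_sd = 0.2, target_sd = 0,
                    noise_sd = noise_sd, ..., seed = seed)
}

# Null screen: every planted positional effect zero.
null_screen_config <- function(seed) {
  small_screen_config(gamma_sense = rep(0, 21), gamma_antisense = rep(0, 23),
                      seed = seed)
}
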