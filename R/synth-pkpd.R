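# Synthetic in vivo PK/PD generator.
#
# Knockdown follows a surge-decay curve K(t) = kd_max (1 - e^{-k_on t}) e^{-k_off t}
# (onset, nadir, recovery), mRNA %-of-control is 100 (1 - K(t)) with
# multiplicative lognormal noise, and Ago2-loaded antisense strand satisfies
# the planted semilog law 100 K(t) = a + b log10(L(t)), inverted for L and
# noised on the log scale. The surge-decay form is the simplest curve with
# the observed onset/nadir/recovery phases; it is a modelling invention, not
# an empirical PD equation.

#' Configuration for the synthetic in vivo time course
#'
#' @param kd_max Maximal knockdown fraction in `[0, 1)`.
#' @param k_on,k_off Onset and recovery rate constants (/day), both `> 0`.
#' @param days Sampled days post-dose (day 0 is pre-dose/baseline).
#' @param animals_per_timepoint Animals per group and time point.
#' @param semilog_a,semilog_b Planted knockdown-vs-log10(loading) line:
#'   `% knockdown = a + b * log10(loading ng/g)`; `b` must be non-zero. The
#'   defaults place EC50 near 0.066 ng/g and EC80 near 0.24 ng/g.
#' @param noise_sd_ln SD of lognormal noise on mRNA and loading observations.
#' @param sense_background Background sense-strand Ago2 loading (ng/g);
#'   sense loading is barely detectable and carries no PD signal.
#' @param group Group label for the generated records.
#' @param seed Integer seed.
#' @return A `pkpd_sim_config` list.
#' @export
pkpd_sim_config <- function(kd_max = 0.92, k_on = 1.5, k_off = 0.05,
                            days = c(0, 0.17, 3, 7, 14, 21, 35),
                            animals_per_timepoint = 3L,
                            semilog_a = 113, semilog_b = 53.5,
                            noise_sd_ln = 0.1, sense_background = 0.01,
                            group = "conjugate", seed = 1L) {
  cfg <- list(kd_max = kd_max, k_on = k_on, k_off = k_off, days = sort(days),
              animals_per_timepoint = as.integer(animals_per_timepoint),
              semilog_a = semilog_a, semilog_b = semilog_b,
              noise_sd_ln = noise_sd_ln, sense_background = sense_background,
              group = group, seed = seed)
  if (cfg$kd_max < 0 || cfg$kd_max >= 1) {
    stop_chemmap("kd_max must lie in [0, 1)", "chemmap_config_error")
  }
  if (cfg$k_on <= 0 || cfg$k_off <= 0) {
    stop_chemmap("k_on and k_off must be positive", "chemmap_config_error")
  }
  if (cfg$semilog_b == 0) {
    stop_chemmap("semilog_b = 0: the loading law is not invertible", "chemmap_config_error")
  }
  if (cfg$noise_sd_ln < 0) {
    stop_chemmap("noise_sd_ln must be >= 0", "chemmap_config_error")
  }
  class(cfg) <- "pkpd_sim_config"
  cfg
}

# Planted knockdown fraction at time t (surge-decay).
pkpd_knockdown <- function(t, config) {
  config$kd_max * (1 - exp(-config$k_on * t)) * exp(-config$k_off * t)
}

#' Generate a synthetic in vivo time course with Ago2 loading
#'
#' @param config A [pkpd_sim_config()].
#' @return List with `mrna` (columns `group`, `animal`, `day`, `value` = %
#'   of control mRNA remaining) and `loading` (columns `group`, `animal`,
#'   `day`, `strand`, `loading` in ng strand per g liver). The planted truth
#'   (`kd_max`, rate constants, semilog `a`/`b`) is attached as attribute
#'   `"planted"` of the returned list.
#' @examples
#' tc <- gen_pkpd_timecourse(pkpd_sim_config(noise_sd_ln = 0, seed = 3))
#' head(tc$mrna)
#' @export
gen_pkpd_timecourse <- function(config = pkpd_sim_config()) {
  stopifnot(inherits(config, "pkpd_sim_config"))
  with_seed(config$seed, {
    grid <- expand.grid(animal = seq_len(config$animals_per_timepoint),
                        day = config$days, KEEP.OUT.ATTRS = FALSE)
    K <- pkpd_knockdown(grid$day, config)
    n <- nrow(grid)
    mrna <- data.frame(group = config$group,
                       animal = paste0(config$group, "_a", grid$animal, "_d", grid$day),
                       day = grid$day,
                       value = 100 * (1 - K) * exp(stats::rnorm(n, 0, config$noise_sd_ln)),
                       stringsAsFactors = FALSE)
    # invert the planted semilog law for antisense loading
    L_as <- 10^((100 * K - config$semilog_a) / config$semilog_b)
    loading <- rbind(
      data.frame(group = config$group, animal = mrna$animal, day = grid$day,
                 strand = "antisense",
                 loading = L_as * exp(stats::rnorm(n, 0, config$noise_sd_ln)),
                 stringsAsFactors = FALSE),
      data.frame(group = config$group, animal = mrna$animal, day = grid$day,
                 strand = "sense",
                 loading = config$sense_background *
                   exp(stats::rnorm(n, 0, config$noise_sd_ln)),
                 stringsAsFactors = FALSE))
    out <- list(mrna = mrna, loading = loading)
    attr(out, "planted") <- list(kd_max = config$kd_max, k_on = config$k_on,
                                 k_off = config$k_off, a = config$semilog_a,
                                 b = config$semilog_b)
    out
  })
}
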