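# Synthetic in vitro screen generator with planted ground truth.
#
# The generator emulates the statistical structure the positional model
# assumes: a log-scale additive model of fraction-of-control mRNA remaining,
#   ln(fraction) = mu + dose effect + target effect + site effect
#                  + sum_p gamma_p * I[position p is 2'-F] + eps,
# with eps ~ Normal(0, noise_sd^2), i.e. multiplicative lognormal noise on
# the fraction scale (observations are always strictly positive and the OLS
# model on ln(fraction) is exactly correct under the generator).

# Planted positional effect vectors (natural-log scale, 2'-F minus 2'-OMe).
# Strongly negative entries at AS2, AS6, AS14 and S11 mirror positions with a
# strong preference for 2'-F; AS8/AS9 carry opposite-signed moderate effects;
# all remaining positions are null.
planted_gamma_defaults <- function() {
  gs <- stats::setNames(rep(0, 21), paste0("S", 1:21))
  ga <- stats::setNames(rep(0, 23), paste0("AS", 1:23))
  gs["S11"] <- -0.35
  gs["S6"] <- -0.10
  ga["AS2"] <- -0.35
  ga["AS6"] <- -0.30
  ga["AS14"] <- -0.40
  ga["AS8"] <- 0.15
  ga["AS9"] <- -0.15
  list(sense = gs, antisense = ga)
}

#' Configuration for the synthetic silencing screen
#'
#' Defaults reproduce the screen dimensions the positional model was built
#' for: 5 targets x 3 sites/target x 126 duplexes/site = 1,890 duplexes,
#' transfected at 10 and 0.1 nM in quadruplicate.
#'
#' @param n_targets,sites_per_target,duplexes_per_site Screen dimensions.
#' @param doses_nM Transfection doses (nM); must be non-empty.
#' @param replicates Replicate transfections per duplex and dose.
#' @param gamma_sense,gamma_antisense Planted per-position 2'-F effects on
#'   the natural-log fraction-remaining scale (length 21 / 23).
#' @param mu Baseline ln fraction remaining of an all-2'-OMe duplex at the
#'   reference dose.
#' @param dose_effect Named numeric of ln shifts per dose (names match
#'   `doses_nM`); the reference dose should carry 0.
#' @param site_sd,target_sd SDs of Normal per-site and per-target baseline
#'   effects (ln scale).
#' @param species_labels Cell-line species labels, assigned per target site
#'   (each site lives in one cell line).
#' @param noise_sd Residual SD on the ln scale (multiplicative lognormal on
#'   the fraction scale).
#' @param patterns Optional list of [chemistry_pattern()]s to use (recycled)
#'   instead of uniform random patterns.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_targets = 5L, sites_per_target = 3L,
                              duplexes_per_site = 126L,
                              doses_nM = c(10, 0.1), replicates = 4L,
                              gamma_sense = planted_gamma_defaults()$sense,
                              gamma_antisense = planted_gamma_defaults()$antisense,
                              mu = log(0.6),
                              dose_effect = c("10" = -1, "0.1" = 0),
                              site_sd = 0.25, target_sd = 0.15,
                              species_labels = c("mouse", "human"),
                              noise_sd = 0.3, patterns = NULL, seed = 1L) {
  cfg <- list(n_targets = as.integer(n_targets),
              sites_per_target = as.integer(sites_per_target),
              duplexes_per_site = as.integer(duplexes_per_site),
              doses_nM = doses_nM, replicates = as.integer(replicates),
              gamma_sense = gamma_sense, gamma_antisense = gamma_antisense,
              mu = mu, dose_effect = dose_effect, site_sd = site_sd,
              target_sd = target_sd, species_labels = species_labels,
              noise_sd = noise_sd, patterns = patterns, seed = seed)
  if (length(cfg$doses_nM) == 0L) {
    stop_chemmap("doses_nM must be non-empty", "chemmap_config_error")
  }
  if (any(c(cfg$n_targets, cfg$sites_per_target, cfg$duplexes_per_site,
            cfg$replicates) < 1L)) {
    stop_chemmap("all screen counts must be positive", "chemmap_config_error")
  }
  if (cfg$noise_sd < 0 || cfg$site_sd < 0 || cfg$target_sd < 0) {
    stop_chemmap("standard deviations must be >= 0", "chemmap_config_error")
  }
  stopifnot(length(cfg$gamma_sense) == 21L, length(cfg$gamma_antisense) == 23L)
  class(cfg) <- "screen_sim_config"
  cfg
}

#' Generate a synthetic silencing screen
#'
#' Draws chemistry patterns (uniform over the 2-chemistry design space unless
#' `patterns` is supplied), assigns per-target and per-site baseline effects
#' and a species label per site, and simulates fraction-of-control mRNA
#' remaining under the planted log-additive positional model.
#'
#' @param config A [screen_sim_config()].
#' @return A data frame with one row per duplex x dose x replicate: columns
#'   `duplex_id`, `target`, `site_id`, `species`, `dose_nM`, `replicate`,
#'   `fraction_remaining`, and per-position chemistry columns `S1..S21`,
#'   `AS1..AS23` (values `"F"`/`"OMe"`). The planted truth (gamma vectors,
#'   baselines, per-site/target effects) is attached as attribute
#'   `"planted"`.
#' @examples
#' scr <- gen_screen(screen_sim_config(n_targets = 1, sites_per_target = 1,
#'                                     duplexes_per_site = 5, seed = 7))
#' @export
gen_screen <- function(config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  gamma <- c(config$gamma_sense, config$gamma_antisense)
  names(gamma) <- position_labels()
  with_seed(config$seed, {
    targets <- paste0("T", seq_len(config$n_targets))
    target_eff <- stats::setNames(stats::rnorm(config$n_targets, 0, config$target_sd), targets)
    n_sites <- config$n_targets * config$sites_per_target
    site_target <- rep(targets, each = config$sites_per_target)
    site_id <- paste0(site_target, "_site", rep(seq_len(config$sites_per_target),
                                                times = config$n_targets))
    site_eff <- stats::setNames(stats::rnorm(n_sites, 0, config$site_sd), site_id)
    site_species <- stats::setNames(
      rep(config$species_labels, length.out = n_sites), site_id)

    n_dup <- n_sites * config$duplexes_per_site
    dup_site <- rep(site_id, each = config$duplexes_per_site)
    dup_id <- paste0(dup_site, "_D",
                     formatC(rep(seq_len(config$duplexes_per_site), times = n_sites),
                             width = 3, flag = "0"))
    if (is.null(config$patterns)) {
      is_F <- matrix(stats::runif(n_dup * 44L) < 0.5, nrow = n_dup)
    } else {
      pat <- rep(config$patterns, length.out = n_dup)
      is_F <- t(vapply(pat, pattern_to_F, logical(44L)))
    }
    colnames(is_F) <- position_labels()

    dup_ln <- config$mu + target_eff[site_target][match(dup_site, site_id)] +
      site_eff[dup_site] + drop(is_F %*% gamma)

    grid <- expand.grid(replicate = seq_len(config$replicates),
                        dose_nM = config$doses_nM,
                        dup = seq_len(n_dup), KEEP.OUT.ATTRS = FALSE)
    dose_eff <- config$dose_effect[as.character(grid$dose_nM)]
    dose_eff[is.na(dose_eff)] <- 0
    ln_frac <- dup_ln[grid$dup] + dose_eff +
      stats::rnorm(nrow(grid), 0, config$noise_sd)

    chem <- matrix(ifelse(is_F[grid$dup, , drop = FALSE], "F", "OMe"),
                   nrow = nrow(grid), dimnames = list(NULL, position_labels()))
    out <- data.frame(duplex_id = dup_id[grid$dup],
                      site_id = dup_site[grid$dup],
                      species = unname(site_species[dup_site[grid$dup]]),
                      dose_nM = grid$dose_nM,
                      replicate = grid$replicate,
                      fraction_remaining = exp(ln_frac),
                      stringsAsFactors = FALSE)
    out$target <- sub("_.*", "", out$site_id)
    out <- out[, c("duplex_id", "target", "site_id", "species", "dose_nM",
                   "replicate", "fraction_remaining")]
    out <- cbind(out, as.data.frame(chem, stringsAsFactors = FALSE))
    attr(out, "planted") <- list(gamma = gamma, mu = config$mu,
                                 dose_effect = config$dose_effect,
                                 target_effects = target_eff,
                                 site_effects = site_eff,
                                 site_species = site_species)
    out
  })
}

#' Simulate a qPCR plate for a known knockdown
#'
#' Generates raw Ct values for target and housekeeping genes in treated and
#' negative-control wells such that delta-delta-Ct processing (see
#' [ddct_relative_expression()]) returns exactly `1 - knockdown_fraction`
#' remaining when `noise_sd = 0`.
#'
#' @param knockdown_fraction Planted knockdown in `[0, 1)`.
#' @param n_wells Wells per condition.
#' @param ct_target,ct_housekeeping Baseline Ct values in control wells.
#' @param noise_sd SD of Normal noise added to every Ct.
#' @param seed Optional seed.
#' @return Data frame with columns `well`, `condition`
#'   (`"treated"`/`"control"`), `gene` (`"target"`/`"housekeeping"`), `ct`.
#' @export
gen_qpcr_plate <- function(knockdown_fraction, n_wells = 4L, ct_target = 20,
                           ct_housekeeping = 15, noise_sd = 0, seed = NULL) {
  if (!is.numeric(knockdown_fraction) || knockdown_fraction < 0 ||
      knockdown_fraction >= 1) {
    stop_chemmap("knockdown_fraction must lie in [0, 1)", "chemmap_domain_error")
  }
  with_seed(seed, {
    ddct <- -log2(1 - knockdown_fraction) # shift in target Ct for treated wells
    grid <- expand.grid(well = seq_len(n_wells),
                        condition = c("treated", "control"),
                        gene = c("target", "housekeeping"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ct0 <- ifelse(grid$gene == "target", ct_target, ct_housekeeping)
    ct0 <- ct0 + ifelse(grid$gene == "target" & grid$condition == "treated", ddct, 0)
    grid$ct <- ct0 + stats::rnorm(nrow(grid), 0, noise_sd)
    grid
  })
}
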