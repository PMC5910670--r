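#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons in the family.
#'
#' @param p Unadjusted p-value(s).
#' @param m Number of comparisons.
#' @return Adjusted p-value(s), capped at 1.
#' @examples
#' sidak_adjust(0.01, 3) # 0.029701
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Two-way ANOVA of group-by-time data with Dunnett or Sidak post-tests
#'
#' Factorial decomposition (main effects of time and design, their
#' interaction, residual) via [stats::aov()], followed by per-time-point
#' comparisons of each design against the control design using the pooled
#' residual mean square. Dunnett-adjusted p-values are computed by seeded
#' Monte Carlo from the joint null distribution of the max-|t| statistic
#' over the comparisons sharing a control (>= `n_draws` draws; documented
#' Monte Carlo tolerance about 0.005 on p); Sidak uses the closed form
#' `1 - (1 - p)^m` with `m` the total number of comparisons. Adjusted
#' p-values are never smaller than unadjusted ones.
#'
#' @param records Data frame with columns `design` (or `group`), `time` (or
#'   `day`), `value`.
#' @param control Label of the control design.
#' @param post `"dunnett"` or `"sidak"`.
#' @param seed Seed for the Monte Carlo draws.
#' @param n_draws Monte Carlo draws (default 100,000).
#' @return Object of class `anova_posttests`: `anova` (term, df, sum_sq,
#'   mean_sq, statistic, p), `comparisons` (time, design, estimate, se, t,
#'   df, p_unadjusted, p_adjusted, significant), `post`, `control`,
#'   `balanced`.
#' @export
anova2_posttests <- function(records, control, post = c("dunnett", "sidak"),
                             seed = 1L, n_draws = 1e5) {
  post <- match.arg(post)
  stopifnot(is.data.frame(records))
  if (!"design" %in% names(records) && "group" %in% names(records)) {
    records$design <- records$group
  }
  if (!"time" %in% names(records) && "day" %in% names(records)) {
    records$time <- records$day
  }
  stopifnot(all(c("design", "time", "value") %in% names(records)))
  records$design <- as.character(records$design)
  if (!control %in% records$design) {
    stop_chemmap(sprintf("control design '%s' absent from records", control),
                 "chemmap_config_error")
  }
  if (length(unique(records$design)) < 2L || length(unique(records$time)) < 2L) {
    stop_chemmap("need >= 2 levels of both design and time", "chemmap_domain_error")
  }
  cells <- table(records$design, records$time)
  if (any(cells == 0)) {
    stop_chemmap("every design x time cell must be non-empty", "chemmap_domain_error")
  }
  balanced <- length(unique(as.vector(cells))) == 1L
  if (!balanced) {
    warning("unbalanced design x time cells: using sequential regression-based decomposition",
            call. = FALSE)
  }

  d <- data.frame(value = records$value,
                  time = factor(records$time),
                  design = factor(records$design))
  fit <- stats::aov(value ~ time * design, data = d)
  tab <- summary(fit)[[1]]
  anova_tab <- data.frame(term = trimws(rownames(tab)),
                          df = tab[["Df"]], sum_sq = tab[["Sum Sq"]],
                          mean_sq = tab[["Mean Sq"]],
                          statistic = tab[["F value"]], p = tab[["Pr(>F)"]],
                          row.names = NULL, stringsAsFactors = FALSE)
  df_res <- anova_tab$df[anova_tab$term == "Residuals"]
  mse <- anova_tab$mean_sq[anova_tab$term == "Residuals"]

  times <- sort(unique(records$time))
  others <- sort(setdiff(unique(records$design), control))
  comp <- do.call(rbind, lapply(times, function(tt) {
    ctrl <- records$value[records$design == control & records$time == tt]
    do.call(rbind, lapply(others, function(dd) {
      trt <- records$value[records$design == dd & records$time == tt]
      se <- sqrt(mse * (1 / length(trt) + 1 / length(ctrl)))
      est <- mean(trt) - mean(ctrl)
      data.frame(time = tt, design = dd, estimate = est, se = se,
                 t = est / se, df = df_res,
                 n_trt = length(trt), n_ctrl = length(ctrl),
                 stringsAsFactors = FALSE)
    }))
  }))
  comp$p_unadjusted <- 2 * stats::pt(-abs(comp$t), comp$df)

  if (post == "sidak") {
    comp$p_adjusted <- pmax(sidak_adjust(comp$p_unadjusted, nrow(comp)),
                            comp$p_unadjusted)
  } else {
    comp$p_adjusted <- NA_real_
    for (tt in times) {
      rows <- which(comp$time == tt)
      k <- length(rows)
      nt <- comp$n_trt[rows]
      nc <- comp$n_ctrl[rows][1]
      maxT <- with_seed(seed, {
        z0 <- stats::rnorm(n_draws) / sqrt(nc)
        s <- sqrt(stats::rchisq(n_draws, df_res) / df_res)
        Tm <- vapply(seq_len(k), function(i) {
          zi <- stats::rnorm(n_draws) / sqrt(nt[i])
          abs(zi - z0) / (s * sqrt(1 / nt[i] + 1 / nc))
        }, numeric(n_draws))
        if (k == 1L) as.numeric(Tm) else apply(Tm, 1, max)
      })
      comp$p_adjusted[rows] <- vapply(rows, function(r) {
        mean(maxT >= abs(comp$t[r]))
      }, numeric(1))
    }
    comp$p_adjusted <- pmax(comp$p_adjusted, comp$p_unadjusted)
  }
  comp$significant <- comp$p_adjusted < 0.05
  comp$n_trt <- comp$n_ctrl <- NULL

  structure(list(anova = anova_tab, comparisons = comp, post = post,
                 control = control, balanced = balanced),
            class = "anova_posttests")
}

#' @export
print.anova_posttests <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (time x design)%s\n",
              if (x$balanced) "" else " [unbalanced: sequential SS]"))
  at <- x$anova
  at$sum_sq <- signif(at$sum_sq, 5); at$mean_sq <- signif(at$mean_sq, 5)
  at$statistic <- signif(at$statistic, 4); at$p <- signif(at$p, 3)
  print(at, row.names = FALSE)
  cat(sprintf("\n%s post-tests vs control '%s':\n",
              if (x$post == "dunnett") "Dunnett (Monte Carlo)" else "Sidak",
              x$control))
  cp <- x$comparisons
  cp$estimate <- signif(cp$estimate, 4); cp$se <- signif(cp$se, 4)
  cp$t <- signif(cp$t, 4)
  cp$p_unadjusted <- signif(cp$p_unadjusted, 3)
  cp$p_adjusted <- signif(cp$p_adjusted, 3)
  print(cp, row.names = FALSE)
  invisible(x)
}
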