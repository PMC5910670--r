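#' Normalize in vivo time courses to pre-dose values
#'
#' Expresses each animal's measurements as a percentage of its own pre-dose
#' (day-0) value, the standard normalization for circulating-protein
#' readouts.
#'
#' @param records Data frame with columns `group`, `animal`, `day`, `value`
#'   (raw measurements); each animal must have exactly one pre-dose row at
#'   `day == predose_day` with a positive value.
#' @param predose_day Day of the pre-dose measurement (default 0).
#' @return The records with `value` rescaled to % of pre-dose (the pre-dose
#'   row maps to 100).
#' @export
normalize_to_predose <- function(records, predose_day = 0) {
  stopifnot(is.data.frame(records),
            all(c("animal", "day", "value") %in% names(records)))
  out <- records
  for (a in unique(records$animal)) {
    rows <- records$animal == a
    pre <- records$value[rows & records$day == predose_day]
    if (length(pre) != 1L || !is.finite(pre) || pre <= 0) {
      stop_chemmap(sprintf(
        "animal '%s': pre-dose value at day %s missing, duplicated, or <= 0",
        a, format(predose_day)), "chemmap_domain_error")
    }
    out$value[rows] <- 100 * records$value[rows] / pre
  }
  out
}

#' Semilog fit of knockdown against Ago2 loading with EC50/EC80
#'
#' Fits the semilog line `knockdown(%) = a + b * log10(loading)` by least
#' squares, where `loading` is the Ago2-loaded antisense strand (ng per g
#' liver), and inverts it for effective-loading values:
#' `EC_p = 10^((p - a)/b)`. EC values outside the observed loading range are
#' flagged as extrapolated rather than suppressed.
#'
#' @param loading Positive loading values (ng/g).
#' @param knockdown_pct Percent knockdown (100 minus % of control).
#' @return An object of class `ec_fit`: list with `a`, `b`, `ec50`, `ec80`,
#'   `residual_ss`, `df`, `n`, `loading_range`, `extrapolated` (named
#'   logical for ec50/ec80).
#' @examples
#' fit_semilog_ec(c(1, 10, 100), 20 + 30 * log10(c(1, 10, 100)))$ec50 # 10
#' @export
fit_semilog_ec <- function(loading, knockdown_pct) {
  loading <- as.numeric(loading)
  knockdown_pct <- as.numeric(knockdown_pct)
  if (length(loading) != length(knockdown_pct)) {
    stop_chemmap("loading and knockdown_pct must have equal length", "chemmap_domain_error")
  }
  if (length(loading) < 3L) {
    stop_chemmap("need at least 3 points for the semilog fit", "chemmap_domain_error")
  }
  if (any(!is.finite(loading) | loading <= 0)) {
    stop_chemmap("loading values must be finite and > 0", "chemmap_domain_error")
  }
  x <- log10(loading)
  if (length(unique(x)) < 2L) {
    stop_chemmap("need at least 2 distinct loading values", "chemmap_domain_error")
  }
  xbar <- mean(x)
  ybar <- mean(knockdown_pct)
  sxx <- sum((x - xbar)^2)
  b <- sum((x - xbar) * (knockdown_pct - ybar)) / sxx
  a <- ybar - b * xbar
  res <- knockdown_pct - (a + b * x)
  rss <- sum(res^2)
  df <- length(x) - 2L
  scale_tol <- 1e-12 * max(1, abs(a), abs(ybar))
  if (abs(b) * sqrt(sxx) <= scale_tol) {
    stop_chemmap("fitted slope is zero within tolerance: EC values undefined",
                 "chemmap_ec_undefined")
  }
  ec <- function(p) 10^((p - a) / b)
  rng <- range(loading)
  ec50 <- ec(50); ec80 <- ec(80)
  structure(list(a = a, b = b, ec50 = ec50, ec80 = ec80,
                 residual_ss = rss, df = df, n = length(x),
                 loading_range = rng,
                 extrapolated = c(ec50 = ec50 < rng[1] || ec50 > rng[2],
                                  ec80 = ec80 < rng[1] || ec80 > rng[2])),
            class = "ec_fit")
}

#' @export
print.ec_fit <- function(x, digits = 4, ...) {
  cat("Semilog EC fit: knockdown(%) = a + b * log10(loading ng/g)\n")
  cat(sprintf("  a = %.*g, b = %.*g (n = %d, residual SS = %.4g)\n",
              digits, x$a, digits, x$b, x$n, x$residual_ss))
  flag <- function(nm) if (x$extrapolated[[nm]]) " (extrapolated)" else ""
  cat(sprintf("  EC50 = %.*g ng/g%s, EC80 = %.*g ng/g%s\n",
              digits, x$ec50, flag("ec50"), digits, x$ec80, flag("ec80")))
  invisible(x)
}

#' @export
coef.ec_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
predict.ec_fit <- function(object, loading, ...) {
  object$a + object$b * log10(loading)
}

#' Extra-sum-of-squares F-test for coincident semilog lines
#'
#' Nested-model comparison asking whether per-group semilog lines fit the
#' data better than one pooled line:
#' `F = [(SS_pooled - SS_separate)/(df_pooled - df_separate)] /
#' (SS_separate/df_separate)`, with `SS_separate` the sum of the per-group
#' residual sums of squares.
#'
#' @param loading Positive loading values.
#' @param knockdown_pct Percent knockdown.
#' @param group Group labels (>= 2 groups, each fittable).
#' @return An object of class `stat_test` with `statistic`, `df_num`,
#'   `df_den`, `p`, `decision` at alpha = 0.05.
#' @export
ess_f_test <- function(loading, knockdown_pct, group) {
  group <- as.character(group)
  stopifnot(length(loading) == length(knockdown_pct),
            length(group) == length(loading))
  gs <- unique(group)
  if (length(gs) < 2L) {
    stop_chemmap("need at least two groups", "chemmap_domain_error")
  }
  fits <- lapply(gs, function(g) {
    fit_semilog_ec(loading[group == g], knockdown_pct[group == g])
  })
  ss_sep <- sum(vapply(fits, function(f) f$residual_ss, numeric(1)))
  df_sep <- sum(vapply(fits, function(f) f$df, numeric(1)))
  pooled <- fit_semilog_ec(loading, knockdown_pct)
  ss_pool <- pooled$residual_ss
  df_pool <- pooled$df
  if (df_sep <= 0) {
    stop_chemmap("separate-lines model leaves no residual degrees of freedom",
                 "chemmap_domain_error")
  }
  f <- max(0, ((ss_pool - ss_sep) / (df_pool - df_sep)) / (ss_sep / df_sep))
  p <- stats::pf(f, df_pool - df_sep, df_sep, lower.tail = FALSE)
  stat_test(f, df_pool - df_sep, df_sep, p,
            method = "extra-sum-of-squares F-test (pooled vs separate semilog lines)")
}

stat_test <- function(statistic, df_num, df_den, p, method) {
  structure(list(statistic = statistic, df_num = df_num, df_den = df_den,
                 p = p, decision = if (p < 0.05) "reject" else "fail to reject",
                 method = method),
            class = "stat_test")
}

#' @export
print.stat_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  statistic = %.4g on (%s, %s) df, p = %.4g -> %s at alpha = 0.05\n",
              x$statistic, format(x$df_num), format(x$df_den), x$p, x$decision))
  invisible(x)
}
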