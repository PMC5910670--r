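#' Baseline-referenced area under a time-course curve
#'
#' Trapezoidal AUC of deviations from a fixed baseline with peak-threshold
#' semantics: the piecewise-linear curve is split at interpolated baseline
#' crossings into peaks (maximal same-sign excursions); a peak whose maximal
#' absolute deviation is less than `peak_ignore_frac` of the full observed
#' Y-range is ignored; retained peaks contribute the absolute value of their
#' enclosed area, so excursions below the baseline count positively.
#'
#' @param days Strictly increasing time points (>= 2).
#' @param values Series values (e.g. % of pre-dose).
#' @param baseline Reference value (default 100).
#' @param peak_ignore_frac Peaks smaller than this fraction of
#'   `max(values) - min(values)` are ignored (default 0.10).
#' @return Total area (value units x day).
#' @examples
#' auc_vs_baseline(0:3, c(100, 50, 50, 100)) # 100
#' @export
auc_vs_baseline <- function(days, values, baseline = 100, peak_ignore_frac = 0.10) {
  days <- as.numeric(days)
  values <- as.numeric(values)
  if (length(days) < 2L || length(days) != length(values)) {
    stop_chemmap("need >= 2 (day, value) pairs of equal length", "chemmap_domain_error")
  }
  if (any(!is.finite(days)) || any(!is.finite(values))) {
    stop_chemmap("days and values must be finite", "chemmap_domain_error")
  }
  if (any(diff(days) <= 0)) {
    stop_chemmap("days must be strictly increasing", "chemmap_domain_error")
  }
  dev <- values - baseline
  # insert interpolated baseline crossings
  x <- days[1]; y <- dev[1]
  for (i in seq_len(length(days) - 1L)) {
    if (dev[i] * dev[i + 1L] < 0) {
      tc <- days[i] + (0 - dev[i]) * (days[i + 1L] - days[i]) / (dev[i + 1L] - dev[i])
      x <- c(x, tc); y <- c(y, 0)
    }
    x <- c(x, days[i + 1L]); y <- c(y, dev[i + 1L])
  }
  nseg <- length(x) - 1L
  seg_sign <- sign(y[-length(y)] + y[-1L]) # constant-sign segments after splitting
  seg_area <- abs(y[-length(y)] + y[-1L]) / 2 * diff(x)
  # group consecutive same-sign segments into peaks
  total <- 0
  yrange <- max(values) - min(values)
  i <- 1L
  while (i <= nseg) {
    if (seg_sign[i] == 0) { i <- i + 1L; next }
    j <- i
    # a peak ends at a crossing, a baseline touch, or a sign change
    while (j < nseg && seg_sign[j + 1L] == seg_sign[i] && y[j + 1L] != 0) {
      j <- j + 1L
    }
    peak_dev <- max(abs(y[i:(j + 1L)]))
    if (peak_dev >= peak_ignore_frac * yrange) {
      total <- total + sum(seg_area[i:j])
    }
    i <- j + 1L
  }
  total
}

#' Compare recovery slopes between two treatment groups
#'
#' Linear regression of the recovery phase (% of control per day) within a
#' day window for each of two groups, with slope equality tested by the
#' group-by-day interaction t-test in the pooled two-line model. The default
#' window is days 29 to 71 post-dose, inclusive at both ends.
#'
#' @param records Data frame with columns `group` (exactly two levels),
#'   `day`, `value`.
#' @param day_window Numeric `c(lo, hi)`, endpoints included.
#' @return List of class `slope_compare`: `slopes` (named per group, % per
#'   day), `difference` (second minus first group, in sorted label order),
#'   `test` (a `stat_test` for slope equality), `window`, `n`.
#' @export
recovery_slope_compare <- function(records, day_window = c(29, 71)) {
  stopifnot(is.data.frame(records),
            all(c("group", "day", "value") %in% names(records)),
            length(day_window) == 2L, day_window[1] <= day_window[2])
  gs <- sort(unique(as.character(records$group)))
  if (length(gs) != 2L) {
    stop_chemmap("recovery_slope_compare expects exactly two groups", "chemmap_domain_error")
  }
  sub <- records[records$day >= day_window[1] & records$day <= day_window[2], ,
                 drop = FALSE]
  for (g in gs) {
    if (sum(sub$group == g) < 3L) {
      stop_chemmap(sprintf("group '%s' has fewer than 3 points in the window [%g, %g]",
                           g, day_window[1], day_window[2]), "chemmap_domain_error")
    }
  }
  slope_of <- function(g) {
    d <- sub[sub$group == g, ]
    xc <- d$day - mean(d$day)
    sum(xc * d$value) / sum(xc^2)
  }
  slopes <- stats::setNames(vapply(gs, slope_of, numeric(1)), gs)

  g2 <- as.numeric(sub$group == gs[2])
  X <- cbind(`(Intercept)` = 1, day = sub$day, group = g2, `day:group` = sub$day * g2)
  fit <- fit_ols(X, sub$value)
  est <- unname(fit$coefficients["day:group"])
  se <- unname(fit$se["day:group"])
  # exact (numerically zero-residual) fits: the t ratio is 0/0 noise
  exact <- fit$residual_ss <= 1e-20 * max(1, sum(sub$value^2))
  if (!exact && !is.na(se) && se > 0) {
    t <- est / se
    p <- 2 * stats::pt(-abs(t), fit$df_residual)
  } else {
    tol <- sqrt(.Machine$double.eps) * max(1, max(abs(slopes)))
    t <- if (abs(est) < tol) 0 else sign(est) * Inf
    p <- if (t == 0) 1 else 0
  }
  structure(list(slopes = slopes, difference = unname(est),
                 test = stat_test(t, 1, fit$df_residual, p,
                                  method = "interaction t-test for equality of recovery slopes"),
                 window = day_window, n = nrow(sub)),
            class = "slope_compare")
}

#' @export
print.slope_compare <- function(x, ...) {
  cat(sprintf("Recovery slopes over days [%g, %g] (n = %d)\n",
              x$window[1], x$window[2], x$n))
  for (g in names(x$slopes)) {
    cat(sprintf("  %s: %.4g %% of control per day\n", g, x$slopes[[g]]))
  }
  cat(sprintf("  difference = %.4g\n", x$difference))
  print(x$test)
  invisible(x)
}
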