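#' Ordinary least squares with explicit rank handling
#'
#' QR-based least-squares solver used by the positional and design-variant
#' models. Rank-deficient columns are detected (pivoted QR, tolerance
#' `1e-10` relative to the leading diagonal of R), dropped with a warning,
#' and reported — never silently aliased. Standard errors are homoskedastic
#' OLS errors from \eqn{\hat\sigma^2 (X^T X)^{-1}} on the retained column
#' set; two-sided p-values use the t distribution on the residual degrees of
#' freedom.
#'
#' @param X Numeric design matrix with column names.
#' @param y Numeric response vector, `length(y) == nrow(X)`.
#' @return An object of class `ols_fit`: list with `coefficients` (full
#'   length, `NA` for dropped columns), `se`, `p`, `cov` (retained columns),
#'   `residuals`, `fitted`, `residual_ss`, `df_residual`, `r2`,
#'   `adjusted_r2`, `overall_p`, `rank`, `dropped` (names of rank-deficient
#'   columns), `inference_available`.
#' @examples
#' X <- cbind(`(Intercept)` = 1, x = c(0, 1))
#' fit_ols(X, c(1, 3))$coefficients # exact interpolation: 1, 2
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop_chemmap("rows of X must match length of y", "chemmap_domain_error")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)

  qr0 <- qr(X, tol = 1e-10)
  r <- qr0$rank
  keep <- sort(qr0$pivot[seq_len(r)])
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  if (length(dropped)) {
    warning(sprintf("rank-deficient design: dropped column(s) %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  Xk <- X[, keep, drop = FALSE]
  qrk <- qr(Xk)
  beta_k <- qr.coef(qrk, y)
  fitted <- drop(Xk %*% beta_k)
  res <- y - fitted
  rss <- sum(res^2)
  df_res <- n - r

  coefficients <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  coefficients[keep] <- beta_k
  se <- p <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  covb <- NULL
  inference <- df_res > 0L
  if (inference) {
    sigma2 <- rss / df_res
    Rinv <- backsolve(qr.R(qrk), diag(r))
    covb <- sigma2 * tcrossprod(Rinv)
    dimnames(covb) <- list(colnames(Xk), colnames(Xk))
    se_k <- sqrt(diag(covb))
    t_k <- beta_k / se_k
    se[keep] <- se_k
    p[keep] <- 2 * stats::pt(-abs(t_k), df_res)
  } else {
    warning("zero residual degrees of freedom: inference unavailable (coefficients returned)",
            call. = FALSE)
  }

  has_int <- any(apply(Xk, 2, function(col) all(col == col[1]) && col[1] != 0))
  tss <- if (has_int) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  adj_df <- n - r
  adjusted_r2 <- if (adj_df > 0 && tss > 0) {
    1 - (1 - r2) * (n - has_int) / adj_df
  } else NA_real_
  overall_p <- NA_real_
  p_model <- r - has_int
  if (inference && p_model > 0 && tss > rss) {
    f <- ((tss - rss) / p_model) / (rss / df_res)
    overall_p <- stats::pf(f, p_model, df_res, lower.tail = FALSE)
  }

  structure(list(coefficients = coefficients, se = se, p = p, cov = covb,
                 residuals = res, fitted = fitted, residual_ss = rss,
                 df_residual = df_res, r2 = r2, adjusted_r2 = adjusted_r2,
                 overall_p = overall_p, rank = r, dropped = dropped,
                 inference_available = inference, n = n),
            class = "ols_fit")
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

#' @export
vcov.ols_fit <- function(object, ...) object$cov

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, rank = %d, residual df = %d\n", x$n, x$rank, x$df_residual))
  cat(sprintf("  residual SS = %.6g, adjusted r^2 = %.4f\n", x$residual_ss, x$adjusted_r2))
  if (length(x$dropped)) cat("  dropped (rank):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
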