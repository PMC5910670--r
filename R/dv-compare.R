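#' Relative expression by the delta-delta-Ct method
#'
#' Computes fraction-of-control expression from raw qPCR Ct values:
#' per-well `dCt = Ct(target) - Ct(housekeeping)`, then
#' `ddCt = mean dCt(treated) - mean dCt(control)`, returning `2^(-ddCt)`.
#' The result is invariant to adding a constant to every Ct on the plate.
#'
#' @param plate Data frame with columns `well`, `condition`, `gene`
#'   (`"target"`/`"housekeeping"`), `ct` (see [gen_qpcr_plate()]).
#' @param control_label,treated_label Condition labels.
#' @return Fraction of control mRNA remaining (scalar).
#' @examples
#' ddct_relative_expression(gen_qpcr_plate(0.75)) # 0.25
#' @export
ddct_relative_expression <- function(plate, control_label = "control",
                                     treated_label = "treated") {
  stopifnot(is.data.frame(plate),
            all(c("well", "condition", "gene", "ct") %in% names(plate)))
  bad <- !is.finite(plate$ct)
  if (any(bad)) {
    drop_wells <- unique(plate[bad, c("condition", "well")])
    warning(sprintf("excluding %d well(s) with non-finite Ct", nrow(drop_wells)),
            call. = FALSE)
    key <- paste(plate$condition, plate$well)
    plate <- plate[!key %in% paste(drop_wells$condition, drop_wells$well), ,
                   drop = FALSE]
  }
  dct_per_well <- function(cond) {
    sub <- plate[plate$condition == cond, , drop = FALSE]
    tg <- sub[sub$gene == "target", ]
    hk <- sub[sub$gene == "housekeeping", ]
    m <- match(tg$well, hk$well)
    ok <- !is.na(m)
    tg$ct[ok] - hk$ct[m[ok]]
  }
  dct_ctrl <- dct_per_well(control_label)
  if (!length(dct_ctrl)) {
    stop_chemmap("no usable control wells on the plate", "chemmap_domain_error")
  }
  dct_trt <- dct_per_well(treated_label)
  if (!length(dct_trt)) {
    stop_chemmap("no usable treated wells on the plate", "chemmap_domain_error")
  }
  ddct <- mean(dct_trt) - mean(dct_ctrl)
  2^(-ddct)
}

#' Compare design variants to a reference design across sequences
#'
#' Covariate-adjusted regression used for directed design efforts: OLS on
#' the natural log of fraction remaining with indicator sets for design
#' variant (the reference design is the dropped level), dose (categorical),
#' target site, and replicate (a categorical blocking factor controlling
#' systematic between-study effects). Each design's coefficient is its
#' model-adjusted mean ln-difference in activity from the reference.
#'
#' @param records Data frame with columns `dv_id`, `site_id`, `dose_nM`,
#'   `replicate`, `fraction_remaining` (> 0).
#' @param reference The reference `dv_id` (e.g. the parent design).
#' @return An object of class `dv_fit`: list with `effects` (data frame:
#'   `dv_id`, `delta_ln`, `se`, `p`, `significant`, `low_support` for DVs
#'   observed at fewer than two sites; the reference row has `delta_ln` 0),
#'   `fit` (`ols_fit`), `reference`, `n`.
#' @export
fit_dv_comparison <- function(records, reference = "parent") {
  stopifnot(is.data.frame(records),
            all(c("dv_id", "site_id", "dose_nM", "replicate",
                  "fraction_remaining") %in% names(records)))
  dvs <- unique(as.character(records$dv_id))
  if (!reference %in% dvs) {
    stop_chemmap(sprintf("reference design '%s' absent from records", reference),
                 "chemmap_config_error")
  }
  if (length(dvs) < 2L) {
    stop_chemmap("need at least two distinct designs including the reference",
                 "chemmap_domain_error")
  }
  if (any(!is.finite(records$fraction_remaining) | records$fraction_remaining <= 0)) {
    stop_chemmap("fraction_remaining must be finite and > 0", "chemmap_domain_error")
  }
  y <- log(records$fraction_remaining)
  n <- nrow(records)
  others <- sort(setdiff(dvs, reference))

  blocks <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  dvm <- vapply(others, function(d) as.numeric(records$dv_id == d), numeric(n))
  colnames(dvm) <- paste0("dv_", others)
  blocks$dv <- dvm
  add_factor <- function(values, prefix) {
    lev <- sort(unique(as.character(values)))
    if (length(lev) < 2L) return(NULL)
    m <- vapply(lev[-1L], function(l) as.numeric(values == l), numeric(n))
    colnames(m) <- paste0(prefix, lev[-1L])
    m
  }
  blocks$dose <- add_factor(records$dose_nM, "dose_")
  blocks$site <- add_factor(records$site_id, "site_")
  blocks$rep <- add_factor(records$replicate, "rep_")
  X <- do.call(cbind, Filter(Negate(is.null), blocks))

  fit <- withCallingHandlers(
    fit_ols(X, y),
    warning = function(w) {
      if (grepl("rank-deficient", conditionMessage(w))) invokeRestart("muffleWarning")
    })

  support <- tapply(records$site_id, records$dv_id,
                    function(s) length(unique(s)))
  eff <- data.frame(dv_id = c(reference, others),
                    delta_ln = c(0, unname(fit$coefficients[paste0("dv_", others)])),
                    se = c(NA_real_, unname(fit$se[paste0("dv_", others)])),
                    p = c(NA_real_, unname(fit$p[paste0("dv_", others)])),
                    stringsAsFactors = FALSE)
  eff$significant <- !is.na(eff$p) & eff$p < 0.05
  eff$low_support <- as.integer(support[eff$dv_id]) < 2L
  eff$reference <- eff$dv_id == reference
  structure(list(effects = eff, fit = fit, reference = reference, n = n),
            class = "dv_fit")
}

#' @export
print.dv_fit <- function(x, ...) {
  cat(sprintf("Design-variant comparison vs reference '%s' (n = %d)\n",
              x$reference, x$n))
  eff <- x$effects
  eff$delta_ln <- round(eff$delta_ln, 4)
  eff$se <- round(eff$se, 4)
  eff$p <- signif(eff$p, 3)
  print(eff, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dv_fit <- function(object, ...) {
  stats::setNames(object$effects$delta_ln, object$effects$dv_id)
}

#' @export
summary.dv_fit <- function(object, ...) {
  cat(sprintf("adjusted r^2 = %.3f; residual df = %d\n",
              object$fit$adjusted_r2, object$fit$df_residual))
  print(object)
  invisible(object)
}
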