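#' Restrict a screen to well-sampled target sites
#'
#' Keeps only records from target sites on which at least `min_designs`
#' distinct duplex designs were evaluated, enriching the analysis for sites
#' that inform positional contrasts. Replicate rows of one duplex count as a
#' single design.
#'
#' @param records Screen data frame (see [gen_screen()] for the column
#'   contract).
#' @param min_designs Minimum number of distinct duplexes per site.
#' @return The retained records, with attribute `"site_counts"`: a data
#'   frame of per-site design counts and keep/drop status.
#' @export
filter_sites <- function(records, min_designs = 10L) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            all(c("site_id", "duplex_id") %in% names(records)))
  counts <- tapply(records$duplex_id, records$site_id,
                   function(d) length(unique(d)))
  report <- data.frame(site_id = names(counts),
                       n_designs = as.integer(counts),
                       kept = as.integer(counts) >= min_designs,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!any(report$kept)) {
    stop_chemmap(paste0("no site reaches ", min_designs, " designs; counts: ",
                        paste(sprintf("%s=%d", report$site_id, report$n_designs),
                              collapse = ", ")),
                 "chemmap_empty_result")
  }
  out <- records[records$site_id %in% report$site_id[report$kept], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "site_counts") <- report
  out
}

# Geometric-mean collapse of replicate rows to one row per duplex x dose.
collapse_replicates <- function(records) {
  key <- interaction(records$duplex_id, records$dose_nM, drop = TRUE)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  out$fraction_remaining <- exp(tapply(log(records$fraction_remaining), key, mean))[
    as.character(key[first])]
  out$replicate <- 1L
  rownames(out) <- NULL
  out
}

#' Build the positional-chemistry design matrix
#'
#' Encodes each record for the sequence-agnostic positional regression: one
#' indicator column per strand position (1 iff the position carries 2'-F;
#' 2'-OMe is the reference chemistry), fixed-effect indicators for target
#' site (first level dropped) and species, optional dose indicators when
#' several doses are present, and an intercept. Phosphorothioate content
#' contributes no column (the analysis is PS-agnostic), and target is
#' absorbed by the site fixed effects (sites are nested within targets).
#' The response is the natural log of fraction remaining.
#'
#' @param records Screen data frame with chemistry columns `S1..S21`,
#'   `AS1..AS23`; `fraction_remaining` must be strictly positive (rows with
#'   non-positive response are rejected, not clamped).
#' @return List with `X` (numeric matrix), `y` (ln fraction remaining), and
#'   `col_map` (data frame mapping columns to roles: intercept, site,
#'   species, dose, chemistry), plus `inestimable`: chemistry positions
#'   constant across all records (no column emitted).
#' @export
build_design_matrix <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  chem_cols <- position_labels()
  missing_chem <- setdiff(chem_cols, names(records))
  if (length(missing_chem)) {
    stop_chemmap(paste0("records lack chemistry columns: ",
                        paste(utils::head(missing_chem, 5), collapse = ", ")),
                 "chemmap_domain_error")
  }
  if (any(!is.finite(records$fraction_remaining) | records$fraction_remaining <= 0)) {
    stop_chemmap("fraction_remaining must be finite and > 0 (rejected at ingest)",
                 "chemmap_domain_error")
  }
  y <- log(records$fraction_remaining)
  n <- nrow(records)

  blocks <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  map <- data.frame(column = "(Intercept)", type = "intercept",
                    label = NA_character_, stringsAsFactors = FALSE)

  add_factor <- function(values, prefix, type) {
    lev <- sort(unique(as.character(values)))
    if (length(lev) < 2L) return(invisible(NULL))
    m <- vapply(lev[-1L], function(l) as.numeric(values == l), numeric(n))
    colnames(m) <- paste0(prefix, lev[-1L])
    blocks[[prefix]] <<- m
    map <<- rbind(map, data.frame(column = colnames(m), type = type,
                                  label = lev[-1L], stringsAsFactors = FALSE))
  }
  if ("site_id" %in% names(records)) add_factor(records$site_id, "site_", "site")
  if ("species" %in% names(records)) add_factor(records$species, "species_", "species")
  if ("dose_nM" %in% names(records)) add_factor(records$dose_nM, "dose_", "dose")

  chem <- as.matrix(records[, chem_cols]) == "F"
  storage.mode(chem) <- "numeric"
  constant <- apply(chem, 2, function(col) all(col == col[1]))
  inestimable <- chem_cols[constant]
  if (any(!constant)) {
    keep <- chem[, !constant, drop = FALSE]
    blocks[["chem"]] <- keep
    map <- rbind(map, data.frame(column = colnames(keep), type = "chemistry",
                                 label = colnames(keep), stringsAsFactors = FALSE))
  }
  X <- do.call(cbind, blocks)
  list(X = X, y = y, col_map = map, inestimable = inestimable)
}

#' Extract the per-position 2'-F effect map from a fitted model
#'
#' Converts the chemistry coefficients of an [fit_ols()] result into a
#' positional map of model-adjusted mean ln-differences of 2'-F from 2'-OMe.
#' The sign convention follows the silencing scale: a negative `delta_ln`
#' means 2'-F at that position improves silencing (lower fraction
#' remaining).
#'
#' @param fit An `ols_fit` from a design matrix built by
#'   [build_design_matrix()].
#' @param design The list returned by [build_design_matrix()] (used for the
#'   column map and the positions dropped as constant).
#' @return A data frame of class `positional_map` with one row per strand
#'   position: `strand`, `position`, `label`, `delta_ln`, `se`, `p`,
#'   `significant` (at alpha = 0.05), `estimable`.
#' @export
extract_positional_map <- function(fit, design) {
  stopifnot(inherits(fit, "ols_fit"), is.list(design), !is.null(design$col_map))
  chem_cols <- design$col_map$column[design$col_map$type == "chemistry"]
  if (length(chem_cols) && !all(chem_cols %in% names(fit$coefficients))) {
    stop_chemmap("column map does not match the fitted model", "chemmap_structure_error")
  }
  labels <- position_labels()
  pos <- t(vapply(labels, function(l) {
    p <- parse_position_label(l)
    c(strand = p$strand, position = p$position)
  }, c(strand = "", position = "")))
  map <- data.frame(strand = pos[, "strand"],
                    position = as.integer(pos[, "position"]),
                    label = labels,
                    delta_ln = NA_real_, se = NA_real_, p = NA_real_,
                    significant = FALSE, estimable = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  est <- intersect(labels, chem_cols)
  est <- est[!is.na(fit$coefficients[est])] # rank-dropped stay inestimable
  idx <- match(est, map$label)
  map$delta_ln[idx] <- fit$coefficients[est]
  map$se[idx] <- fit$se[est]
  map$p[idx] <- fit$p[est]
  map$estimable[idx] <- TRUE
  map$significant <- map$estimable & !is.na(map$p) & map$p < 0.05
  class(map) <- c("positional_map", "data.frame")
  map
}

#' Fit the positional 2'-F/2'-OMe activity model
#'
#' The central model of the screening paradigm: a multiple linear regression
#' of the natural log of fraction-of-control mRNA remaining on per-position
#' chemistry indicators (2'-F vs the 2'-OMe reference) with target-site and
#' species fixed effects, fitted across sequences so positional effects are
#' sequence-agnostic. Sites with fewer than `min_designs` distinct designs
#' are excluded first; replicates are collapsed to per-duplex geometric
#' means by default.
#'
#' @param records Screen data frame (see [gen_screen()]).
#' @param dose_nM Optional single dose to restrict to (e.g. `0.1`); `NULL`
#'   uses all doses and adjusts for dose as a factor.
#' @param min_designs Site inclusion threshold (distinct designs per site).
#' @param aggregate `"duplex_mean"` (default) collapses replicates to the
#'   per-duplex geometric mean; `"replicate"` models every replicate row.
#' @return An object of class `positional_fit`: list with `map` (see
#'   [extract_positional_map()]), `fit` (`ols_fit`), `site_counts`,
#'   `absorbed` (columns removed as rank-deficient, e.g. species absorbed by
#'   site effects), `inestimable`, `n_records`, `n_duplexes`, `call`.
#' @examples
#' scr <- gen_screen(screen_sim_config(duplexes_per_site = 20, seed = 2))
#' pf <- fit_positional(scr, dose_nM = 0.1)
#' coef(pf)[c("AS2", "AS6", "AS14", "S11")]
#' @export
fit_positional <- function(records, dose_nM = NULL, min_designs = 10L,
                           aggregate = c("duplex_mean", "replicate")) {
  aggregate <- match.arg(aggregate)
  cl <- match.call()
  if (!is.null(dose_nM)) {
    records <- records[records$dose_nM %in% dose_nM, , drop = FALSE]
    if (!nrow(records)) {
      stop_chemmap("no records at the requested dose", "chemmap_empty_result")
    }
  }
  records <- filter_sites(records, min_designs = min_designs)
  site_counts <- attr(records, "site_counts")
  if (aggregate == "duplex_mean") records <- collapse_replicates(records)
  design <- build_design_matrix(records)
  absorbed <- character(0)
  fit <- withCallingHandlers(
    fit_ols(design$X, design$y),
    warning = function(w) {
      if (grepl("rank-deficient", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  absorbed <- fit$dropped
  map <- extract_positional_map(fit, design)
  structure(list(map = map, fit = fit, site_counts = site_counts,
                 absorbed = absorbed, inestimable = design$inestimable,
                 n_records = nrow(records),
                 n_duplexes = length(unique(records$duplex_id)), call = cl),
            class = "positional_fit")
}

#' @export
print.positional_fit <- function(x, ...) {
  cat("Positional 2'-F vs 2'-OMe activity model\n")
  cat(sprintf("  %d records, %d duplexes, %d sites; adjusted r^2 = %.3f\n",
              x$n_records, x$n_duplexes, sum(x$site_counts$kept),
              x$fit$adjusted_r2))
  sig <- x$map$label[x$map$significant]
  cat("  significant positions (p < 0.05):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
summary.positional_fit <- function(object, ...) {
  structure(list(map = object$map, adjusted_r2 = object$fit$adjusted_r2,
                 overall_p = object$fit$overall_p, n_records = object$n_records,
                 n_duplexes = object$n_duplexes, absorbed = object$absorbed,
                 inestimable = object$inestimable),
            class = "summary.positional_fit")
}

#' @export
print.summary.positional_fit <- function(x, ...) {
  cat("Positional 2'-F vs 2'-OMe activity model\n")
  cat(sprintf("  n = %d records (%d duplexes); adjusted r^2 = %.3f; overall p = %.3g\n",
              x$n_records, x$n_duplexes, x$adjusted_r2, x$overall_p))
  if (length(x$absorbed)) {
    cat("  absorbed/rank-dropped columns:", paste(x$absorbed, collapse = ", "), "\n")
  }
  if (length(x$inestimable)) {
    cat("  inestimable positions (constant chemistry):",
        paste(x$inestimable, collapse = ", "), "\n")
  }
  m <- x$map[x$map$estimable, c("label", "delta_ln", "se", "p", "significant")]
  m$delta_ln <- round(m$delta_ln, 4)
  m$se <- round(m$se, 4)
  m$p <- signif(m$p, 3)
  print(m, row.names = FALSE)
  invisible(x)
}

#' @export
coef.positional_fit <- function(object, ...) {
  stats::setNames(object$map$delta_ln, object$map$label)
}

#' Predict the activity difference of a pattern under a positional fit
#'
#' @param object A `positional_fit`.
#' @param pattern,reference [chemistry_pattern()]s (or duplexes); the
#'   prediction is the additive sum of signed positional coefficients over
#'   positions where they differ.
#' @param ... Unused.
#' @return Predicted ln-difference in fraction remaining
#'   (`pattern - reference`).
#' @export
predict.positional_fit <- function(object, pattern, reference, ...) {
  predict_delta_ln(pattern, object$map, reference)
}

#' @export
plot.positional_fit <- function(x, ...) {
  m <- x$map
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in c("antisense", "sense")) {
    ms <- m[m$strand == s, ]
    h <- ifelse(ms$estimable, ms$delta_ln, 0)
    bp <- graphics::barplot(h, names.arg = ms$position,
                            col = ifelse(ms$significant, "firebrick", "grey70"),
                            xlab = paste(s, "position (5'->3')"),
                            ylab = "delta ln (2'-F - 2'-OMe)", ...)
    sig <- which(ms$significant)
    if (length(sig)) {
      graphics::text(bp[sig], h[sig], labels = "*",
                     pos = ifelse(h[sig] >= 0, 3, 1), xpd = NA)
    }
    graphics::abline(h = 0)
  }
  invisible(x)
}
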