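#' Positional constraints for design search
#'
#' Encodes the constraint language used when proposing reduced-2'-F designs:
#' positions that must stay 2'-F (e.g. the critical positions AS2, AS6, AS14
#' and S11), positions that must stay 2'-OMe, and position pairs required to
#' share a chemistry (default the AS8/AS9 pair, where either a pair of 2'-F
#' or a pair of 2'-OMe is advantageous but a mixed pair is not).
#'
#' @param fixed_F,fixed_OMe Character vectors of position labels
#'   (`"S1".."S21"`, `"AS1".."AS23"`).
#' @param paired List of length-2 label vectors that must share chemistry.
#' @return An object of class `design_constraints`.
#' @examples
#' design_constraints(fixed_F = c("AS2", "AS6", "AS14", "S11"))
#' @export
design_constraints <- function(fixed_F = character(), fixed_OMe = character(),
                               paired = list(c("AS8", "AS9"))) {
  fixed_F <- unique(as.character(fixed_F))
  fixed_OMe <- unique(as.character(fixed_OMe))
  lapply(c(fixed_F, fixed_OMe, unlist(paired)), parse_position_label)
  conflict <- intersect(fixed_F, fixed_OMe)
  if (length(conflict)) {
    stop_chemmap(sprintf("infeasible constraints: position(s) %s fixed to both chemistries",
                         paste(conflict, collapse = ", ")),
                 "chemmap_infeasible")
  }
  paired <- lapply(paired, function(p) {
    p <- as.character(p)
    if (length(p) != 2L || p[1] == p[2]) {
      stop_chemmap("each paired constraint must name two distinct positions",
                   "chemmap_infeasible")
    }
    sort(p)
  })
  for (p in paired) {
    if ((p[1] %in% fixed_F && p[2] %in% fixed_OMe) ||
        (p[1] %in% fixed_OMe && p[2] %in% fixed_F)) {
      stop_chemmap(sprintf("infeasible constraints: pair (%s, %s) fixed to opposite chemistries",
                           p[1], p[2]), "chemmap_infeasible")
    }
  }
  structure(list(fixed_F = fixed_F, fixed_OMe = fixed_OMe, paired = paired),
            class = "design_constraints")
}

#' Predict the activity difference between two chemistry patterns
#'
#' Additive positional prediction: the sum, over positions where `pattern`
#' and `reference` differ, of the signed positional coefficient (`+delta_ln`
#' where the pattern has 2'-F and the reference 2'-OMe, `-delta_ln` for the
#' reverse). Negative totals predict improved silencing relative to the
#' reference.
#'
#' @param pattern,reference [chemistry_pattern()]s (or [duplex()]s).
#' @param map A `positional_map` (see [extract_positional_map()]).
#' @return Predicted ln-difference in fraction remaining.
#' @export
predict_delta_ln <- function(pattern, map, reference) {
  f1 <- pattern_to_F(pattern)
  f0 <- pattern_to_F(reference)
  diff_pos <- names(f1)[f1 != f0]
  if (!length(diff_pos)) return(0)
  idx <- match(diff_pos, map$label)
  if (anyNA(idx)) {
    stop_chemmap(sprintf("positional map lacks position(s): %s",
                         paste(diff_pos[is.na(idx)], collapse = ", ")),
                 "chemmap_structure_error")
  }
  bad <- !map$estimable[idx]
  if (any(bad)) {
    stop_chemmap(sprintf("inestimable coefficient at differing position(s): %s",
                         paste(diff_pos[bad], collapse = ", ")),
                 "chemmap_inestimable")
  }
  sum(ifelse(f1[diff_pos], 1, -1) * map$delta_ln[idx])
}

# Coefficient lookup with estimability check, for search internals.
map_coef <- function(map, labels) {
  if (!length(labels)) return(numeric(0))
  idx <- match(labels, map$label)
  ok <- !is.na(idx) & map$estimable[ifelse(is.na(idx), 1L, idx)]
  if (any(!ok)) {
    stop_chemmap(sprintf("inestimable coefficient at position(s): %s",
                         paste(labels[!ok], collapse = ", ")),
                 "chemmap_inestimable")
  }
  stats::setNames(map$delta_ln[idx], labels)
}

#' Propose minimal-2'-F designs under a positional map
#'
#' Formalizes the design-minimization goal — maintain predicted activity
#' while reducing 2'-F content — as: minimize the total number of 2'-F
#' positions subject to (i) all positional constraints and (ii) predicted
#' activity loss relative to the parent pattern of at most
#' `max_predicted_loss` on the natural-log scale. The search is exhaustive
#' over the free positions when there are at most `exhaustive_limit` free
#' units (paired positions count as one unit); above that a documented
#' greedy is used (starting from all-2'-F, iteratively convert to 2'-OMe the
#' unit whose coefficient sum is least harmful to convert, respecting pair
#' constraints) and results are flagged non-exhaustive. Ties in 2'-F count
#' are broken by better predicted activity, then lexicographic pattern
#' order.
#'
#' @param map A `positional_map`.
#' @param constraints A [design_constraints()].
#' @param parent Parent [chemistry_pattern()] (or duplex) — the activity
#'   reference.
#' @param max_predicted_loss Maximum tolerated predicted ln-loss (>= 0);
#'   default 0.1.
#' @param top_k Number of proposals to return (exhaustive mode).
#' @param strands `"both"` searches the combined 44-position pattern
#'   (strand designs are interdependent); `"sense"`/`"antisense"` freeze the
#'   other strand at the parent chemistry.
#' @param exhaustive_limit Maximum number of free units enumerated
#'   exhaustively (default 22, about 4M patterns).
#' @return An object of class `design_proposals`: data frame with columns
#'   `rank`, `n_F_total`, `predicted_delta_ln` (vs parent), `sense`,
#'   `antisense` (compact `F`/`o` strings) and a list column `pattern`;
#'   attribute `"exhaustive"` marks whether the search was exhaustive.
#' @export
propose_variants <- function(map, constraints = design_constraints(), parent,
                             max_predicted_loss = 0.1, top_k = 20L,
                             strands = c("both", "sense", "antisense"),
                             exhaustive_limit = 22L) {
  strands <- match.arg(strands)
  stopifnot(inherits(constraints, "design_constraints"))
  if (exhaustive_limit > 24L) {
    stop_chemmap("exhaustive_limit above 24 free units is not supported (memory)",
                 "chemmap_domain_error")
  }
  if (!is.numeric(max_predicted_loss) || max_predicted_loss < 0) {
    stop_chemmap("max_predicted_loss must be >= 0", "chemmap_domain_error")
  }
  parentF <- pattern_to_F(parent)
  labels <- position_labels()

  status <- stats::setNames(rep("free", 44L), labels)
  if (strands != "both") {
    frozen <- if (strands == "sense") grepl("^AS", labels) else !grepl("^AS", labels)
    status[frozen] <- ifelse(parentF[frozen], "F", "OMe")
  }
  status[constraints$fixed_F] <- "F"
  status[constraints$fixed_OMe] <- "OMe"

  # resolve pair constraints into units
  units <- as.list(labels[status == "free"])
  for (p in constraints$paired) {
    st <- status[p]
    if (all(st != "free")) {
      if (st[1] != st[2]) {
        stop_chemmap(sprintf("infeasible: pair (%s, %s) forced to opposite chemistries",
                             p[1], p[2]), "chemmap_infeasible")
      }
      next
    }
    if (any(st != "free")) { # one side fixed: the pair follows it
      status[p] <- st[st != "free"][1]
      units <- Filter(function(u) !any(u %in% p), units)
      next
    }
    units <- Filter(function(u) !any(u %in% p), units)
    units <- c(units, list(p))
  }

  fixed_pos <- labels[status != "free"]
  fixedF_pos <- labels[status == "F"]
  # positions whose chemistry can differ from the parent need a coefficient
  need <- union(unlist(units), fixed_pos[(status[fixed_pos] == "F") != parentF[fixed_pos]])
  coefs <- map_coef(map, need)
  coef_of <- function(pos) unname(coefs[pos])

  # delta(assignment) = C0 + sum_j isF_j * S_j  (vs parent)
  C0 <- 0
  diff_fixed <- fixed_pos[(status[fixed_pos] == "F") != parentF[fixed_pos]]
  if (length(diff_fixed)) {
    C0 <- sum(ifelse(status[diff_fixed] == "F", 1, -1) * coef_of(diff_fixed))
  }
  unit_S <- vapply(units, function(u) sum(coef_of(u)), numeric(1))
  unit_size <- vapply(units, length, integer(1))
  # constant part from free-unit positions that are F in the parent
  for (j in seq_along(units)) {
    pf <- units[[j]][parentF[units[[j]]]]
    if (length(pf)) C0 <- C0 - sum(coef_of(pf))
  }
  n_fixed_F <- sum(status == "F")
  m <- length(units)

  build_pattern <- function(isF_units) {
    isF <- status == "F"
    for (j in seq_len(m)) if (isF_units[j]) isF[units[[j]]] <- TRUE
    F_to_pattern(isF)
  }
  pattern_key <- function(pat) {
    paste(c(ifelse(pat$sense == "F", "F", "o"),
            ifelse(pat$antisense == "F", "F", "o")), collapse = "")
  }

  if (m <= exhaustive_limit) {
    delta <- C0
    count <- n_fixed_F
    for (j in seq_len(m)) { # recursive doubling over unit assignments
      delta <- c(delta, delta + unit_S[j])
      count <- c(count, count + unit_size[j])
    }
    feasible <- which(delta <= max_predicted_loss + 1e-12)
    if (!length(feasible)) {
      stop_chemmap("no pattern satisfies the constraints within max_predicted_loss",
                   "chemmap_infeasible")
    }
    ord <- feasible[order(count[feasible], delta[feasible])]
    cand <- utils::head(ord, max(1000L, 5L * top_k))
    decode <- function(idx) vapply(seq_len(m), function(j) {
      ((idx - 1L) %/% 2^(j - 1L)) %% 2 == 1
    }, logical(1))
    pats <- lapply(cand, function(i) build_pattern(decode(i)))
    keys <- vapply(pats, pattern_key, character(1))
    ord2 <- order(count[cand], delta[cand], keys)
    sel <- utils::head(ord2, top_k)
    res <- data.frame(rank = seq_along(sel),
                      n_F_total = count[cand][sel],
                      predicted_delta_ln = delta[cand][sel],
                      stringsAsFactors = FALSE)
    res$sense <- vapply(pats[sel], function(p) paste(ifelse(p$sense == "F", "F", "o"),
                                                     collapse = ""), character(1))
    res$antisense <- vapply(pats[sel], function(p) paste(ifelse(p$antisense == "F", "F", "o"),
                                                         collapse = ""), character(1))
    res$pattern <- pats[sel]
    exhaustive <- TRUE
  } else {
    isF_units <- rep(TRUE, m)
    delta <- C0 + sum(unit_S)
    ord <- order(unit_S, decreasing = TRUE) # least harmful to convert first
    for (j in ord) {
      new_delta <- delta - unit_S[j]
      if (new_delta <= max_predicted_loss + 1e-12 || new_delta < delta) {
        isF_units[j] <- FALSE
        delta <- new_delta
      }
    }
    if (delta > max_predicted_loss + 1e-12) {
      stop_chemmap("greedy search found no pattern within max_predicted_loss",
                   "chemmap_infeasible")
    }
    pat <- build_pattern(isF_units)
    res <- data.frame(rank = 1L,
                      n_F_total = n_fixed_F + sum(unit_size[isF_units]),
                      predicted_delta_ln = delta, stringsAsFactors = FALSE)
    res$sense <- paste(ifelse(pat$sense == "F", "F", "o"), collapse = "")
    res$antisense <- paste(ifelse(pat$antisense == "F", "F", "o"), collapse = "")
    res$pattern <- list(pat)
    exhaustive <- FALSE
  }
  attr(res, "exhaustive") <- exhaustive
  attr(res, "max_predicted_loss") <- max_predicted_loss
  class(res) <- c("design_proposals", "data.frame")
  res
}

#' @export
print.design_proposals <- function(x, ...) {
  cat(sprintf("Design proposals (%s search, predicted loss tolerance %.3g ln)\n",
              if (isTRUE(attr(x, "exhaustive"))) "exhaustive" else "greedy, non-exhaustive",
              attr(x, "max_predicted_loss")))
  df <- as.data.frame(x)[, c("rank", "n_F_total", "predicted_delta_ln",
                             "sense", "antisense")]
  df$predicted_delta_ln <- round(df$predicted_delta_ln, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
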