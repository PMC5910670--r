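#' Construct a 21/23-mer siRNA duplex
#'
#' The duplex architecture is a 21-nt sense (passenger) strand annealed to a
#' 23-nt antisense (guide) strand carrying a 2-nt 3' overhang. Antisense
#' position `i` is expected to be complementary to sense position `22 - i`
#' for `i` in 1..21; violations produce a warning rather than an error, since
#' strands may carry placeholder bases when only the chemistry pattern is of
#' interest.
#'
#' @param duplex_id Character identifier.
#' @param sense A 21-nt [modified_strand()].
#' @param antisense A 23-nt [modified_strand()].
#' @param check_complementarity Warn on base-pairing violations (default
#'   `TRUE`).
#' @return An object of class `duplex`.
#' @export
duplex <- function(duplex_id, sense, antisense, check_complementarity = TRUE) {
  stopifnot(is.character(duplex_id), length(duplex_id) == 1L,
            inherits(sense, "modified_strand"), inherits(antisense, "modified_strand"))
  if (length(sense) != 21L) {
    stop_chemmap(sprintf("sense strand must be 21 nt (got %d)", length(sense)),
                 "chemmap_domain_error")
  }
  if (length(antisense) != 23L) {
    stop_chemmap(sprintf("antisense strand must be 23 nt (got %d)", length(antisense)),
                 "chemmap_domain_error")
  }
  if (isTRUE(check_complementarity)) {
    sb <- strsplit(sense$bases, "", fixed = TRUE)[[1]]
    ab <- strsplit(antisense$bases, "", fixed = TRUE)[[1]]
    expect <- rev(rna_complement(sb))
    mism <- which(ab[1:21] != expect)
    if (length(mism)) {
      warning(sprintf("duplex '%s': antisense positions %s not complementary to sense",
                      duplex_id, paste(mism, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(duplex_id = duplex_id, sense = sense, antisense = antisense),
            class = "duplex")
}

#' @export
print.duplex <- function(x, ...) {
  cat(sprintf("siRNA duplex '%s' (21/23-mer)\n", x$duplex_id))
  cat("  sense:     ", write_strand_notation(x$sense), "\n", sep = "")
  cat("  antisense: ", write_strand_notation(x$antisense), "\n", sep = "")
  invisible(x)
}

#' Base-free chemistry pattern of a duplex
#'
#' A `chemistry_pattern` keeps only the per-position ribosugar chemistry of
#' the two strands (no nucleobases), which is how duplexes are encoded for
#' the sequence-agnostic positional model.
#'
#' @param sense_chem Character vector of length 21 over `{"F", "OMe"}`.
#' @param antisense_chem Character vector of length 23 over `{"F", "OMe"}`.
#' @return An object of class `chemistry_pattern`.
#' @examples
#' p <- chemistry_pattern(rep("OMe", 21), rep("OMe", 23))
#' @export
chemistry_pattern <- function(sense_chem, antisense_chem) {
  sense_chem <- as.character(sense_chem)
  antisense_chem <- as.character(antisense_chem)
  if (length(sense_chem) != 21L || length(antisense_chem) != 23L) {
    stop_chemmap("chemistry pattern must have 21 sense and 23 antisense entries",
                 "chemmap_domain_error")
  }
  if (!all(c(sense_chem, antisense_chem) %in% c("F", "OMe"))) {
    stop_chemmap("chemistry entries must be \"F\" or \"OMe\"", "chemmap_domain_error")
  }
  structure(list(sense = sense_chem, antisense = antisense_chem),
            class = "chemistry_pattern")
}

#' @rdname chemistry_pattern
#' @param x A [duplex()] or `chemistry_pattern`.
#' @export
as_chemistry_pattern <- function(x) {
  if (inherits(x, "chemistry_pattern")) return(x)
  if (inherits(x, "duplex")) return(chemistry_pattern(x$sense$sugar, x$antisense$sugar))
  stop_chemmap("cannot coerce to chemistry_pattern", "chemmap_domain_error")
}

#' @export
print.chemistry_pattern <- function(x, ...) {
  compact <- function(v) paste(ifelse(v == "F", "F", "o"), collapse = "")
  cat("Chemistry pattern (F = 2'-F, o = 2'-OMe)\n")
  cat("  sense 5'->3':     ", compact(x$sense), "\n", sep = "")
  cat("  antisense 5'->3': ", compact(x$antisense), "\n", sep = "")
  invisible(x)
}

# Canonical position labels: S1..S21 then AS1..AS23.
position_labels <- function() c(paste0("S", 1:21), paste0("AS", 1:23))

# Logical is-2'-F vector of length 44 named by position label.
pattern_to_F <- function(pattern) {
  pattern <- as_chemistry_pattern(pattern)
  stats::setNames(c(pattern$sense == "F", pattern$antisense == "F"), position_labels())
}

# Inverse of pattern_to_F.
F_to_pattern <- function(is_F) {
  stopifnot(length(is_F) == 44L)
  chemistry_pattern(ifelse(is_F[1:21], "F", "OMe"), ifelse(is_F[22:44], "F", "OMe"))
}

# Split a position label like "AS14" into strand/index.
parse_position_label <- function(label) {
  m <- regmatches(label, regexec("^(AS|S)([0-9]+)$", label))[[1]]
  if (length(m) != 3L) {
    stop_chemmap(sprintf("invalid position label '%s' (use S1..S21 or AS1..AS23)", label),
                 "chemmap_domain_error")
  }
  strand <- if (m[2] == "S") "sense" else "antisense"
  pos <- as.integer(m[3])
  max_pos <- if (strand == "sense") 21L else 23L
  if (pos < 1L || pos > max_pos) {
    stop_chemmap(sprintf("position '%s' outside its strand (1..%d)", label, max_pos),
                 "chemmap_domain_error")
  }
  list(strand = strand, position = pos)
}
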