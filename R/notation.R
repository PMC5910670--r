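#' Construct a chemically modified siRNA strand
#'
#' A `modified_strand` records the nucleobase sequence of one siRNA strand
#' together with its per-position ribosugar chemistry (2'-deoxy-2'-fluoro,
#' `"F"`, or 2'-O-methyl, `"OMe"`), the positions of phosphorothioate (PS)
#' backbone linkages, and an optional 3'-terminal conjugate such as the
#' triantennary GalNAc ligand used for hepatocyte delivery.
#'
#' Positions are 1-based from the strand's 5' end. A PS linkage index `i` in
#' `ps_after` denotes a phosphorothioate between residues `i` and `i + 1`, so
#' valid indices run from 1 to `length - 1`.
#'
#' @param bases Character scalar over the RNA alphabet `A`, `C`, `G`, `U`
#'   (case-insensitive), or a character vector of single bases.
#' @param sugar Character vector with one entry per base, each `"F"` or
#'   `"OMe"`.
#' @param ps_after Integer vector of 1-based linkage positions.
#' @param conjugate `NULL` or a single tag such as `"GalNAc"`; the dialect
#'   only supports 3'-terminal conjugation.
#' @return An object of class `modified_strand`: a list with elements
#'   `bases` (character scalar), `sugar`, `ps_after` (sorted integer), and
#'   `conjugate`.
#' @seealso [parse_strand_notation()], [write_strand_notation()],
#'   [pattern_stats()]
#' @examples
#' s <- modified_strand("ACGU", c("F", "F", "OMe", "OMe"), ps_after = c(1, 2))
#' write_strand_notation(s)
#' @export
modified_strand <- function(bases, sugar, ps_after = integer(), conjugate = NULL) {
  if (length(bases) == 1L && nchar(bases) > 1L) {
    bases <- strsplit(bases, "", fixed = TRUE)[[1]]
  }
  bases <- toupper(as.character(bases))
  if (length(bases) == 0L) {
    stop_chemmap("a strand must contain at least one residue", "chemmap_parse_error")
  }
  bad <- !bases %in% c("A", "C", "G", "U")
  if (any(bad)) {
    stop_chemmap(sprintf("invalid base(s): %s", paste(unique(bases[bad]), collapse = ", ")),
                 "chemmap_domain_error")
  }
  sugar <- as.character(sugar)
  if (length(sugar) != length(bases)) {
    stop_chemmap("length(sugar) must equal the number of bases", "chemmap_domain_error")
  }
  if (!all(sugar %in% c("F", "OMe"))) {
    stop_chemmap("sugar entries must be \"F\" or \"OMe\"", "chemmap_domain_error")
  }
  ps_after <- sort(unique(as.integer(ps_after)))
  n <- length(bases)
  if (length(ps_after) && (any(ps_after < 1L) || any(ps_after > n - 1L))) {
    stop_chemmap(sprintf("ps_after indices must lie in [1, %d]", n - 1L),
                 "chemmap_linkage_error")
  }
  if (!is.null(conjugate)) {
    conjugate <- as.character(conjugate)
    stopifnot(length(conjugate) == 1L)
  }
  structure(
    list(bases = paste(bases, collapse = ""), sugar = sugar,
         ps_after = ps_after, conjugate = conjugate),
    class = "modified_strand"
  )
}

#' @export
length.modified_strand <- function(x) nchar(x$bases)

#' @export
print.modified_strand <- function(x, ...) {
  st <- pattern_stats(x)
  cat(sprintf("Modified siRNA strand: %d nt (%d x 2'-F, %d x 2'-OMe, %d PS)%s\n",
              length(x), st$n_F, st$n_OMe, st$n_PS,
              if (is.null(x$conjugate)) "" else paste0(", 3'-", x$conjugate)))
  cat("  ", write_strand_notation(x), "\n", sep = "")
  invisible(x)
}

#' Parse modified-oligonucleotide shorthand into a strand object
#'
#' The notation dialect mirrors common modified-siRNA shorthand: a lowercase
#' letter (`a`, `c`, `g`, `u`) is a 2'-O-methyl residue; an uppercase letter
#' followed by `f` (`Af`, `Cf`, `Gf`, `Uf`) is a 2'-fluoro residue; `s`
#' between two residues marks a phosphorothioate linkage; a trailing `-L96`
#' marks the 3'-GalNAc conjugate.
#'
#' @param text A non-empty notation string, e.g. `"asusc"` or `"AfsCfsgu"`.
#' @return A [modified_strand()].
#' @details Errors name the 1-based character offset of the first offending
#'   token. An `s` at the start or end of the strand, or two `s` in a row,
#'   is a linkage-placement error.
#' @examples
#' parse_strand_notation("AfsCfsgu")
#' @export
parse_strand_notation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) stop_chemmap("empty notation string", "chemmap_parse_error")
  conjugate <- NULL
  if (grepl("-L96$", text)) {
    conjugate <- "GalNAc"
    text <- sub("-L96$", "", text)
    if (!nzchar(text)) stop_chemmap("conjugate tag without residues", "chemmap_parse_error")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bases <- character()
  sugar <- character()
  ps_after <- integer()
  last_was_s <- FALSE
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("a", "c", "g", "u")) {
      bases <- c(bases, toupper(ch))
      sugar <- c(sugar, "OMe")
      last_was_s <- FALSE
      i <- i + 1L
    } else if (ch %in% c("A", "C", "G", "U")) {
      if (i == n || chars[i + 1L] != "f") {
        stop_chemmap(sprintf(
          "parse error at offset %d: uppercase '%s' must be followed by 'f' (2'-F residue)",
          i, ch), "chemmap_parse_error")
      }
      bases <- c(bases, ch)
      sugar <- c(sugar, "F")
      last_was_s <- FALSE
      i <- i + 2L
    } else if (ch == "s") {
      if (length(bases) == 0L) {
        stop_chemmap(sprintf("linkage-placement error at offset %d: 's' before any residue", i),
                     "chemmap_linkage_error")
      }
      if (last_was_s) {
        stop_chemmap(sprintf("linkage-placement error at offset %d: doubled 's'", i),
                     "chemmap_linkage_error")
      }
      ps_after <- c(ps_after, length(bases))
      last_was_s <- TRUE
      i <- i + 1L
    } else {
      stop_chemmap(sprintf("parse error at offset %d: unknown token '%s'", i, ch),
                   "chemmap_parse_error")
    }
  }
  if (last_was_s) {
    stop_chemmap(sprintf("linkage-placement error at offset %d: strand ends in 's'", n),
                 "chemmap_linkage_error")
  }
  modified_strand(bases, sugar, ps_after = ps_after, conjugate = conjugate)
}

#' Write a strand object back to notation shorthand
#'
#' Inverse of [parse_strand_notation()]:
#' `parse_strand_notation(write_strand_notation(s))` reproduces `s` for every
#' valid strand.
#'
#' @param strand A [modified_strand()].
#' @return A notation string.
#' @examples
#' write_strand_notation(modified_strand("AUC", rep("OMe", 3), ps_after = c(1, 2)))
#' @export
write_strand_notation <- function(strand) {
  stopifnot(inherits(strand, "modified_strand"))
  bases <- strsplit(strand$bases, "", fixed = TRUE)[[1]]
  toks <- ifelse(strand$sugar == "F", paste0(bases, "f"), tolower(bases))
  n <- length(bases)
  out <- character(0)
  for (i in seq_len(n)) {
    out <- c(out, toks[i])
    if (i %in% strand$ps_after) out <- c(out, "s")
  }
  paste0(paste(out, collapse = ""), if (!is.null(strand$conjugate)) "-L96" else "")
}

#' Summary counts of a strand's chemistry
#'
#' @param strand A [modified_strand()].
#' @return A list with `n_F`, `n_OMe` (ribosugar counts; they sum to the
#'   strand length) and `n_PS` (number of phosphorothioate linkages).
#' @examples
#' pattern_stats(parse_strand_notation("AfsCfsgu"))
#' @export
pattern_stats <- function(strand) {
  stopifnot(inherits(strand, "modified_strand"))
  list(n_F = sum(strand$sugar == "F"),
       n_OMe = sum(strand$sugar == "OMe"),
       n_PS = length(strand$ps_after))
}

#' Number of two-chemistry modification patterns for a strand
#'
#' With two ribosugar chemistries per position, a strand of length `L` admits
#' `2^L` modification patterns (2,097,152 for a 21-mer sense strand and
#' 8,388,608 for a 23-mer antisense strand) — the design space the positional
#' model samples from.
#'
#' @param strand_length Non-negative integer.
#' @return `2^strand_length` as an exact double (exact up to length 53).
#' @examples
#' design_space_size(21)
#' @export
design_space_size <- function(strand_length) {
  stopifnot(is.numeric(strand_length), length(strand_length) == 1L)
  if (is.na(strand_length) || strand_length < 0 || strand_length != floor(strand_length)) {
    stop_chemmap("strand_length must be a non-negative integer", "chemmap_domain_error")
  }
  if (strand_length > 53) {
    stop_chemmap("strand_length too large for exact integer arithmetic", "chemmap_domain_error")
  }
  2^strand_length
}
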