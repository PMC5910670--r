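# Reference design fixtures.
#
# The parent Enhanced Stabilization Chemistry (ESC) template and the design
# variants below are figure-derived reconstructions: the source figures show
# modification patterns only as coloured squares, so the exact patterns are
# not ground truth. The reconstruction is anchored to the printed aggregate
# facts that ARE asserted by tests: the parent antisense strand carries nine
# 2'-F residues; removing 2'-F at AS4/AS10/AS18/AS20 and applying the AS8/AS9
# pair rule yields six (pair-F) and four (pair-OMe) antisense 2'-F; PS
# linkages sit after sense positions 1,2 and antisense positions 1,2,21,22;
# GalNAc is conjugated to the sense 3' end. Bases are a synthetic placeholder
# sequence (target sequences are not reproduced here); the antisense is built
# as the exact reverse complement of the sense over positions 1-21 with a UU
# 3' overhang.

ref_chem <- function(len, f_positions) {
  chem <- rep("OMe", len)
  chem[f_positions] <- "F"
  chem
}

# 2'-F position sets for the shipped designs (1-based from each 5' end).
ref_design_F_sets <- function() {
  list(
    parent = list(sense = seq(1, 21, by = 2),            # 11 x 2'-F
                  antisense = c(2, 4, 6, 8, 10, 14, 16, 18, 20)), # 9 x 2'-F
    dv5  = list(sense = seq(1, 21, by = 2), antisense = c(2, 6, 9, 14, 16)),
    dv6  = list(sense = seq(1, 21, by = 2), antisense = c(2, 6, 14, 16)),
    dv7  = list(sense = seq(1, 21, by = 2), antisense = c(2, 6, 8, 9, 14, 16)),
    dv18 = list(sense = c(6, 9, 11, 13), antisense = c(2, 6, 8, 9, 14, 16)),
    dv22 = list(sense = c(6, 9, 11, 13), antisense = c(2, 6, 14, 16))
  )
}

#' Packaged reference siRNA designs (figure-derived fixtures)
#'
#' Returns the parent fully 2'-modified template and a set of reduced-2'-F
#' design variants (DV5-DV7 antisense series; DV18 and DV22 combination
#' designs) as [duplex()] objects. Modification patterns are reconstructions
#' from published pattern graphics and are not ground truth; only their
#' aggregate properties (the parent antisense's nine 2'-F residues, the
#' terminal PS architecture, the DV6/DV7 antisense 2'-F counts of four and
#' six) are authoritative. Bases are a synthetic placeholder sequence.
#'
#' @return Named list of `duplex` objects with an attribute
#'   `"provenance" = "figure-derived, not ground truth; synthetic bases"`.
#' @examples
#' pattern_stats(reference_designs()$parent$antisense)$n_F # nine
#' @export
reference_designs <- function() {
  sense_bases <- "ACGUUAGCAUCGAAUGCUAGA" # synthetic placeholder, 21 nt
  sb <- strsplit(sense_bases, "", fixed = TRUE)[[1]]
  as_bases <- c(rev(rna_complement(sb)), "U", "U") # 23 nt, UU 3' overhang
  sets <- ref_design_F_sets()
  out <- lapply(names(sets), function(id) {
    s <- sets[[id]]
    duplex(
      duplex_id = id,
      sense = modified_strand(sb, ref_chem(21L, s$sense),
                              ps_after = c(1L, 2L), conjugate = "GalNAc"),
      antisense = modified_strand(as_bases, ref_chem(23L, s$antisense),
                                  ps_after = c(1L, 2L, 21L, 22L)),
      check_complementarity = FALSE
    )
  })
  names(out) <- names(sets)
  attr(out, "provenance") <- "figure-derived, not ground truth; synthetic bases"
  out
}

#' Read a duplex table of notation strings
#'
#' Reads a tab-separated table with columns `duplex_id`, `sense_notation`,
#' `antisense_notation` and parses each row into a [duplex()].
#'
#' @param path Path to a TSV file.
#' @return Named list of `duplex` objects.
#' @seealso [validate_duplexes()]
#' @export
read_duplex_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("duplex_id", "sense_notation", "antisense_notation")
  if (!all(need %in% names(tab))) {
    stop_chemmap(sprintf("duplex table must have columns: %s", paste(need, collapse = ", ")),
                 "chemmap_io_error")
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    duplex(tab$duplex_id[i],
           parse_strand_notation(tab$sense_notation[i]),
           parse_strand_notation(tab$antisense_notation[i]))
  })
  names(out) <- tab$duplex_id
  out
}

#' Validate a duplex table
#'
#' Per-duplex validation report: parseability, strand lengths, PS
#' architecture (sense PS after positions 1,2; antisense PS after 1,2,21,22)
#' and chemistry counts.
#'
#' @param x Path to a duplex TSV (see [read_duplex_table()]) or a named list
#'   of [duplex()] objects.
#' @return A data frame with one row per duplex: `duplex_id`, `valid`,
#'   `n_F_sense`, `n_F_antisense`, `n_PS_sense`, `n_PS_antisense`,
#'   `standard_ps`, `message`.
#' @export
validate_duplexes <- function(x) {
  if (is.character(x)) {
    tab <- utils::read.delim(x, stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      res <- tryCatch(
        withCallingHandlers(
          list(d = duplex(tab$duplex_id[i],
                          parse_strand_notation(tab$sense_notation[i]),
                          parse_strand_notation(tab$antisense_notation[i])),
               msg = ""),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) list(d = NULL, msg = conditionMessage(e)))
      validate_one(tab$duplex_id[i], res$d, res$msg)
    })
  } else {
    rows <- lapply(x, function(d) validate_one(d$duplex_id, d, ""))
  }
  do.call(rbind, rows)
}

validate_one <- function(id, d, msg) {
  if (is.null(d)) {
    return(data.frame(duplex_id = id, valid = FALSE, n_F_sense = NA_integer_,
                      n_F_antisense = NA_integer_, n_PS_sense = NA_integer_,
                      n_PS_antisense = NA_integer_, standard_ps = NA,
                      message = msg, stringsAsFactors = FALSE))
  }
  ss <- pattern_stats(d$sense)
  as <- pattern_stats(d$antisense)
  std <- identical(d$sense$ps_after, c(1L, 2L)) &&
    identical(d$antisense$ps_after, c(1L, 2L, 21L, 22L))
  data.frame(duplex_id = id, valid = TRUE, n_F_sense = ss$n_F,
             n_F_antisense = as$n_F, n_PS_sense = ss$n_PS,
             n_PS_antisense = as$n_PS, standard_ps = std, message = "",
             stringsAsFactors = FALSE)
}
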