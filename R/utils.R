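# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the stream so we have something to restore
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# RNA complement; input and output are character vectors of single bases.
rna_complement <- function(bases) {
  comp <- c(A = "U", U = "A", C = "G", G = "C")
  unname(comp[bases])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_chemmap <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "chemmap_error")))
}
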