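# internal helpers shared across modules

stop_input <- function(...) stop(..., call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded simulation helpers do
#' not perturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# vectorized reverse complement on plain character vectors
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0L))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x)
}

# open a (possibly gzipped) connection for text reading
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, open = "rt") else file(path, open = "rt")
}

check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || anyNA(seq)) {
    stop_input(what, " must be a character vector without NA")
  }
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop_input(what, " contains characters outside A,C,G,T,N ",
               "(lowercase or non-IUPAC input is rejected)")
  }
  invisible(seq)
}
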