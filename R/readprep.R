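#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records (plain or gzipped). Sequence and quality
#' lengths must agree; a truncated trailing record raises an error naming
#' the record index.
#'
#' @param path FASTQ file, optionally `.gz`.
#' @return Data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(0L), seq = character(0L),
                      qual = character(0L), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop_input(sprintf("truncated FASTQ record at record %d", n %/% 4L + 1L))
  }
  ids <- lines[seq(1L, n, by = 4L)]
  if (any(substr(ids, 1L, 1L) != "@")) {
    bad <- which(substr(ids, 1L, 1L) != "@")[1L]
    stop_input(sprintf("malformed FASTQ header at record %d", bad))
  }
  seqs <- lines[seq(2L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  if (any(nchar(seqs) != nchar(quals))) {
    bad <- which(nchar(seqs) != nchar(quals))[1L]
    stop_input(sprintf("sequence/quality length mismatch at record %d", bad))
  }
  data.frame(id = sub("^@", "", ids), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads Data frame with `id`, `seq`, `qual`.
#' @param path Output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    out <- character(4L * nrow(reads))
    out[seq(1L, length(out), 4L)] <- paste0("@", reads$id)
    out[seq(2L, length(out), 4L)] <- reads$seq
    out[seq(3L, length(out), 4L)] <- "+"
    out[seq(4L, length(out), 4L)] <- reads$qual
    writeLines(out, con)
  }
  invisible(path)
}

#' Trim DamID adaptors from reads
#'
#' Removes the DamID PCR primer from the 5' end (the longest read prefix
#' matching a suffix of the primer, allowing a mismatch rate of
#' `max_error_rate` and requiring at least `min_overlap` matching bases)
#' and the index adaptor from the 3' end (adaptor prefix matching the read
#' suffix, same tolerance), with qualities trimmed in register. Matching
#' repeats until a fixed point so that trimming is idempotent; untrimmable
#' reads pass through unchanged.
#'
#' @param reads Data frame `id`, `seq`, `qual` (see [read_fastq()]).
#' @param adaptors List with `five_prime` and `three_prime` sequences;
#'   defaults to [damid_adaptors()].
#' @param max_error_rate Allowed mismatch fraction per overlap.
#' @param min_overlap Minimum overlap length considered a match.
#' @return Data frame of the same shape with trimmed `seq`/`qual`.
#' @export
trim_reads <- function(reads, adaptors = damid_adaptors(),
                       max_error_rate = 0.1, min_overlap = 3L) {
  stopifnot(all(c("seq", "qual") %in% names(reads)))
  if (nrow(reads) == 0L) return(reads)
  seqs <- reads$seq
  quals <- reads$qual
  active <- rep(TRUE, length(seqs))
  # iterate to a fixed point; each pass can expose a new terminal match
  while (any(active)) {
    res <- trim_pass(seqs[active], adaptors, max_error_rate, min_overlap)
    changed <- res$lstrip > 0L | res$rstrip > 0L
    idx <- which(active)
    if (any(changed)) {
      ci <- idx[changed]
      ls <- res$lstrip[changed]
      rs <- res$rstrip[changed]
      newlen <- nchar(seqs[ci]) - ls - rs
      seqs[ci] <- substr(seqs[ci], ls + 1L, ls + newlen)
      quals[ci] <- substr(quals[ci], ls + 1L, ls + newlen)
    }
    active[idx[!changed]] <- FALSE
    active[idx[changed]] <- nchar(seqs[idx[changed]]) > 0L
  }
  reads$seq <- seqs
  reads$qual <- quals
  reads
}

# one matching pass via Biostrings::trimLRPatterns; returns per-read
# numbers of bases to strip at each end. Mismatch tolerance per overlap
# width o is floor(rate * o); overlaps below min_overlap never match.
trim_pass <- function(seqs, adaptors, rate, min_overlap) {
  dna <- Biostrings::DNAStringSet(seqs)
  widths <- Biostrings::width(dna)
  mm_vec <- function(adaptor) {
    w <- seq_len(nchar(adaptor))
    ifelse(w < min_overlap, -1, floor(rate * w))
  }
  kept <- Biostrings::trimLRPatterns(
    Lpattern = adaptors$five_prime, Rpattern = adaptors$three_prime,
    subject = dna,
    max.Lmismatch = mm_vec(adaptors$five_prime),
    max.Rmismatch = mm_vec(adaptors$three_prime),
    with.Lindels = FALSE, with.Rindels = FALSE, ranges = TRUE)
  list(lstrip = IRanges::start(kept) - 1L,
       rstrip = widths - IRanges::end(kept))
}

#' Length-filter trimmed reads
#'
#' Keeps reads whose length lies in `[min_len, max_len]`, mirroring the
#' post-trimming filter used for DamID libraries (defaults 30 and 50 nt
#' for SE50 sequencing).
#'
#' @param reads Data frame `id`, `seq`, `qual`.
#' @param min_len,max_len Inclusive length bounds.
#' @return List with `reads` (kept rows) and `counts`, a named integer
#'   vector `kept`, `too_short`, `too_long` partitioning the input.
#' @export
length_filter <- function(reads, min_len = 30L, max_len = 50L) {
  if (min_len > max_len) stop_input("min_len must not exceed max_len")
  len <- nchar(reads$seq)
  keep <- len >= min_len & len <= max_len
  counts <- c(kept = sum(keep), too_short = sum(len < min_len),
              too_long = sum(len > max_len))
  list(reads = reads[keep, , drop = FALSE], counts = counts)
}

#' Per-file read QC summary
#'
#' Read count and length histogram, suitable for a TSV report aggregating
#' trimming results across libraries.
#'
#' @param reads Data frame `id`, `seq`, `qual`.
#' @return List with `n_reads` and `length_histogram` (table).
#' @export
read_qc_summary <- function(reads) {
  list(n_reads = nrow(reads),
       length_histogram = table(nchar(reads$seq)))
}
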