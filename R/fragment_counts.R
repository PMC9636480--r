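#' Exact-match toy aligner
#'
#' Places each read at the unique exact occurrence of its sequence (or its
#' reverse complement) in the genome. Reads matching more than once are
#' counted as multimapped and reads with no match (including reads
#' containing N) as unaligned; neither is reported as an alignment. This
#' is sufficient for simulator-derived reads on toy genomes, where inserts
#' are genuine genome substrings.
#'
#' @param reads Data frame with a `seq` column (and optionally `id`).
#' @param genome Named character genome.
#' @return List with `alignments` (data.frame `chrom`, `start` (0-based),
#'   `strand`, `length`) and `stats` (named counts `aligned`, `unaligned`,
#'   `multimapped`).
#' @export
align_exact <- function(reads, genome) {
  genome <- as_genome(genome)
  seqs <- reads$seq
  n <- length(seqs)
  empty <- data.frame(chrom = character(0L), start = integer(0L),
                      strand = character(0L), length = integer(0L),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(alignments = empty,
                stats = c(aligned = 0L, unaligned = 0L, multimapped = 0L)))
  }
  clean <- !grepl("[^ACGT]", seqs) & nchar(seqs) > 0L
  uniq <- unique(seqs[clean])
  # per-unique-sequence occurrence count and single placement
  hit_n <- stats::setNames(integer(length(uniq)), uniq)
  hit_chrom <- stats::setNames(character(length(uniq)), uniq)
  hit_start <- stats::setNames(integer(length(uniq)), uniq)
  hit_strand <- stats::setNames(character(length(uniq)), uniq)
  if (length(uniq) > 0L) {
    widths <- nchar(uniq)
    subjects <- lapply(genome, Biostrings::DNAString)
    for (w in sort(unique(widths))) {
      grp <- uniq[widths == w]
      fwd <- Biostrings::DNAStringSet(grp)
      rev <- Biostrings::reverseComplement(fwd)
      for (strand in c("+", "-")) {
        pd <- Biostrings::PDict(if (strand == "+") fwd else rev)
        for (chr in names(subjects)) {
          mi <- Biostrings::matchPDict(pd, subjects[[chr]])
          starts <- Biostrings::startIndex(mi)
          cnt <- lengths(starts)
          has <- which(cnt > 0L)
          for (j in has) {
            key <- grp[j]
            hit_n[key] <- hit_n[key] + cnt[j]
            hit_chrom[key] <- chr
            hit_start[key] <- starts[[j]][1L] - 1L
            hit_strand[key] <- strand
          }
        }
      }
    }
  }
  occ <- integer(n)
  occ[clean] <- hit_n[seqs[clean]]
  aligned <- clean & occ == 1L
  stats <- c(aligned = sum(aligned),
             unaligned = sum(occ == 0L | !clean),
             multimapped = sum(occ > 1L))
  key <- seqs[aligned]
  aln <- data.frame(chrom = unname(hit_chrom[key]),
                    start = unname(hit_start[key]),
                    strand = unname(hit_strand[key]),
                    length = nchar(key),
                    stringsAsFactors = FALSE)
  list(alignments = aln, stats = stats)
}

#' Ingest alignments from SAM text
#'
#' Reads the minimal SAM subset used downstream: header lines are skipped;
#' per record only FLAG (0x4 marks unmapped and is skipped, 0x10 sets the
#' minus strand), RNAME, POS (1-based, converted to 0-based) and the SEQ
#' length are used. Records with fewer than 11 mandatory columns raise a
#' format error naming the line.
#'
#' @param path SAM text file.
#' @return Data frame `chrom`, `start`, `strand`, `length`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  out <- data.frame(chrom = character(0L), start = integer(0L),
                    strand = character(0L), length = integer(0L),
                    stringsAsFactors = FALSE)
  if (length(body) == 0L) return(out)
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  short <- lengths(parts) < 11L
  if (any(short)) {
    stop_input(sprintf("SAM record missing mandatory columns at line %d",
                       body[which(short)[1L]]))
  }
  flag <- as.integer(vapply(parts, `[[`, "", 2L))
  mapped <- bitwAnd(flag, 4L) == 0L
  parts <- parts[mapped]
  flag <- flag[mapped]
  data.frame(
    chrom = vapply(parts, `[[`, "", 3L),
    start = as.integer(vapply(parts, `[[`, "", 4L)) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    length = nchar(vapply(parts, `[[`, "", 10L)),
    stringsAsFactors = FALSE
  )
}

# extend alignments to `extension` bp in strand direction (never shorter
# than the read itself), clipped at chromosome ends; 0-based half-open
extend_alignments <- function(aln, extension, seqlengths) {
  unknown <- setdiff(unique(aln$chrom), names(seqlengths))
  if (length(unknown) > 0L) {
    stop_input("unknown chromosome in alignments: ",
               paste(unknown, collapse = ", "))
  }
  ext <- pmax(extension, aln$length)
  L <- unname(seqlengths[aln$chrom])
  s <- ifelse(aln$strand == "+", aln$start, aln$start + aln$length - ext)
  e <- ifelse(aln$strand == "+", aln$start + ext, aln$start + aln$length)
  data.frame(chrom = aln$chrom, start = pmax(0L, as.integer(s)),
             end = pmin(L, as.integer(e)), stringsAsFactors = FALSE)
}

#' Accumulate per-GATC-fragment read weights
#'
#' Each alignment is extended to `extension` bp in its strand direction
#' (clipped at chromosome ends; an extension shorter than the read keeps
#' the read's own length) and its unit weight distributed over the GATC
#' fragments it overlaps, proportionally to overlap length. Total weight
#' therefore equals the aligned read count exactly.
#'
#' @param alignments Data frame `chrom`, `start`, `strand`, `length`.
#' @param map A `gatc_map`.
#' @param extension Extension length in bp (default 300).
#' @param mode `"fractional"` (overlap-proportional, default) or `"all"`
#'   (full unit weight to every overlapped fragment).
#' @return Object of class `fragment_counts`: list with `map`, `weights`
#'   (numeric, one per fragment row of `map`), `library_size`.
#' @export
count_fragments <- function(alignments, map, extension = 300L,
                            mode = c("fractional", "all")) {
  stopifnot(inherits(map, "gatc_map"))
  mode <- match.arg(mode)
  f <- map$fragments
  weights <- numeric(nrow(f))
  ext <- extend_alignments(alignments, extension, map$seqlengths)
  for (chr in unique(ext$chrom)) {
    sel <- ext$chrom == chr
    frow <- which(f$chrom == chr)
    reads_ir <- IRanges::IRanges(start = ext$start[sel] + 1L,
                                 end = ext$end[sel])
    frag_ir <- IRanges::IRanges(start = f$start[frow] + 1L,
                                end = f$end[frow])
    hits <- IRanges::findOverlaps(reads_ir, frag_ir)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(reads_ir[qh], frag_ir[sh]))
    contrib <- if (mode == "fractional") {
      ov / IRanges::width(reads_ir)[qh]
    } else {
      rep(1, length(ov))
    }
    acc <- rowsum(contrib, group = sh)
    weights[frow[as.integer(rownames(acc))]] <-
      weights[frow[as.integer(rownames(acc))]] + as.numeric(acc)
  }
  structure(list(map = map, weights = weights,
                 library_size = nrow(alignments)),
            class = "fragment_counts")
}

#' @export
print.fragment_counts <- function(x, ...) {
  cat(sprintf("<fragment_counts> %d fragments, library size %d, total weight %.2f\n",
              length(x$weights), x$library_size, sum(x$weights)))
  invisible(x)
}

#' Bin the genome and count extended-read presence
#'
#' Reads are extended to `extension` bp (default 150) and each bin of
#' `bin_size` bp (default 500; the last bin of a chromosome may be short)
#' counts the number of extended reads overlapping it by at least 1 bp.
#'
#' @param alignments Data frame `chrom`, `start`, `strand`, `length`.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param bin_size Bin width in bp.
#' @param extension Read extension in bp.
#' @return Object of class `binned_coverage`: list with `bins` (data.frame
#'   `chrom`, `start`, `end`), `count`, `bin_size`, `extension`.
#' @export
bin_coverage <- function(alignments, chrom_sizes, bin_size = 500L,
                         extension = 150L) {
  if (bin_size <= 0L) stop_input("bin_size must be positive")
  if (is.data.frame(chrom_sizes)) {
    chrom_sizes <- stats::setNames(as.integer(chrom_sizes[[2L]]),
                                   chrom_sizes[[1L]])
  }
  bins <- do.call(rbind, lapply(names(chrom_sizes), function(chr) {
    L <- chrom_sizes[[chr]]
    starts <- seq(0L, L - 1L, by = bin_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + bin_size, L), stringsAsFactors = FALSE)
  }))
  count <- integer(nrow(bins))
  if (nrow(alignments) > 0L) {
    ext <- extend_alignments(alignments, extension, chrom_sizes)
    offset <- 0L
    for (chr in names(chrom_sizes)) {
      nb <- sum(bins$chrom == chr)
      sel <- which(ext$chrom == chr)
      if (length(sel) > 0L) {
        b1 <- ext$start[sel] %/% bin_size
        b2 <- (ext$end[sel] - 1L) %/% bin_size
        span <- b2 - b1
        for (k in 0:max(span)) {
          idx <- b1[span >= k] + k
          count[offset + seq_len(nb)] <- count[offset + seq_len(nb)] +
            tabulate(idx + 1L, nbins = nb)
        }
      }
      offset <- offset + nb
    }
  }
  structure(list(bins = bins, count = count, bin_size = as.integer(bin_size),
                 extension = as.integer(extension)),
            class = "binned_coverage")
}

#' Read / write a chrom.sizes TSV
#'
#' Two columns, chromosome name and length, as used by genome-browser
#' tooling.
#'
#' @param path File path.
#' @param sizes Named integer vector.
#' @return `read_chrom_sizes` returns a named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("chrom.sizes must have two columns")
  stats::setNames(as.integer(df[[2L]]), df[[1L]])
}

#' @rdname read_chrom_sizes
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), unname(sizes)), path)
  invisible(path)
}
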