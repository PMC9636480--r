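#' Find GATC motif positions in a DNA sequence
#'
#' DamID methylation happens exclusively at adenines within GATC motifs, so
#' the positions of the motif define the resolution of the whole assay.
#' The scan is exhaustive; `GATC` cannot overlap itself, so a fixed-pattern
#' scan finds every occurrence.
#'
#' @param seq A single uppercase DNA string over the alphabet A,C,G,T,N.
#' @return Integer vector of 0-based motif start positions, strictly
#'   increasing. Motifs touching an `N` never match.
#' @export
#' @examples
#' find_gatc_sites("GATCGATCA")  # 0, 4
find_gatc_sites <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop_input("seq must be a single DNA string")
  }
  check_dna(seq, "seq")
  hits <- gregexpr("GATC", seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0L))
  as.integer(hits) - 1L
}

#' Build the GATC fragment map of a genome
#'
#' Tiles every chromosome into half-open fragments delimited by GATC motifs.
#' Each internal boundary sits at `motif_start + 2`, i.e. the blunt DpnI cut
#' between GA and TC, so a fully methylated genome would release exactly
#' these fragments. A chromosome with k motifs yields k + 1 fragments; with
#' no motif it is a single fragment covering the whole chromosome.
#'
#' @param genome Named character vector of uppercase chromosome sequences,
#'   or a [Biostrings::DNAStringSet].
#' @return An object of class `gatc_map`: a list with `fragments`
#'   (data.frame `chrom`, `start`, `end`; 0-based half-open, genome order),
#'   `seqlengths` (named integer) and `sites` (named list of 0-based motif
#'   start positions per chromosome).
#' @export
build_fragment_map <- function(genome) {
  genome <- as_genome(genome)
  if (length(genome) == 0L) stop_input("genome is empty")
  sites <- lapply(unname(genome), find_gatc_sites)
  names(sites) <- names(genome)
  lens <- vapply(genome, nchar, integer(1L))
  frag <- lapply(names(genome), function(chr) {
    b <- sites[[chr]] + 2L
    starts <- c(0L, b)
    ends <- c(b, lens[[chr]])
    data.frame(chrom = chr, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  frag <- do.call(rbind, frag)
  structure(list(fragments = frag, seqlengths = lens, sites = sites),
            class = "gatc_map")
}

#' @export
print.gatc_map <- function(x, ...) {
  cat(sprintf("<gatc_map> %d chromosome(s), %d fragments, %d GATC sites\n",
              length(x$seqlengths), nrow(x$fragments),
              sum(lengths(x$sites))))
  invisible(x)
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome)) {
    stop_input("genome must be a named character vector or DNAStringSet")
  }
  if (length(genome) == 0L) stop_input("genome is empty")
  nm <- names(genome)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop_input("chromosome names must be unique and nonempty")
  }
  if (any(nchar(genome) < 1L)) stop_input("chromosome sequences must be nonempty")
  check_dna(genome, "genome")
  genome
}

same_map <- function(a, b) {
  identical(a$fragments$chrom, b$fragments$chrom) &&
    identical(a$fragments$start, b$fragments$start) &&
    identical(a$fragments$end, b$fragments$end)
}

#' Read / write a genome FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] returning the plain
#' named-character genome representation used throughout the package.
#'
#' @param path File path.
#' @param genome Named character vector of chromosome sequences.
#' @return `read_genome_fasta` returns a named character vector of uppercase
#'   sequences; `write_genome_fasta` returns `path` invisibly.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; the first word is the name
  names(ss) <- sub("\\s.*$", "", names(ss))
  as_genome(toupper(stats::setNames(as.character(ss), names(ss))))
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

#' Serialize a GATC fragment map to GFF3
#'
#' Fragments are written as 9-column GFF3 records with source `gatcmap` and
#' feature type `GATC_frag`, converting the internal 0-based half-open
#' coordinates to the 1-based inclusive convention of GFF. A write/read
#' round trip reproduces the map exactly.
#'
#' @param map A `gatc_map`.
#' @param path Output (input) file path.
#' @return `write_gatc_gff` returns `path` invisibly; `read_gatc_gff`
#'   returns a `gatc_map` (without the `sites` cache of motif positions,
#'   which are recoverable from internal boundaries).
#' @export
write_gatc_gff <- function(map, path) {
  stopifnot(inherits(map, "gatc_map"))
  f <- map$fragments
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", names(map$seqlengths),
            unname(map$seqlengths)),
    sprintf("%s\tgatcmap\tGATC_frag\t%d\t%d\t.\t.\t.\tID=frag%06d",
            f$chrom, f$start + 1L, f$end, seq_len(nrow(f)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gatc_gff
#' @export
read_gatc_gff <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop_input("malformed GFF: ", conditionMessage(e))
  )
  if (length(gr) == 0L) stop_input("GFF contains no fragment records")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start)) stop_input("malformed GFF: end before start")
  # validate per-chromosome exact tiling: sorted, no gaps, no overlaps
  lens <- integer(0L)
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (d$start[1L] != 0L) stop_input("fragments on ", chr, " do not start at 0")
    if (nrow(d) > 1L && any(d$start[-1L] != d$end[-nrow(d)])) {
      stop_input("fragments on ", chr, " overlap or leave gaps")
    }
    lens[chr] <- d$end[nrow(d)]
  }
  df <- df[order(match(df$chrom, names(lens)), df$start), , drop = FALSE]
  rownames(df) <- NULL
  sites <- lapply(names(lens), function(chr) {
    ends <- df$end[df$chrom == chr]
    ib <- ends[-length(ends)]          # internal boundaries = motif_start + 2
    as.integer(ib - 2L)
  })
  names(sites) <- names(lens)
  structure(list(fragments = df, seqlengths = lens, sites = sites),
            class = "gatc_map")
}
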