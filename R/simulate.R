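#' Simulation configuration for synthetic NanoDam experiments
#'
#' Bundles every knob of the read simulator. Defaults emulate a desk-scale
#' NanoDam experiment: a single 200 kb chromosome with GATC motifs planted
#' at a mean spacing of 190 bp (the motif density of the Drosophila
#' genome), 40 bound fragments, strong methylation (0.8) of GATC sites
#' flanking bound fragments in fusion samples, a low open-chromatin
#' background rate (0.05) everywhere, 50,000 released library molecules
#' per sample, ~300 bp sonication, mild PCR duplication (mean 1.5 copies)
#' and single-end 50 nt reads carrying the DamID PCR primer.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Length of each chromosome (bp).
#' @param mean_gatc_spacing Mean start-to-start distance between planted
#'   GATC motifs (bp); spacings are geometric.
#' @param n_binding_sites Number of true binding fragments planted.
#' @param p_bound Methylation probability of a GATC bordering a bound
#'   fragment (fusion samples).
#' @param p_open Background methylation probability at open chromatin.
#' @param n_molecules Released library molecules per sample (pre-PCR).
#' @param pcr_duplicate_mean Mean copies per molecule after PCR (>= 1).
#' @param read_length Read length (nt).
#' @param sonication_mean Mean sonicated fragment size (bp); sd is 15% of
#'   the mean, truncated below at `read_length`.
#' @param include_adaptors Prefix inserts with the DamID PCR primer and pad
#'   short inserts with the index adaptor, as in real libraries.
#' @param seed Base RNG seed; sample i of an experiment uses `seed + i`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 1L,
                       chromosome_length = 200000L,
                       mean_gatc_spacing = 190,
                       n_binding_sites = 40L,
                       p_bound = 0.8,
                       p_open = 0.05,
                       n_molecules = 50000L,
                       pcr_duplicate_mean = 1.5,
                       read_length = 50L,
                       sonication_mean = 300,
                       include_adaptors = TRUE,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              mean_gatc_spacing = mean_gatc_spacing,
              n_binding_sites = as.integer(n_binding_sites),
              p_bound = p_bound, p_open = p_open,
              n_molecules = as.integer(n_molecules),
              pcr_duplicate_mean = pcr_duplicate_mean,
              read_length = as.integer(read_length),
              sonication_mean = sonication_mean,
              include_adaptors = isTRUE(include_adaptors),
              seed = as.integer(seed))
  if (!(cfg$p_open >= 0 && cfg$p_open <= 1 && cfg$p_bound >= 0 &&
        cfg$p_bound <= 1)) {
    stop_input("p_open and p_bound must lie in [0, 1]")
  }
  if (cfg$p_open > cfg$p_bound) stop_input("p_open must not exceed p_bound")
  if (cfg$read_length < 1L) stop_input("read_length must be >= 1")
  if (cfg$pcr_duplicate_mean < 1) stop_input("pcr_duplicate_mean must be >= 1")
  if (cfg$mean_gatc_spacing <= 4) stop_input("mean_gatc_spacing must exceed 4 bp")
  class(cfg) <- "sim_config"
  cfg
}

# random DNA free of GATC: mutate any accidental motif until none remain
random_gatc_free <- function(n) {
  if (n <= 0L) return("")
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  repeat {
    hit <- regexpr("GATC", s, fixed = TRUE)
    if (hit == -1L) return(s)
    substr(s, hit + 2L, hit + 2L) <- "A"  # GATC -> GAAC
  }
}

#' Simulate a toy genome with controlled GATC spacing
#'
#' Plants GATC motifs with geometric start-to-start spacing of mean
#' `mean_gatc_spacing`; the intervening sequence is generated free of
#' accidental GATC occurrences, so [find_gatc_sites()] recovers exactly the
#' planted positions. Junctions between filler and motifs cannot create new
#' motifs (no suffix of GATC is a prefix of GATC).
#'
#' @param cfg A [sim_config()].
#' @return Named character genome with an attribute `planted_sites` (list
#'   of 0-based motif positions per chromosome).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$mean_gatc_spacing
  L <- cfg$chromosome_length
  if (L < m + 8) stop_input("chromosome_length too short for one GATC motif")
  with_seed(cfg$seed, {
    chroms <- character(cfg$n_chromosomes)
    sites <- vector("list", cfg$n_chromosomes)
    for (i in seq_len(cfg$n_chromosomes)) {
      # start-to-start gaps: 4 + geometric, mean = mean_gatc_spacing
      p <- 1 / (m - 3)
      ngap <- ceiling(L / m * 1.5) + 20L
      gaps <- 4L + stats::rgeom(ngap, p)
      pos <- cumsum(gaps)
      pos <- pos[pos + 4L <= L]
      if (length(pos) == 0L) stop_input("chromosome_length too short for one GATC motif")
      pieces <- character(2L * length(pos) + 1L)
      prev <- 0L
      for (j in seq_along(pos)) {
        pieces[2L * j - 1L] <- random_gatc_free(pos[j] - prev)
        pieces[2L * j] <- "GATC"
        prev <- pos[j] + 4L
      }
      pieces[length(pieces)] <- random_gatc_free(L - prev)
      chroms[i] <- paste(pieces, collapse = "")
      sites[[i]] <- as.integer(pos)
    }
    names(chroms) <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
    names(sites) <- names(chroms)
    attr(chroms, "planted_sites") <- sites
    chroms
  })
}

#' Choose ground-truth binding fragments
#'
#' Samples `n_binding_sites` interior GATC fragments, enforcing a minimum
#' separation of two fragments between chosen sites so that planted signals
#' stay resolvable as distinct peaks.
#'
#' @param map A `gatc_map` built from the simulated genome.
#' @param cfg A [sim_config()].
#' @return Object of class `sim_truth`: data.frame `chrom`, `start`, `end`
#'   (0-based half-open) plus the fragment row indices in `map` as
#'   attribute `frag_index`.
#' @export
simulate_truth <- function(map, cfg) {
  stopifnot(inherits(map, "gatc_map"), inherits(cfg, "sim_config"))
  f <- map$fragments
  # interior fragments only: both borders are GATC motifs
  interior <- which(ave(seq_len(nrow(f)), f$chrom, FUN = function(i) {
    seq_along(i) > 1L & seq_along(i) < length(i)
  }) == 1L)
  if (length(interior) < cfg$n_binding_sites) {
    stop_input("not enough interior fragments for n_binding_sites")
  }
  with_seed(cfg$seed + 1000L, {
    chosen <- integer(0L)
    pool <- sample(interior)
    for (idx in pool) {
      if (length(chosen) == cfg$n_binding_sites) break
      if (all(abs(chosen - idx) > 2L)) chosen <- c(chosen, idx)
    }
    if (length(chosen) < cfg$n_binding_sites) {
      stop_input("could not place n_binding_sites with the required spacing")
    }
    chosen <- sort(chosen)
    truth <- f[chosen, , drop = FALSE]
    rownames(truth) <- NULL
    structure(truth, frag_index = chosen, class = c("sim_truth", "data.frame"))
  })
}

#' Simulate one NanoDam sequencing sample
#'
#' Implements the DamID methylation and fragment-release biology: per
#' genome copy, every GATC site methylates independently (probability
#' `p_bound` at sites bordering a truth fragment in `fusion` samples,
#' `p_open` everywhere else and in `damonly` samples); a library molecule
#' is released between every pair of consecutive methylated sites (DpnI
#' double-cut logic: isolated methylated sites release nothing); molecules
#' are sonicated to ~`sonication_mean` bp and sequenced from a random end
#' as a single `read_length` nt read on the corresponding strand; each
#' molecule receives a geometric PCR copy count with mean
#' `pcr_duplicate_mean` (duplicates are exact copies). Genome copies are
#' drawn until `n_molecules` released molecules accumulate.
#'
#' @param genome Named character genome (from [simulate_genome()]).
#' @param map Its `gatc_map`.
#' @param truth A `sim_truth` (ignored for the methylation probabilities of
#'   `damonly` samples, but retained for bookkeeping).
#' @param role `"fusion"` or `"damonly"`.
#' @param cfg A [sim_config()].
#' @param sample_index Integer i; the sample uses seed `cfg$seed + i`.
#' @param barcode Index barcode recorded in read identifiers.
#' @return List with `reads` (data.frame `id`, `seq`, `qual`),
#'   `site_tally` (list per chromosome: methylation events per GATC site),
#'   `n_copies` (genome copies drawn), and `molecules` (data.frame of
#'   released fragments `chrom`, `start`, `end`).
#' @export
simulate_sample <- function(genome, map, truth, role, cfg,
                            sample_index = 1L,
                            barcode = damid_index_barcodes()[[1L]]) {
  stopifnot(inherits(map, "gatc_map"), inherits(cfg, "sim_config"))
  if (!role %in% c("fusion", "damonly")) {
    stop_input("role must be 'fusion' or 'damonly'")
  }
  genome <- as_genome(genome)
  if (!is.null(truth)) {
    key <- paste(truth$chrom, truth$start, truth$end)
    mk <- paste(map$fragments$chrom, map$fragments$start, map$fragments$end)
    if (!all(key %in% mk)) stop_input("truth fragments are not in the fragment map")
  }

  with_seed(cfg$seed + as.integer(sample_index), {
    mols <- list(); tally <- list(); ncop <- 0L
    for (chr in names(genome)) {
      s <- map$sites[[chr]]
      k <- length(s)
      tally[[chr]] <- integer(k)
      if (k < 2L) next
      b <- s + 2L  # cut positions
      p <- rep(cfg$p_open, k)
      if (role == "fusion" && !is.null(truth)) {
        tb <- truth[truth$chrom == chr, , drop = FALSE]
        if (nrow(tb) > 0L) {
          border <- match(c(tb$start, tb$end), b)   # motifs flanking truth
          border <- border[!is.na(border)]
          p[border] <- cfg$p_bound
        }
      }
      expected <- max(sum(p) - 1, 0.05)
      got <- 0L; out <- list(); batch <- 0L
      while (got < cfg$n_molecules) {
        ncopies <- max(10L, ceiling((cfg$n_molecules - got) / expected * 1.2))
        ncopies <- min(ncopies, 100000L)
        meth <- stats::runif(k * ncopies) < p       # recycles p per copy
        tally[[chr]] <- tally[[chr]] +
          as.integer(rowSums(matrix(meth, nrow = k)))
        ncop <- ncop + ncopies
        idx <- which(meth)
        if (length(idx) >= 2L) {
          copy <- (idx - 1L) %/% k
          site <- (idx - 1L) %% k + 1L
          samecopy <- copy[-1L] == copy[-length(copy)]
          left <- site[-length(site)][samecopy]
          right <- site[-1L][samecopy]
          if (length(left) > 0L) {
            batch <- batch + 1L
            out[[batch]] <- data.frame(chrom = chr, start = b[left],
                                       end = b[right],
                                       stringsAsFactors = FALSE)
            got <- got + length(left)
          }
        }
        if (expected < 0.1 && cfg$p_open == 0 && cfg$p_bound == 0) break
        if (ncop > 1e7) break  # degenerate probabilities; give up gracefully
      }
      mols[[chr]] <- if (length(out)) do.call(rbind, out) else
        data.frame(chrom = character(0L), start = integer(0L),
                   end = integer(0L), stringsAsFactors = FALSE)
    }
    molecules <- do.call(rbind, mols)
    rownames(molecules) <- NULL
    if (nrow(molecules) > cfg$n_molecules) {
      molecules <- molecules[seq_len(cfg$n_molecules), , drop = FALSE]
    }
    reads <- sonicate_and_read(molecules, genome, cfg, role, sample_index,
                               barcode)
    list(reads = reads, site_tally = tally, n_copies = ncop,
         molecules = molecules)
  })
}

# sonication, end selection, PCR duplication and read sequence emission
sonicate_and_read <- function(molecules, genome, cfg, role, sample_index,
                              barcode) {
  n <- nrow(molecules)
  empty <- data.frame(id = character(0L), seq = character(0L),
                      qual = character(0L), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  fraglen <- molecules$end - molecules$start
  son <- round(stats::rnorm(n, cfg$sonication_mean, 0.15 * cfg$sonication_mean))
  piece <- pmin(fraglen, pmax(son, cfg$read_length))
  from_left <- stats::runif(n) < 0.5
  ad <- damid_adaptors()
  genome_nt <- if (cfg$include_adaptors) {
    cfg$read_length - nchar(ad$five_prime)
  } else {
    cfg$read_length
  }
  span <- pmin(piece, genome_nt)
  s0 <- ifelse(from_left, molecules$start, molecules$end - span)
  e0 <- ifelse(from_left, molecules$start + span, molecules$end)
  insert <- substring(genome[molecules$chrom], s0 + 1L, e0)
  insert[!from_left] <- revcomp(insert[!from_left])
  if (cfg$include_adaptors) {
    seqs <- substr(paste0(ad$five_prime, insert, ad$three_prime,
                          strrep("A", cfg$read_length)),
                   1L, cfg$read_length)
  } else {
    seqs <- insert
  }
  copies <- 1L + stats::rgeom(n, prob = 1 / cfg$pcr_duplicate_mean)
  rows <- rep.int(seq_len(n), copies)
  dup <- sequence(copies)
  ids <- sprintf("sim_%s_%d:m%07d:d%d:bc%s", role, sample_index, rows, dup,
                 barcode)
  data.frame(id = ids, seq = seqs[rows],
             qual = strrep("I", nchar(seqs[rows])),
             stringsAsFactors = FALSE)
}

#' Write / read ground-truth binding fragments as BED
#'
#' Standard BED6 (0-based half-open); round trips are exact.
#'
#' @param truth A `sim_truth` or data.frame with `chrom`, `start`, `end`.
#' @param path File path.
#' @return `write_truth_bed` returns `path` invisibly; `read_truth_bed` a
#'   data.frame `chrom`, `start`, `end`.
#' @export
write_truth_bed <- function(truth, path) {
  n <- nrow(truth)
  lines <- if (n == 0L) character(0L) else
    sprintf("%s\t%d\t%d\ttruth%04d\t0\t.", truth$chrom, truth$start,
            truth$end, seq_len(n))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth_bed
#' @export
read_truth_bed <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0L), start = integer(0L),
                      end = integer(0L), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop_input("malformed BED line")
  data.frame(chrom = vapply(parts, `[[`, "", 1L),
             start = as.integer(vapply(parts, `[[`, "", 2L)),
             end = as.integer(vapply(parts, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Simulate a complete NanoDam experiment to disk
#'
#' Generates a genome, its fragment map, ground truth, and FASTQ files for
#' `n_fusion` fusion and `n_damonly` Dam-only samples (sample i uses seed
#' `cfg$seed + i`), writing genome FASTA, GATC GFF, chrom.sizes TSV, truth
#' BED and one FASTQ per sample into `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param n_fusion,n_damonly Replicate counts per role.
#' @return List with `genome`, `map`, `truth`, `samples` (data.frame `id`,
#'   `role`, `path`) and the file paths written.
#' @export
simulate_experiment <- function(cfg, dir, n_fusion = 3L, n_damonly = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(cfg)
  map <- build_fragment_map(genome)
  truth <- simulate_truth(map, cfg)
  fasta <- file.path(dir, "genome.fasta")
  write_genome_fasta(genome, fasta)
  gff <- file.path(dir, "gatc_fragments.gff")
  write_gatc_gff(map, gff)
  sizes <- file.path(dir, "genome.chrom.sizes")
  write_chrom_sizes(map$seqlengths, sizes)
  truth_bed <- file.path(dir, "truth.bed")
  write_truth_bed(truth, truth_bed)

  roles <- c(rep("fusion", n_fusion), rep("damonly", n_damonly))
  ids <- c(sprintf("tfgfp_R%d", seq_len(n_fusion)),
           sprintf("dam_R%d", seq_len(n_damonly)))
  barcodes <- damid_index_barcodes()
  paths <- character(length(ids))
  for (i in seq_along(ids)) {
    sm <- simulate_sample(genome, map, truth, roles[i], cfg,
                          sample_index = i,
                          barcode = barcodes[[(i - 1L) %% length(barcodes) + 1L]])
    paths[i] <- file.path(dir, paste0(ids[i], ".fastq"))
    write_fastq(sm$reads, paths[i])
  }
  list(genome = genome, map = map, truth = truth,
       samples = data.frame(id = ids, role = roles, path = paths,
                            stringsAsFactors = FALSE),
       files = list(fasta = fasta, gff = gff, chrom_sizes = sizes,
                    truth = truth_bed))
}
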