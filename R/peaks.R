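#' Parameters of the broad peak caller
#'
#' The native Poisson local-lambda model: the background rate of a
#' fragment is the maximum read density among the fragment itself, the
#' windows of `background_windows` bp centered on it, and a genome-wide
#' floor, estimated from the control and scaled to the experimental
#' library size. Fragments significant at `q_sig` seed peaks; maximal runs
#' of fragments at `q_link` containing at least one seed become broad
#' peaks.
#'
#' @param q_sig Significant q cut-off (default 0.05).
#' @param q_link Linking q cut-off (default 0.1; must be >= `q_sig`).
#' @param background_windows Background window sizes in bp.
#' @param min_fragments Minimum significant fragments per peak.
#' @param scaling How the control background is scaled to the experiment:
#'   `"median_ratio"` (default) uses the median per-fragment
#'   experiment/control weight ratio, which calibrates the background
#'   correctly even when a sizeable share of the experimental library sits
#'   in peaks; `"library_size"` uses the total-read ratio.
#' @return List of class `peak_call_params`.
#' @export
peak_call_params <- function(q_sig = 0.05, q_link = 0.1,
                             background_windows = c(1000L, 5000L, 10000L),
                             min_fragments = 1L,
                             scaling = c("median_ratio", "library_size")) {
  if (q_link < q_sig) stop_input("q_link must be >= q_sig")
  structure(list(q_sig = q_sig, q_link = q_link,
                 background_windows = as.integer(background_windows),
                 min_fragments = as.integer(min_fragments),
                 scaling = match.arg(scaling)),
            class = "peak_call_params")
}

#' The default ladder of -log10(FDR) consensus thresholds
#'
#' 41 round-number values: 0..5 by 1, 10..100 by 10, 125, 150, 175, 200,
#' 250..500 by 50 and 600..2000 by 100.
#'
#' @return Sorted numeric vector of length 41 (first 0, last 2000).
#' @export
default_fdr_thresholds <- function() {
  c(0:5, seq(10L, 100L, by = 10L), c(125L, 150L, 175L, 200L),
    seq(250L, 500L, by = 50L), seq(600L, 2000L, by = 100L))
}

#' Consensus / reproducibility configuration
#'
#' @param thresholds Ascending -log10(FDR) thresholds (default the
#'   41-value ladder of [default_fdr_thresholds()]).
#' @param reproducible_fraction Minimum fraction of pairwise comparisons a
#'   consensus peak must appear in (default 0.5; the boundary is
#'   inclusive, so exactly half counts).
#' @param min_overlap Minimum overlap in bp counting as an occurrence.
#' @return List of class `consensus_config`.
#' @export
consensus_config <- function(thresholds = default_fdr_thresholds(),
                             reproducible_fraction = 0.5,
                             min_overlap = 1L) {
  if (length(thresholds) == 0L) stop_input("threshold list must be nonempty")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_input("thresholds must be strictly ascending")
  }
  if (reproducible_fraction <= 0 || reproducible_fraction > 1) {
    stop_input("reproducible_fraction must lie in (0, 1]")
  }
  structure(list(thresholds = thresholds,
                 reproducible_fraction = reproducible_fraction,
                 min_overlap = as.integer(min_overlap)),
            class = "consensus_config")
}

#' Per-fragment Poisson enrichment p-values
#'
#' For fragment i the local background lambda_i is the maximum, over the
#' fragment itself, each window in `params$background_windows` centered on
#' it, and the genome-wide control mean, of the control read density
#' scaled to the experimental sequencing depth (see the `scaling` argument
#' of [peak_call_params()]), times the fragment length.
#' p_i = P(X >= round(w_i)) for X ~ Poisson(lambda_i) with w_i the
#' experimental fragment weight; a fragment with zero weight has p = 1.
#'
#' @param exp_counts,ctrl_counts `fragment_counts` sharing one map, both
#'   with positive library size.
#' @param params A [peak_call_params()].
#' @return Numeric vector of p-values in (0, 1], one per fragment.
#' @export
fragment_pvalues <- function(exp_counts, ctrl_counts,
                             params = peak_call_params()) {
  stopifnot(inherits(exp_counts, "fragment_counts"),
            inherits(ctrl_counts, "fragment_counts"))
  if (!same_map(exp_counts$map, ctrl_counts$map)) {
    stop_input("experiment and control use different fragment maps")
  }
  if (exp_counts$library_size <= 0L || ctrl_counts$library_size <= 0L) {
    stop_input("library sizes must be positive")
  }
  map <- exp_counts$map
  f <- map$fragments
  scale <- background_scale(exp_counts, ctrl_counts, params$scaling)
  genome_len <- sum(map$seqlengths)
  floor_density <- sum(ctrl_counts$weights) / genome_len
  lambda <- numeric(nrow(f))
  for (chr in names(map$seqlengths)) {
    rows <- which(f$chrom == chr)
    L <- map$seqlengths[[chr]]
    flen <- f$end[rows] - f$start[rows]
    dens_bp <- rep(ctrl_counts$weights[rows] / flen, flen)
    cum <- c(0, cumsum(dens_bp))
    center <- (f$start[rows] + f$end[rows]) / 2
    dens <- ctrl_counts$weights[rows] / flen   # the fragment itself
    for (w in params$background_windows) {
      lo <- pmax(0, floor(center - w / 2))
      hi <- pmin(L, ceiling(center + w / 2))
      dens <- pmax(dens, (cum[hi + 1L] - cum[lo + 1L]) / (hi - lo))
    }
    dens <- pmax(dens, floor_density)
    lambda[rows] <- dens * scale * flen
  }
  w <- round(exp_counts$weights)
  p <- stats::ppois(w - 1, lambda, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with enforced monotonicity
#' (via [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector with values in (0, 1].
#' @return Numeric vector of q-values in (0, 1].
#' @export
bh_qvalues <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0L))
  if (anyNA(pvalues) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop_input("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# experiment/control background scale factor. The median per-fragment
# ratio is robust to the fraction of the experimental library captured in
# peaks; the library-size ratio is kept as a simple alternative.
background_scale <- function(exp_counts, ctrl_counts, scaling) {
  lib_ratio <- exp_counts$library_size / ctrl_counts$library_size
  if (identical(scaling, "library_size")) return(lib_ratio)
  ok <- ctrl_counts$weights > 0
  if (!any(ok)) return(lib_ratio)
  s <- stats::median(exp_counts$weights[ok] / ctrl_counts$weights[ok])
  if (!is.finite(s) || s <= 0) lib_ratio else s
}

new_peak_set <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(chrom = character(0L), start = integer(0L),
                     end = integer(0L), name = character(0L),
                     score = integer(0L), strand = character(0L),
                     signalValue = numeric(0L), pValue = numeric(0L),
                     qValue = numeric(0L), stringsAsFactors = FALSE)
  }
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Call broad peaks from a pairwise comparison
#'
#' Fragments with q <= `q_sig` seed peaks; maximal runs of consecutive
#' fragments with q <= `q_link` that contain at least one seed are emitted
#' as broad peaks. Peak `pValue`/`qValue` are the -log10 of the minimum
#' fragment p/q inside the run, `signalValue` is the mean log2 ratio over
#' the run, and `score` is `min(1000, round(10 * qValue))`.
#'
#' @inheritParams fragment_pvalues
#' @param pseudocount Pseudocount for the signalValue log2 ratio.
#' @param name_prefix Prefix for peak names.
#' @return A `peak_set` data.frame in broadPeak column order.
#' @export
call_broad_peaks <- function(exp_counts, ctrl_counts,
                             params = peak_call_params(),
                             pseudocount = 0.5, name_prefix = "peak") {
  p <- fragment_pvalues(exp_counts, ctrl_counts, params)
  q <- bh_qvalues(p)
  ratio <- ratio_track(exp_counts, ctrl_counts, pseudocount)$score
  f <- exp_counts$map$fragments
  out <- list()
  for (chr in unique(f$chrom)) {
    rows <- which(f$chrom == chr)
    link <- q[rows] <= params$q_link
    seed <- q[rows] <= params$q_sig
    r <- rle(link)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run <- starts[j]:ends[j]
      if (sum(seed[run]) < params$min_fragments) next
      rr <- rows[run]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = f$start[rr[1L]], end = f$end[rr[length(rr)]],
        signalValue = mean(ratio[rr]),
        pValue = -log10(min(p[rr])), qValue = -log10(min(q[rr])),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(new_peak_set())
  df <- do.call(rbind, out)
  df$name <- sprintf("%s_%d", name_prefix, seq_len(nrow(df)))
  df$score <- pmin(1000L, as.integer(round(10 * df$qValue)))
  df$strand <- "."
  new_peak_set(df[c("chrom", "start", "end", "name", "score", "strand",
                    "signalValue", "pValue", "qValue")])
}

# merge intervals overlapping by >= 1 bp; annotate merged records with the
# maxima of the constituent statistics
merge_peak_records <- function(df, name_prefix = "merge") {
  if (nrow(df) == 0L) return(new_peak_set())
  out <- list()
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    red <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(red, ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    mx <- function(v) {
      as.numeric(tapply(v[sh], factor(qh, levels = seq_along(red)), max))
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = chr, start = IRanges::start(red) - 1L, end = IRanges::end(red),
      signalValue = unname(mx(d$signalValue)),
      pValue = unname(mx(d$pValue)), qValue = unname(mx(d$qValue)),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), , drop = FALSE]
  rownames(df) <- NULL
  df$name <- sprintf("%s_%d", name_prefix, seq_len(nrow(df)))
  df$score <- pmin(1000L, as.integer(round(10 * df$qValue)))
  df$strand <- "."
  new_peak_set(df[c("chrom", "start", "end", "name", "score", "strand",
                    "signalValue", "pValue", "qValue")])
}

#' FDR-threshold consensus peak sets
#'
#' For each threshold F in `cfg$thresholds`, peaks with qValue (-log10
#' FDR) >= F are kept across all pairwise comparisons, pooled, sorted and
#' merged (>= 1 bp overlap) into one consensus set -- by default 41
#' `.mergePeak`-style outputs.
#'
#' @param peak_sets Named list of `peak_set`s, one per pairwise
#'   comparison.
#' @param cfg A [consensus_config()].
#' @return Named list (threshold as name) of merged `peak_set`s.
#' @export
threshold_consensus <- function(peak_sets, cfg = consensus_config()) {
  stopifnot(inherits(cfg, "consensus_config"))
  if (length(peak_sets) < 1L) stop_input("need at least one peak set")
  pooled <- do.call(rbind, lapply(peak_sets, as.data.frame))
  out <- lapply(cfg$thresholds, function(F) {
    kept <- pooled[pooled$qValue >= F, , drop = FALSE]
    merge_peak_records(kept)
  })
  names(out) <- as.character(cfg$thresholds)
  out
}

#' Reproducible peaks at one FDR threshold
#'
#' Consensus peaks at `at_threshold` are retained iff they overlap (by at
#' least `cfg$min_overlap` bp) a thresholded peak in at least
#' `cfg$reproducible_fraction` of the per-pair sets; the boundary is
#' inclusive, so a peak present in exactly half of the files survives the
#' default 50% rule.
#'
#' @param peak_sets Named list of per-pair `peak_set`s (>= 2).
#' @param cfg A [consensus_config()].
#' @param at_threshold The -log10(FDR) threshold to filter at.
#' @return A `peak_set` of reproducible consensus peaks.
#' @export
reproducible_peaks <- function(peak_sets, cfg = consensus_config(),
                               at_threshold = 10) {
  stopifnot(inherits(cfg, "consensus_config"))
  if (length(peak_sets) < 2L) stop_input("need at least two peak sets")
  thresholded <- lapply(peak_sets, function(ps) {
    ps[ps$qValue >= at_threshold, , drop = FALSE]
  })
  pooled <- do.call(rbind, lapply(thresholded, as.data.frame))
  candidates <- merge_peak_records(pooled, name_prefix = "repro")
  if (nrow(candidates) == 0L) return(candidates)
  support <- integer(nrow(candidates))
  for (ps in thresholded) {
    support <- support + peak_overlap_any(candidates, ps, cfg$min_overlap)
  }
  needed <- cfg$reproducible_fraction * length(peak_sets)
  candidates[support >= needed, , drop = FALSE]
}

# per-candidate indicator of >= min_overlap bp overlap with any peak in ps
peak_overlap_any <- function(candidates, ps, min_overlap = 1L) {
  hit <- logical(nrow(candidates))
  if (nrow(ps) == 0L || nrow(candidates) == 0L) return(as.integer(hit))
  for (chr in unique(candidates$chrom)) {
    ci <- which(candidates$chrom == chr)
    d <- ps[ps$chrom == chr, , drop = FALSE]
    if (nrow(d) == 0L) next
    cir <- IRanges::IRanges(candidates$start[ci] + 1L, candidates$end[ci])
    pir <- IRanges::IRanges(d$start + 1L, d$end)
    hit[ci] <- IRanges::overlapsAny(cir, pir, minoverlap = min_overlap)
  }
  as.integer(hit)
}

#' Write / read broadPeak (BED6+3) files
#'
#' Nine tab-separated columns: chrom, start, end, name, score, strand,
#' signalValue, pValue, qValue, 0-based half-open and sorted; `pValue`/
#' `qValue` are -log10-scaled and serialized at 6 significant digits.
#' Reading validates column count and sortedness.
#'
#' @param peaks A `peak_set`.
#' @param path File path.
#' @return `write_broadpeak` returns `path` invisibly; `read_broadpeak` a
#'   `peak_set`.
#' @export
write_broadpeak <- function(peaks, path) {
  df <- as.data.frame(peaks)
  lines <- if (nrow(df) == 0L) character(0L) else
    sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s",
            df$chrom, df$start, df$end, df$name, df$score, df$strand,
            sprintf("%.6g", df$signalValue),
            sprintf("%.6g", df$pValue),
            sprintf("%.6g", df$qValue))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_broadpeak
#' @export
read_broadpeak <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(new_peak_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L)) {
    stop_input(sprintf("broadPeak line %d does not have 9 columns",
                       which(lengths(parts) != 9L)[1L]))
  }
  col <- function(i) vapply(parts, `[[`, "", i)
  df <- data.frame(chrom = col(1L), start = as.integer(col(2L)),
                   end = as.integer(col(3L)), name = col(4L),
                   score = as.integer(col(5L)), strand = col(6L),
                   signalValue = as.numeric(col(7L)),
                   pValue = as.numeric(col(8L)),
                   qValue = as.numeric(col(9L)), stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop_input("broadPeak interval with end <= start")
  for (chr in unique(df$chrom)) {
    s <- df$start[df$chrom == chr]
    if (is.unsorted(s)) stop_input("broadPeak records on ", chr,
                                   " are not sorted")
  }
  new_peak_set(df)
}

#' Write intervals as BED6
#'
#' @param peaks A `peak_set` or data.frame with `chrom`, `start`, `end`
#'   (optionally `name`, `score`, `strand`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  df <- as.data.frame(peaks)
  n <- nrow(df)
  name <- if ("name" %in% names(df)) df$name else sprintf("region_%d", seq_len(n))
  score <- if ("score" %in% names(df)) df$score else rep(0L, n)
  strand <- if ("strand" %in% names(df)) df$strand else rep(".", n)
  lines <- if (n == 0L) character(0L) else
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", df$chrom, df$start, df$end, name,
            as.integer(score), strand)
  writeLines(lines, path)
  invisible(path)
}
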