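#' QC thresholds for replicate correlation
#'
#' The recommended keep/flag rules: individual libraries should correlate
#' at Pearson >= 0.9 with libraries of the same type, and pairwise-ratio
#' tracks at Pearson >= 0.8 with comparisons from the same setup. Both
#' boundaries are inclusive.
#'
#' @param within Within-type minimum Pearson correlation.
#' @param comparison Pairwise-comparison minimum Pearson correlation.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(within = 0.9, comparison = 0.8) {
  if (!(within > 0 && within <= 1 && comparison > 0 && comparison <= 1)) {
    stop_input("thresholds must lie in (0, 1]")
  }
  structure(list(within = within, comparison = comparison),
            class = "qc_thresholds")
}

#' Genome-wide Pearson correlation matrix
#'
#' Pearson correlation over all bins (or fragments) between every pair of
#' tracks. Zero-variance tracks yield NA correlations and are reported in
#' the `flagged_constant` attribute.
#'
#' @param tracks Named list of `binned_coverage` or `dam_track` objects on
#'   identical schemes, or a numeric matrix with one column per sample.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `flagged_constant` names zero-variance samples.
#' @export
correlation_matrix <- function(tracks) {
  m <- if (is.matrix(tracks)) tracks else {
    vals <- lapply(tracks, function(t) {
      if (inherits(t, "binned_coverage")) t$count
      else if (inherits(t, "dam_track")) t$score
      else as.numeric(t)
    })
    if (length(unique(lengths(vals))) != 1L) {
      stop_input("tracks have different lengths")
    }
    do.call(cbind, vals)
  }
  if (ncol(m) < 2L) stop_input("need at least two tracks")
  constant <- apply(m, 2L, stats::sd) == 0
  cm <- suppressWarnings(stats::cor(m, method = "pearson"))
  diag(cm) <- 1
  attr(cm, "flagged_constant") <- colnames(m)[constant]
  cm
}

#' Flag libraries by replicate correlation
#'
#' A sample is flagged when the median of its correlations to the other
#' members of its group falls below the applicable threshold: the
#' within-type threshold (default 0.9) for replicate groups, the
#' comparison threshold (default 0.8) for groups of pairwise-ratio
#' tracks. Groups with a single member yield the decision
#' `"insufficient_replicates"`.
#'
#' @param mat Correlation matrix from [correlation_matrix()], with row and
#'   column names.
#' @param groups Named character vector mapping each sample to its group.
#' @param kind Named character vector mapping each group to `"within"`
#'   (replicate libraries) or `"comparison"` (pairwise-ratio tracks);
#'   groups absent from `kind` default to `"within"`.
#' @param thresholds A [qc_thresholds()].
#' @return Data frame `sample`, `group`, `median_cor`, `threshold`,
#'   `decision` (`keep` / `flag` / `insufficient_replicates`).
#' @export
flag_libraries <- function(mat, groups, kind = character(0L),
                           thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  samples <- rownames(mat)
  if (is.null(samples)) stop_input("correlation matrix must have row names")
  if (!all(samples %in% names(groups))) {
    stop_input("groups must name every sample in the matrix")
  }
  res <- lapply(samples, function(s) {
    g <- groups[[s]]
    peers <- setdiff(samples[groups[samples] == g], s)
    k <- if (g %in% names(kind)) kind[[g]] else "within"
    thr <- if (identical(k, "comparison")) thresholds$comparison else
      thresholds$within
    if (length(peers) == 0L) {
      return(data.frame(sample = s, group = g, median_cor = NA_real_,
                        threshold = thr,
                        decision = "insufficient_replicates",
                        stringsAsFactors = FALSE))
    }
    med <- stats::median(mat[s, peers])
    data.frame(sample = s, group = g, median_cor = med, threshold = thr,
               decision = if (!is.na(med) && med >= thr) "keep" else "flag",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Library complexity curve (expected distinct reads)
#'
#' The c-curve analogue: at each subsampling depth n, the expected number
#' of distinct reads when drawing n of the N reads without replacement,
#' computed exactly from the hypergeometric expectation
#' `sum_u (1 - C(N - c_u, n) / C(N, n))` over duplicate classes u with
#' multiplicity c_u. Duplicate classes are defined by identical alignment
#' coordinates (or whatever keys are supplied).
#'
#' @param keys Vector of duplicate-class keys, one per read (e.g. from
#'   [alignment_keys()]).
#' @param n_points Number of evenly spaced depths up to N.
#' @return Object of class `complexity_curve`: data.frame `total_reads`,
#'   `expected_distinct`.
#' @export
complexity_curve <- function(keys, n_points = 20L) {
  N <- length(keys)
  if (N == 0L) stop_input("read multiset is empty")
  counts <- as.integer(table(keys))
  n <- unique(pmax(1L, round(seq_len(n_points) / n_points * N)))
  d <- vapply(n, function(ni) {
    sum(1 - exp(lchoose(N - counts, ni) - lchoose(N, ni)))
  }, numeric(1L))
  structure(data.frame(total_reads = n, expected_distinct = d),
            class = c("complexity_curve", "data.frame"))
}

#' Duplicate-class keys from alignments
#'
#' PCR duplicates share coordinates, so the duplicate class of a read is
#' its (chromosome, start, strand, length) tuple.
#'
#' @param alignments Data frame `chrom`, `start`, `strand`, `length`.
#' @return Character vector of keys.
#' @export
alignment_keys <- function(alignments) {
  paste(alignments$chrom, alignments$start, alignments$strand,
        alignments$length, sep = ":")
}

#' Fingerprint curve of a binned read distribution
#'
#' Bins are ranked by ascending read count; the curve gives the
#' cumulative read fraction contained in the k lowest-ranked bins against
#' the bin-rank fraction k/n. Concentrated (high signal-to-noise)
#' libraries push the elbow toward the lower right.
#'
#' @param binned A `binned_coverage` or a numeric vector of bin counts.
#' @return Object of class `fingerprint_curve`: data.frame `rank_fraction`,
#'   `read_fraction`, both nondecreasing, ending at (1, 1).
#' @export
fingerprint_curve <- function(binned) {
  counts <- if (inherits(binned, "binned_coverage")) binned$count else
    as.numeric(binned)
  if (length(counts) == 0L) stop_input("need at least one bin")
  total <- sum(counts)
  if (total <= 0) stop_input("total bin count is zero")
  s <- sort(counts)
  structure(data.frame(rank_fraction = seq_along(s) / length(s),
                       read_fraction = cumsum(s) / total),
            class = c("fingerprint_curve", "data.frame"))
}

#' Mean signal profile over peak centers
#'
#' Samples a track at `n_positions` evenly spaced offsets within
#' `[-half_width, +half_width]` around each peak center and averages
#' across peaks, the meta-profile used to verify that binding signal is
#' enriched on called peaks.
#'
#' @param track A `dam_track`.
#' @param peaks A `peak_set` or data.frame with `chrom`, `start`, `end`.
#' @param half_width Profile half-width in bp.
#' @param n_positions Number of sampled offsets (odd values include 0).
#' @return Object of class `enrichment_profile`: data.frame `offset`,
#'   `mean_signal`; attribute `n_peaks`.
#' @export
enrichment_profile <- function(track, peaks, half_width = 1000L,
                               n_positions = 50L) {
  stopifnot(inherits(track, "dam_track"))
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0L) stop_input("peak set is empty")
  offsets <- seq(-half_width, half_width, length.out = n_positions)
  iv <- track$intervals
  # per-chromosome step-function lookup of the track
  lookup <- lapply(split(seq_len(nrow(iv)), iv$chrom), function(rows) {
    list(starts = iv$start[rows], ends = iv$end[rows],
         score = track$score[rows])
  })
  centers <- floor((peaks$start + peaks$end) / 2)
  prof <- matrix(NA_real_, nrow = nrow(peaks), ncol = n_positions)
  for (i in seq_len(nrow(peaks))) {
    lk <- lookup[[peaks$chrom[i]]]
    if (is.null(lk)) next
    pos <- centers[i] + offsets
    j <- findInterval(pos, lk$starts)
    ok <- j >= 1L & pos >= 0 & pos < lk$ends[pmax(j, 1L)]
    prof[i, ok] <- lk$score[j[ok]]
  }
  structure(data.frame(offset = offsets,
                       mean_signal = colMeans(prof, na.rm = TRUE)),
            n_peaks = nrow(peaks),
            class = c("enrichment_profile", "data.frame"))
}

#' Library pooling calculator
#'
#' Applies the standard DamID sequencing pooling formulas: per-library
#' molarity `(1500 / average fragment size) * concentration(ng/uL)` (nM),
#' per-library volume `(target / molarity) * (final_volume / n)` and water
#' top-up `final_volume - sum(volumes)`; the achieved concentration is
#' the mass balance `sum(molarity_i * volume_i) / final_volume`.
#'
#' @param fragment_size Average fragment sizes in bp (one per library).
#' @param concentration DNA concentrations in ng/uL.
#' @param target_nM Target pooled concentration (nM, default 20).
#' @param final_volume Final pool volume (uL, default 50).
#' @return List with `libraries` (data.frame `fragment_size`,
#'   `concentration`, `molarity_nM`, `volume_uL`), `water_uL`,
#'   `achieved_nM`.
#' @export
pooling_plan <- function(fragment_size, concentration, target_nM = 20,
                         final_volume = 50) {
  n <- length(fragment_size)
  if (n == 0L || length(concentration) != n) {
    stop_input("fragment_size and concentration must have equal, positive length")
  }
  if (any(fragment_size <= 0) || any(concentration <= 0) ||
      target_nM <= 0 || final_volume <= 0) {
    stop_input("all pooling inputs must be positive")
  }
  molarity <- (1500 / fragment_size) * concentration
  volume <- (target_nM / molarity) * (final_volume / n)
  water <- final_volume - sum(volume)
  if (water < 0) {
    stop_input("infeasible pooling plan: required library volumes exceed ",
               "the final volume (libraries too dilute)")
  }
  achieved <- sum(molarity * volume) / final_volume
  list(libraries = data.frame(fragment_size = fragment_size,
                              concentration = concentration,
                              molarity_nM = molarity, volume_uL = volume),
       water_uL = water, achieved_nM = achieved)
}
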