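#' Scored interval tracks
#'
#' A `dam_track` is one real value per interval of a shared interval
#' scheme (usually the GATC fragment map), the in-memory form of a
#' bedgraph.
#'
#' @param intervals Data frame `chrom`, `start`, `end` (0-based half-open,
#'   sorted within chromosome).
#' @param score Numeric vector, one value per interval.
#' @param label Track label.
#' @return Object of class `dam_track`.
#' @export
dam_track <- function(intervals, score, label = "") {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end") %in% names(intervals)))
  if (length(score) != nrow(intervals)) {
    stop_input("score must have one value per interval")
  }
  structure(list(intervals = intervals[c("chrom", "start", "end")],
                 score = as.numeric(score), label = label),
            class = "dam_track")
}

#' @export
print.dam_track <- function(x, ...) {
  cat(sprintf("<dam_track> '%s': %d intervals, score range [%.3g, %.3g]\n",
              x$label, length(x$score),
              suppressWarnings(min(x$score)), suppressWarnings(max(x$score))))
  invisible(x)
}

same_intervals <- function(a, b) {
  identical(a$intervals$chrom, b$intervals$chrom) &&
    identical(as.integer(a$intervals$start), as.integer(b$intervals$start)) &&
    identical(as.integer(a$intervals$end), as.integer(b$intervals$end))
}

#' Reads-per-million scaling of fragment counts
#'
#' value_i = weight_i / library_size * 1e6.
#'
#' @param counts A `fragment_counts`.
#' @param label Track label.
#' @return A `dam_track` of RPM values on the fragment map.
#' @export
rpm_scale <- function(counts, label = "rpm") {
  stopifnot(inherits(counts, "fragment_counts"))
  if (counts$library_size <= 0L) stop_input("library size must be positive")
  dam_track(counts$map$fragments,
            counts$weights / counts$library_size * 1e6, label)
}

#' Log2 ratio binding track of a fusion sample against a Dam-only control
#'
#' The core DamID signal: value_i = log2((expRPM_i + psi) / (ctrlRPM_i +
#' psi)) with a symmetric pseudocount psi in RPM units, so swapping
#' experiment and control exactly negates the track.
#'
#' @param exp_counts,ctrl_counts `fragment_counts` sharing one map.
#' @param pseudocount psi > 0, in RPM units.
#' @param label Track label.
#' @return A `dam_track` of log2 ratios.
#' @export
ratio_track <- function(exp_counts, ctrl_counts, pseudocount = 0.5,
                        label = "ratio") {
  stopifnot(inherits(exp_counts, "fragment_counts"),
            inherits(ctrl_counts, "fragment_counts"))
  if (!same_map(exp_counts$map, ctrl_counts$map)) {
    stop_input("experiment and control use different fragment maps")
  }
  if (pseudocount <= 0) stop_input("pseudocount must be positive")
  e <- rpm_scale(exp_counts)$score
  c0 <- rpm_scale(ctrl_counts)$score
  dam_track(exp_counts$map$fragments,
            log2((e + pseudocount) / (c0 + pseudocount)), label)
}

#' Quantile-normalize a set of tracks
#'
#' Forces all tracks to share the same value distribution: rank r in every
#' output track carries the mean of the r-th order statistics across the
#' input tracks; ties within a track receive the mean of the reference
#' values for their tied ranks.
#'
#' @param tracks List of `dam_track`s on identical intervals.
#' @return List of normalized `dam_track`s, same order and labels.
#' @export
quantile_normalize <- function(tracks) {
  if (length(tracks) < 1L) stop_input("need at least one track")
  stopifnot(all(vapply(tracks, inherits, logical(1L), "dam_track")))
  if (!all(vapply(tracks[-1L], same_intervals, logical(1L), b = tracks[[1L]]))) {
    stop_input("tracks are on different interval sets")
  }
  if (length(tracks) == 1L) return(tracks)
  m <- vapply(tracks, `[[`, numeric(length(tracks[[1L]]$score)), "score")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  lapply(seq_along(tracks), function(i) {
    dam_track(tracks[[i]]$intervals, qn[, i], tracks[[i]]$label)
  })
}

#' Average tracks element-wise
#'
#' @param tracks Nonempty list of `dam_track`s on identical intervals.
#' @param label Label for the averaged track.
#' @return A `dam_track` with value_i = mean over tracks.
#' @export
average_tracks <- function(tracks, label = "mean") {
  if (length(tracks) < 1L) stop_input("need at least one track")
  stopifnot(all(vapply(tracks, inherits, logical(1L), "dam_track")))
  if (!all(vapply(tracks[-1L], same_intervals, logical(1L), b = tracks[[1L]]))) {
    stop_input("tracks are on different interval sets")
  }
  m <- vapply(tracks, `[[`, numeric(length(tracks[[1L]]$score)), "score")
  dam_track(tracks[[1L]]$intervals, rowMeans(as.matrix(m)), label)
}

#' CATaDa-style Dam-only accessibility track
#'
#' The unnormalized (not control-compared) RPM signal of a Dam-only
#' sample, reading stochastic open-chromatin methylation as a chromatin
#' accessibility profile.
#'
#' @param ctrl_counts `fragment_counts` of a Dam-only sample.
#' @param label Track label.
#' @return A `dam_track` (identical to [rpm_scale()] output).
#' @export
damonly_track <- function(ctrl_counts, label = "damonly") {
  rpm_scale(ctrl_counts, label = label)
}

#' Write / read a 4-column bedgraph
#'
#' Intervals are written 0-based half-open, grouped by chromosome and
#' sorted by start, with values at 6 significant digits. Reading validates
#' sortedness and non-overlap within chromosomes and errors otherwise.
#'
#' @param track A `dam_track`.
#' @param path File path.
#' @return `write_bedgraph` returns `path` invisibly; `read_bedgraph` a
#'   `dam_track`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "dam_track"))
  iv <- track$intervals
  o <- order(match(iv$chrom, unique(iv$chrom)), iv$start)
  writeLines(sprintf("%s\t%d\t%d\t%s", iv$chrom[o], iv$start[o], iv$end[o],
                     sprintf("%.6g", track$score[o])),
             path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(dam_track(data.frame(chrom = character(0L), start = integer(0L),
                                end = integer(0L)), numeric(0L),
                     basename(path)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop_input(sprintf("bedgraph line %d does not have 4 columns",
                       which(lengths(parts) != 4L)[1L]))
  }
  df <- data.frame(chrom = vapply(parts, `[[`, "", 1L),
                   start = as.integer(vapply(parts, `[[`, "", 2L)),
                   end = as.integer(vapply(parts, `[[`, "", 3L)),
                   stringsAsFactors = FALSE)
  score <- as.numeric(vapply(parts, `[[`, "", 4L))
  if (any(is.na(df$start)) || any(is.na(df$end)) || any(is.na(score))) {
    stop_input("bedgraph contains non-numeric coordinates or values")
  }
  if (any(df$end <= df$start)) stop_input("bedgraph interval with end <= start")
  for (chr in unique(df$chrom)) {
    sel <- df$chrom == chr
    s <- df$start[sel]; e <- df$end[sel]
    if (is.unsorted(s, strictly = TRUE)) {
      stop_input("bedgraph intervals on ", chr, " are not sorted")
    }
    if (length(s) > 1L && any(s[-1L] < e[-length(e)])) {
      stop_input("bedgraph intervals on ", chr, " overlap")
    }
  }
  dam_track(df, score, basename(path))
}
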