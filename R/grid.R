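#' Build the all-pairwise comparison grid
#'
#' Every experimental (Dam-fusion) sample is compared against every
#' control (Dam-only) sample; pairs are named `"<exp>_vs_<ctrl>"` and
#' ordered experiment-major. With `exclude_self = TRUE` pairs whose two
#' IDs are identical are dropped, which supports the negative-control
#' design where Dam-only samples are compared against each other.
#'
#' @param exp_ids,ctrl_ids Nonempty character vectors of unique sample
#'   IDs.
#' @param exclude_self Drop same-ID pairs.
#' @return Object of class `comparison_grid` with elements `exp_ids`,
#'   `ctrl_ids`, `pairs` (data.frame `exp`, `ctrl`, `name`) and
#'   `exclude_self`.
#' @export
build_grid <- function(exp_ids, ctrl_ids, exclude_self = FALSE) {
  for (ids in list(exp_ids, ctrl_ids)) {
    if (length(ids) == 0L || any(!nzchar(ids))) {
      stop_input("sample ID lists must be nonempty")
    }
    if (anyDuplicated(ids)) stop_input("duplicate sample IDs: ",
                                       paste(ids[duplicated(ids)], collapse = ", "))
  }
  pairs <- expand.grid(ctrl = ctrl_ids, exp = exp_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[c("exp", "ctrl")]
  pairs <- pairs[order(match(pairs$exp, exp_ids), match(pairs$ctrl, ctrl_ids)), ]
  if (isTRUE(exclude_self)) pairs <- pairs[pairs$exp != pairs$ctrl, ]
  pairs$name <- paste0(pairs$exp, "_vs_", pairs$ctrl)
  rownames(pairs) <- NULL
  structure(list(exp_ids = exp_ids, ctrl_ids = ctrl_ids, pairs = pairs,
                 exclude_self = isTRUE(exclude_self)),
            class = "comparison_grid")
}

#' @export
print.comparison_grid <- function(x, ...) {
  cat(sprintf("<comparison_grid> %d experiment(s) x %d control(s): %d pairs\n",
              length(x$exp_ids), length(x$ctrl_ids), nrow(x$pairs)))
  invisible(x)
}

#' Execute a comparison grid
#'
#' For every pair, writes a `"<exp>_vs_<ctrl>"` directory under
#' `output_root` containing the log2 ratio bedgraph and the broadPeak
#' calls of that comparison, plus a `run_grid.log` recording all
#' parameters and inputs. Availability of every sample's counts is checked
#' before any output is written, so a missing ID aborts cleanly. Re-runs
#' with identical inputs overwrite deterministically (the log carries no
#' timestamps).
#'
#' @param grid A [build_grid()] result.
#' @param counts_by_id Named list of `fragment_counts`, one per sample ID.
#' @param output_root Output directory (created if needed).
#' @param pseudocount Pseudocount for ratio tracks.
#' @param peak_params A [peak_call_params()].
#' @param seed Seed recorded in the log (the stage itself is
#'   deterministic).
#' @param extension Extension recorded in the log.
#' @return Invisibly, a named list per pair with elements `dir`, `ratio`
#'   (`dam_track`) and `peaks` (`peak_set`).
#' @export
run_grid <- function(grid, counts_by_id, output_root, pseudocount = 0.5,
                     peak_params = peak_call_params(), seed = NULL,
                     extension = 300L) {
  stopifnot(inherits(grid, "comparison_grid"))
  needed <- unique(c(grid$pairs$exp, grid$pairs$ctrl))
  missing <- setdiff(needed, names(counts_by_id))
  if (length(missing) > 0L) {
    stop_input("missing counts for sample ID(s): ",
               paste(missing, collapse = ", "))
  }
  dir.create(output_root, recursive = TRUE, showWarnings = FALSE)
  results <- vector("list", nrow(grid$pairs))
  names(results) <- grid$pairs$name
  for (i in seq_len(nrow(grid$pairs))) {
    pr <- grid$pairs[i, ]
    pdir <- file.path(output_root, pr$name)
    dir.create(pdir, showWarnings = FALSE)
    ratio <- ratio_track(counts_by_id[[pr$exp]], counts_by_id[[pr$ctrl]],
                         pseudocount, label = pr$name)
    write_bedgraph(ratio, file.path(pdir, paste0(pr$name, ".ratio.bedgraph")))
    peaks <- call_broad_peaks(counts_by_id[[pr$exp]],
                              counts_by_id[[pr$ctrl]], peak_params,
                              pseudocount, name_prefix = pr$name)
    write_broadpeak(peaks, file.path(pdir, paste0(pr$name, ".broadPeak")))
    results[[i]] <- list(dir = pdir, ratio = ratio, peaks = peaks)
  }
  log <- c(
    sprintf("nanodamr run_grid %s", as.character(utils::packageVersion("nanodamr"))),
    sprintf("pairs: %d", nrow(grid$pairs)),
    sprintf("experiments: %s", paste(grid$exp_ids, collapse = ",")),
    sprintf("controls: %s", paste(grid$ctrl_ids, collapse = ",")),
    sprintf("exclude_self: %s", grid$exclude_self),
    sprintf("pseudocount: %g", pseudocount),
    sprintf("extension: %d", extension),
    sprintf("q_sig: %g  q_link: %g  windows: %s", peak_params$q_sig,
            peak_params$q_link,
            paste(peak_params$background_windows, collapse = ",")),
    sprintf("seed: %s", if (is.null(seed)) "none" else as.character(seed))
  )
  writeLines(log, file.path(output_root, "run_grid.log"))
  invisible(results)
}
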