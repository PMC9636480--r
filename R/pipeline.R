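#' Pipeline configuration
#'
#' Collects every input and stage parameter of the end-to-end workflow in
#' one validated object: trimming bounds, the 300 bp fragment-count
#' extension, the 500 bp / 150 bp correlation binning, the ratio
#' pseudocount, peak calling, consensus thresholds and QC rules.
#'
#' @param genome_fasta Genome FASTA path.
#' @param samples Data frame with columns `id`, `role` (`fusion` /
#'   `damonly`), `path` and optionally `format` (`fastq`, default, or
#'   `sam`).
#' @param output_dir Output root directory.
#' @param prefix Output prefix for the `*_tracks` / `*_peaks` folders.
#' @param min_len,max_len Read length filter bounds.
#' @param extension Read extension for fragment counting (bp).
#' @param bin_size,bin_extension Binning for the correlation/fingerprint
#'   QC.
#' @param pseudocount Ratio-track pseudocount (RPM).
#' @param peak_params A [peak_call_params()].
#' @param consensus A [consensus_config()].
#' @param repro_threshold -log10(FDR) threshold of the reproducible set
#'   highlighted by the pipeline.
#' @param qc A [qc_thresholds()].
#' @param trim Logical: run adaptor trimming.
#' @param seed RNG seed recorded and used for any stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fasta, samples, output_dir,
                            prefix = "nanodam",
                            min_len = 30L, max_len = 50L,
                            extension = 300L, bin_size = 500L,
                            bin_extension = 150L, pseudocount = 0.5,
                            peak_params = peak_call_params(),
                            consensus = consensus_config(),
                            repro_threshold = 10,
                            qc = qc_thresholds(), trim = TRUE, seed = 1L) {
  stopifnot(is.data.frame(samples),
            all(c("id", "role", "path") %in% names(samples)))
  if (!"format" %in% names(samples)) samples$format <- "fastq"
  if (anyDuplicated(samples$id)) stop_input("duplicate sample IDs")
  if (!all(samples$role %in% c("fusion", "damonly"))) {
    stop_input("sample roles must be 'fusion' or 'damonly'")
  }
  if (!all(samples$format %in% c("fastq", "sam"))) {
    stop_input("sample formats must be 'fastq' or 'sam'")
  }
  cfg <- list(genome_fasta = genome_fasta, samples = samples,
              output_dir = output_dir, prefix = prefix,
              min_len = as.integer(min_len), max_len = as.integer(max_len),
              extension = as.integer(extension),
              bin_size = as.integer(bin_size),
              bin_extension = as.integer(bin_extension),
              pseudocount = pseudocount, peak_params = peak_params,
              consensus = consensus, repro_threshold = repro_threshold,
              qc = qc, trim = isTRUE(trim), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full NanoDam analysis pipeline
#'
#' Executes trim -> align/ingest -> count -> pairwise ratio grid ->
#' quantile normalization -> averaging -> broad peaks -> FDR consensus ->
#' reproducible peaks -> QC, writing the damMer-style output layout under
#' `output_dir`: one `"<exp>_vs_<ctrl>"` folder per pairwise comparison,
#' `<prefix>_tracks` (individual, quantile-normalized and averaged ratio
#' bedgraphs), `<prefix>_DamOnly_tracks` (CATaDa-style accessibility
#' tracks), `<prefix>_peaks` (per-pair broadPeak, one `.mergePeak` per
#' consensus threshold and one `.reproPeak` per threshold) and
#' `<prefix>_DamOnly_peaks` (the Dam-only negative-control grid). All
#' input paths are checked before any output is written; re-running an
#' identical configuration reproduces every file byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the genome `map`, per-sample `counts`
#'   and alignment `stats`, the `grid` results, normalized and averaged
#'   `tracks`, `peaks` (per pair), `consensus`, `repro`, `damonly`
#'   results and the `qc` tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- c(config$genome_fasta, config$samples$path)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop_input("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  genome <- read_genome_fasta(config$genome_fasta)
  map <- build_fragment_map(genome)

  # per-sample: read prep, alignment, counting
  counts <- list(); aln_by_id <- list(); stats <- list()
  trim_tsv <- list()
  for (i in seq_len(nrow(config$samples))) {
    s <- config$samples[i, ]
    if (s$format == "sam") {
      aln <- read_sam(s$path)
      st <- c(aligned = nrow(aln), unaligned = NA_integer_,
              multimapped = NA_integer_, kept = NA_integer_,
              too_short = NA_integer_, too_long = NA_integer_)
    } else {
      reads <- read_fastq(s$path)
      n_raw <- nrow(reads)
      if (config$trim) reads <- trim_reads(reads)
      lf <- length_filter(reads, config$min_len, config$max_len)
      al <- align_exact(lf$reads, genome)
      aln <- al$alignments
      st <- c(al$stats, lf$counts, n_raw = n_raw)
    }
    aln_by_id[[s$id]] <- aln
    counts[[s$id]] <- count_fragments(aln, map, config$extension)
    stats[[s$id]] <- st
    trim_tsv[[s$id]] <- data.frame(sample = s$id, t(st))
  }

  fusion_ids <- config$samples$id[config$samples$role == "fusion"]
  damonly_ids <- config$samples$id[config$samples$role == "damonly"]
  if (length(fusion_ids) == 0L || length(damonly_ids) == 0L) {
    stop_input("need at least one fusion and one damonly sample")
  }

  # pairwise fusion-vs-control grid with ratio tracks and broad peaks
  grid <- build_grid(fusion_ids, damonly_ids)
  grid_res <- run_grid(grid, counts, config$output_dir,
                       config$pseudocount, config$peak_params,
                       seed = config$seed, extension = config$extension)
  ratio_tracks <- lapply(grid_res, `[[`, "ratio")
  pair_peaks <- lapply(grid_res, `[[`, "peaks")

  # *_tracks: individual, quantile-normalized and averaged ratio tracks
  tracks_dir <- file.path(config$output_dir,
                          paste0(config$prefix, "_tracks"))
  dir.create(tracks_dir, showWarnings = FALSE)
  qn <- quantile_normalize(ratio_tracks)
  names(qn) <- names(ratio_tracks)
  avg <- average_tracks(qn, label = paste0(config$prefix, "_mean"))
  for (nm in names(ratio_tracks)) {
    write_bedgraph(ratio_tracks[[nm]],
                   file.path(tracks_dir, paste0(nm, ".ratio.bedgraph")))
    write_bedgraph(qn[[nm]],
                   file.path(tracks_dir, paste0(nm, ".quantnorm.bedgraph")))
  }
  write_bedgraph(avg, file.path(tracks_dir,
                                paste0(config$prefix, ".mean.bedgraph")))

  # *_DamOnly_tracks: accessibility tracks, normalized to each other
  dam_dir <- file.path(config$output_dir,
                       paste0(config$prefix, "_DamOnly_tracks"))
  dir.create(dam_dir, showWarnings = FALSE)
  dam_tracks <- lapply(damonly_ids, function(id) {
    damonly_track(counts[[id]], label = id)
  })
  names(dam_tracks) <- damonly_ids
  dam_qn <- quantile_normalize(dam_tracks)
  names(dam_qn) <- damonly_ids
  dam_avg <- average_tracks(dam_qn, label = "DamOnly_mean")
  for (id in damonly_ids) {
    write_bedgraph(dam_tracks[[id]],
                   file.path(dam_dir, paste0(id, ".rpm.bedgraph")))
    write_bedgraph(dam_qn[[id]],
                   file.path(dam_dir, paste0(id, ".quantnorm.bedgraph")))
  }
  write_bedgraph(dam_avg, file.path(dam_dir, "DamOnly.mean.bedgraph"))

  # *_peaks: per-pair broadPeak + consensus + reproducible sets
  peaks_dir <- file.path(config$output_dir, paste0(config$prefix, "_peaks"))
  dir.create(peaks_dir, showWarnings = FALSE)
  for (nm in names(pair_peaks)) {
    write_broadpeak(pair_peaks[[nm]],
                    file.path(peaks_dir, paste0(nm, ".broadPeak")))
  }
  consensus <- threshold_consensus(pair_peaks, config$consensus)
  for (thr in names(consensus)) {
    write_broadpeak(consensus[[thr]],
                    file.path(peaks_dir,
                              sprintf("%s_FDR%s.mergePeak", config$prefix, thr)))
  }
  repro <- list()
  if (length(pair_peaks) >= 2L) {
    for (thr in config$consensus$thresholds) {
      rp <- reproducible_peaks(pair_peaks, config$consensus, thr)
      repro[[as.character(thr)]] <- rp
      write_broadpeak(rp, file.path(peaks_dir,
                                    sprintf("%s_FDR%s.reproPeak",
                                            config$prefix, thr)))
    }
  }

  # *_DamOnly_peaks: negative-control grid (Dam-only vs Dam-only)
  dam_peaks <- list(); dam_consensus <- list()
  if (length(damonly_ids) >= 2L) {
    dam_grid <- build_grid(damonly_ids, damonly_ids, exclude_self = TRUE)
    dampk_dir <- file.path(config$output_dir,
                           paste0(config$prefix, "_DamOnly_peaks"))
    dir.create(dampk_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(dam_grid$pairs))) {
      pr <- dam_grid$pairs[i, ]
      pk <- call_broad_peaks(counts[[pr$exp]], counts[[pr$ctrl]],
                             config$peak_params, config$pseudocount,
                             name_prefix = pr$name)
      dam_peaks[[pr$name]] <- pk
      write_broadpeak(pk, file.path(dampk_dir, paste0(pr$name, ".broadPeak")))
    }
    dam_consensus <- threshold_consensus(dam_peaks, config$consensus)
  }

  # QC: correlation, complexity, fingerprint, enrichment
  binned <- lapply(aln_by_id, bin_coverage, chrom_sizes = map$seqlengths,
                   bin_size = config$bin_size,
                   extension = config$bin_extension)
  qc_dir <- file.path(config$output_dir, paste0(config$prefix, "_qc"))
  dir.create(qc_dir, showWarnings = FALSE)
  cor_raw <- correlation_matrix(binned)
  utils::write.table(round(cor_raw, 6), file.path(qc_dir, "correlation_raw.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  groups <- stats::setNames(config$samples$role, config$samples$id)
  flags <- flag_libraries(cor_raw, groups, thresholds = config$qc)
  utils::write.table(flags, file.path(qc_dir, "library_flags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  complexity <- lapply(aln_by_id, function(a) {
    complexity_curve(alignment_keys(a))
  })
  fingerprints <- lapply(binned, fingerprint_curve)
  for (id in names(complexity)) {
    utils::write.table(complexity[[id]],
                       file.path(qc_dir, sprintf("%s.complexity.tsv", id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fingerprints[[id]],
                       file.path(qc_dir, sprintf("%s.fingerprint.tsv", id)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  repro_at <- repro[[as.character(config$repro_threshold)]]
  enrich <- NULL
  if (!is.null(repro_at) && nrow(repro_at) > 0L) {
    enrich <- enrichment_profile(avg, repro_at)
    utils::write.table(enrich, file.path(qc_dir, "enrichment_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(do.call(rbind, trim_tsv),
                     file.path(qc_dir, "readprep_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  write_run_log(config, map, stats)

  invisible(list(map = map, counts = counts, alignments = aln_by_id,
                 stats = stats, grid = grid, grid_results = grid_res,
                 ratio_tracks = ratio_tracks, qn_tracks = qn,
                 mean_track = avg, damonly_tracks = dam_tracks,
                 damonly_mean = dam_avg, peaks = pair_peaks,
                 consensus = consensus, repro = repro,
                 damonly_peaks = dam_peaks,
                 damonly_consensus = dam_consensus,
                 qc = list(correlation = cor_raw, flags = flags,
                           complexity = complexity,
                           fingerprints = fingerprints,
                           enrichment = enrich, binned = binned)))
}

# deterministic run log: versions, parameters, input checksums (no clock)
write_run_log <- function(config, map, stats) {
  sums <- tools::md5sum(c(config$genome_fasta, config$samples$path))
  lines <- c(
    sprintf("nanodamr %s", as.character(utils::packageVersion("nanodamr"))),
    sprintf("seed: %d", config$seed),
    sprintf("prefix: %s", config$prefix),
    sprintf("trim: %s  min_len: %d  max_len: %d", config$trim,
            config$min_len, config$max_len),
    sprintf("extension: %d  bin_size: %d  bin_extension: %d",
            config$extension, config$bin_size, config$bin_extension),
    sprintf("pseudocount: %g", config$pseudocount),
    sprintf("q_sig: %g  q_link: %g  windows: %s", config$peak_params$q_sig,
            config$peak_params$q_link,
            paste(config$peak_params$background_windows, collapse = ",")),
    sprintf("consensus thresholds: %s",
            paste(config$consensus$thresholds, collapse = ",")),
    sprintf("reproducible_fraction: %g  repro_threshold: %g",
            config$consensus$reproducible_fraction, config$repro_threshold),
    sprintf("genome: %d chromosome(s), %d fragments",
            length(map$seqlengths), nrow(map$fragments)),
    sprintf("input %s md5 %s", names(sums), unname(sums)),
    vapply(names(stats), function(id) {
      s <- stats[[id]]
      sprintf("sample %s: %s", id,
              paste(sprintf("%s=%s", names(s), s), collapse = " "))
    }, character(1L))
  )
  writeLines(lines, file.path(config$output_dir, "run_pipeline.log"))
}
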