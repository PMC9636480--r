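# shared fixtures, built in code at test time

# the length-20 toy chromosome with motifs at 4 and 12:
# fragments [0,6), [6,14), [14,20)
toy_genome <- function() {
  c(chr_toy = "AAAAGATCTTTTGATCAAAA")
}

toy_map <- function() build_fragment_map(toy_genome())

# a small random genome with a handful of motifs, deterministic
random_toy_genome <- function(seed, length = 2000L, spacing = 150) {
  cfg <- sim_config(chromosome_length = as.integer(length),
                    mean_gatc_spacing = spacing, n_binding_sites = 1L,
                    seed = seed)
  simulate_genome(cfg)
}

# peak_set constructor for hand-built fixtures
make_peaks <- function(chrom, start, end, qValue,
                       signalValue = 1, pValue = qValue + 1) {
  n <- length(start)
  df <- data.frame(chrom = rep_len(chrom, n), start = start, end = end,
                   name = sprintf("p%d", seq_len(n)),
                   score = pmin(1000L, as.integer(round(10 * qValue))),
                   strand = rep(".", n),
                   signalValue = rep_len(signalValue, n),
                   pValue = rep_len(pValue, n), qValue = qValue,
                   stringsAsFactors = FALSE)
  class(df) <- c("peak_set", "data.frame")
  df
}

# fragment_counts with prescribed weights on a map
make_counts <- function(map, weights, library_size = sum(weights)) {
  structure(list(map = map, weights = as.numeric(weights),
                 library_size = library_size),
            class = "fragment_counts")
}

# memoized full-scale simulated experiment + pipeline run (study conditions:
# 200 kb, mean GATC spacing 190 bp, 40 binding fragments, pBound 0.8,
# pOpen 0.05, 3 fusion + 3 Dam-only samples, 50,000 molecules, seed 1)
.fixture_cache <- new.env(parent = emptyenv())

default_simulation <- function() {
  if (!is.null(.fixture_cache$default)) return(.fixture_cache$default)
  dir <- file.path(tempdir(), "nanodamr-default-sim")
  cfg <- sim_config(seed = 1L)
  ex <- simulate_experiment(cfg, dir, n_fusion = 3L, n_damonly = 3L)
  pc <- pipeline_config(ex$files$fasta, ex$samples,
                        file.path(dir, "out"), seed = 1L)
  res <- run_pipeline(pc)
  .fixture_cache$default <- list(cfg = cfg, experiment = ex, config = pc,
                                 result = res)
  .fixture_cache$default
}
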