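# a 600 bp genome with a few motifs, plus helper reads cut from it
aln_fixture <- function(seed = 21L) {
  g <- random_toy_genome(seed, length = 600L, spacing = 80)
  list(genome = g, map = build_fragment_map(g), seq = g[[1L]])
}

test_that("align_exact recovers unique placements on both strands", {
  fx <- aln_fixture()
  fwd <- substr(fx$seq, 101L, 150L)
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  reads <- data.frame(id = c("f", "r", "n"),
                      seq = c(fwd, rev, strrep("N", 50L)),
                      qual = strrep("I", 50L), stringsAsFactors = FALSE)
  al <- align_exact(reads, fx$genome)
  expect_identical(al$stats, c(aligned = 2L, unaligned = 1L, multimapped = 0L))
  expect_identical(al$alignments$start, c(100L, 100L))
  expect_identical(al$alignments$strand, c("+", "-"))
  expect_identical(al$alignments$length, c(50L, 50L))
})

test_that("align_exact counts multimapping reads without emitting them", {
  g <- c(chrA = paste0(strrep("A", 30L), "CCGTTAGCATTG", strrep("T", 30L),
                       "CCGTTAGCATTG", strrep("G", 30L)))
  reads <- data.frame(id = "m", seq = "CCGTTAGCATTG", qual = strrep("I", 12L),
                      stringsAsFactors = FALSE)
  al <- align_exact(reads, g)
  expect_identical(unname(al$stats["multimapped"]), 1L)
  expect_identical(nrow(al$alignments), 0L)
})

test_that("align_exact recovers simulator source coordinates exactly", {
  cfg <- sim_config(chromosome_length = 20000L, n_binding_sites = 4L,
                    n_molecules = 300L, seed = 22L,
                    include_adaptors = FALSE, pcr_duplicate_mean = 1)
  g <- simulate_genome(cfg)
  map <- build_fragment_map(g)
  sm <- simulate_sample(g, map, simulate_truth(map, cfg), "fusion", cfg)
  al <- align_exact(sm$reads, g)
  # every aligned read lies inside its source molecule
  expect_gt(nrow(al$alignments), 0.9 * nrow(sm$reads))
  mol <- sm$molecules
  ok <- vapply(seq_len(nrow(al$alignments)), function(i) {
    a <- al$alignments[i, ]
    any(mol$start <= a$start & mol$end >= a$start + a$length)
  }, logical(1L))
  expect_true(all(ok))
})

test_that("read_sam parses the mandatory-column subset", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 101, 42, "50M", "*", 0, 0, strrep("A", 50L),
          strrep("I", 50L), sep = "\t"),
    paste("r2", 16, "chr1", 201, 42, "40M", "*", 0, 0, strrep("C", 40L),
          strrep("I", 40L), sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0, strrep("G", 50L),
          strrep("I", 50L), sep = "\t")
  ), path)
  aln <- read_sam(path)
  expect_identical(nrow(aln), 2L)                 # FLAG 4 skipped
  expect_identical(aln$start, c(100L, 200L))      # POS converted to 0-based
  expect_identical(aln$strand, c("+", "-"))       # 0x10 semantics
  expect_identical(aln$length, c(50L, 40L))

  writeLines(c("@HD\tVN:1.6", "r1\t0\tchr1\t10"), path)
  expect_error(read_sam(path), "line 2")
})

test_that("SAM ingestion and the toy aligner give identical fragment counts", {
  fx <- aln_fixture(23L)
  starts <- c(50L, 120L, 300L)
  reads <- data.frame(
    id = sprintf("r%d", seq_along(starts)),
    seq = substring(fx$seq, starts + 1L, starts + 40L),
    qual = strrep("I", 40L), stringsAsFactors = FALSE)
  al <- align_exact(reads, fx$genome)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    sprintf("@SQ\tSN:%s\tLN:%d", names(fx$genome), nchar(fx$seq)),
    sprintf("%s\t%d\t%s\t%d\t42\t40M\t*\t0\t0\t%s\t%s",
            reads$id, ifelse(al$alignments$strand == "+", 0L, 16L),
            al$alignments$chrom, al$alignments$start + 1L, reads$seq,
            reads$qual)
  ), sam)
  fc1 <- count_fragments(al$alignments, fx$map)
  fc2 <- count_fragments(read_sam(sam), fx$map)
  expect_equal(fc1$weights, fc2$weights)
  expect_identical(fc1$library_size, fc2$library_size)
})

test_that("count_fragments distributes extended-read weight by overlap", {
  m <- toy_map()   # fragments [0,6), [6,14), [14,20) on a 20 bp chromosome
  aln <- data.frame(chrom = "chr_toy", start = 0L, strand = "+",
                    length = 10L, stringsAsFactors = FALSE)
  fc <- count_fragments(aln, m, extension = 300L)
  expect_equal(fc$weights, c(6, 8, 6) / 20)       # clipped to [0,20)

  inside <- data.frame(chrom = "chr_toy", start = 7L, strand = "+",
                       length = 3L, stringsAsFactors = FALSE)
  fc2 <- count_fragments(inside, m, extension = 3L)
  expect_equal(fc2$weights, c(0, 1, 0))           # fully inside one fragment

  two <- count_fragments(rbind(aln, aln), m)
  expect_equal(two$weights, 2 * fc$weights)       # linearity
  expect_equal(sum(two$weights), 2)

  bad <- data.frame(chrom = "chrX", start = 0L, strand = "+", length = 5L)
  expect_error(count_fragments(bad, m), "chrX")
})

test_that("total fragment weight equals the aligned read count", {
  fx <- aln_fixture(24L)
  set.seed(42L)
  n <- 200L
  starts <- sample(0:550, n, replace = TRUE)
  aln <- data.frame(chrom = names(fx$genome), start = starts,
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    length = 40L, stringsAsFactors = FALSE)
  fc <- count_fragments(aln, fx$map, extension = 150L)
  expect_equal(sum(fc$weights), n, tolerance = 1e-6)
  expect_identical(fc$library_size, n)
})

test_that("bin_coverage counts extended-read presence per bin", {
  sizes <- c(chr1 = 1500L)
  one <- data.frame(chrom = "chr1", start = 100L, strand = "+",
                    length = 50L, stringsAsFactors = FALSE)
  bc <- bin_coverage(one, sizes)                  # extended to [100, 250)
  expect_identical(bc$count, c(1L, 0L, 0L))
  expect_identical(bc$bins$end, c(500L, 1000L, 1500L))

  spanning <- data.frame(chrom = "chr1", start = 450L, strand = "+",
                         length = 50L, stringsAsFactors = FALSE)
  bc2 <- bin_coverage(spanning, sizes)            # [450, 600) crosses a bin
  expect_identical(bc2$count, c(1L, 1L, 0L))

  none <- bin_coverage(one[0L, ], sizes)
  expect_true(all(none$count == 0L))
  expect_error(bin_coverage(one, sizes, bin_size = 0L), "bin_size")
})

test_that("chrom.sizes TSV round trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  sizes <- c(chr1 = 1000L, chr2 = 500L)
  write_chrom_sizes(sizes, path)
  expect_identical(read_chrom_sizes(path), sizes)
})
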