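# independent naive BH reference: q_(i) = min_{k >= i} p_(k) * n / k
naive_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# a larger uniform fixture map for calling tests
uniform_fixture <- function(seed = 31L, length = 20000L) {
  g <- random_toy_genome(seed, length = length, spacing = 150)
  build_fragment_map(g)
}

test_that("bh_qvalues matches a naive O(n^2)-style reference", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_qvalues(0.2), 0.2)
  expect_equal(bh_qvalues(rep(1, 5L)), rep(1, 5L))
  set.seed(101L)
  for (i in 1:50) {
    p <- stats::runif(sample(1:100, 1L))
    expect_equal(bh_qvalues(p), naive_bh(p))
  }
  expect_error(bh_qvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("fragment p-values behave at the boundaries", {
  m <- uniform_fixture()
  nf <- nrow(m$fragments)
  ctrl <- make_counts(m, rep(5, nf), library_size = 5L * nf)
  zero_exp <- make_counts(m, rep(0, nf), library_size = 1L)
  p0 <- fragment_pvalues(zero_exp, ctrl)
  expect_true(all(p0 == 1))                        # empty upper tail

  # exp == ctrl: p concentrated near/above the Poisson median, none pass BH
  same <- fragment_pvalues(ctrl, ctrl)
  expect_gt(min(same), 0.3)
  expect_true(all(bh_qvalues(same) > 0.05))

  # massive enrichment over a tiny background
  w <- rep(1, nf); w[10L] <- 100
  strong <- make_counts(m, w, library_size = as.integer(sum(w)))
  p <- fragment_pvalues(strong, make_counts(m, rep(1, nf), nf))
  expect_lt(p[10L], 1e-100)
})

test_that("broad peaks seed at q_sig and link through q_link runs", {
  m <- uniform_fixture(32L)
  nf <- nrow(m$fragments)
  ctrl <- make_counts(m, rep(10, nf), library_size = 10L * nf)

  # null: identical counts give no peaks
  expect_identical(nrow(call_broad_peaks(ctrl, ctrl)), 0L)

  # one isolated strongly enriched fragment -> one peak, exactly there
  w <- rep(10, nf); w[25L] <- 400
  one <- call_broad_peaks(make_counts(m, w, as.integer(sum(w))), ctrl)
  expect_identical(nrow(one), 1L)
  expect_identical(one$start, m$fragments$start[25L])
  expect_identical(one$end, m$fragments$end[25L])
  expect_identical(one$score,
                   pmin(1000L, as.integer(round(10 * one$qValue))))
  expect_true(one$qValue <= one$pValue)

  # two seeds separated by one linking-level fragment merge into one peak:
  # with q_sig 1e-20 / q_link 0.5, weight 30 sits between the cut-offs
  # (q ~ 1e-6 against lambda 10) while 400 is a seed
  w2 <- rep(10, nf); w2[c(30L, 32L)] <- 400; w2[31L] <- 30
  exp2 <- make_counts(m, w2, as.integer(sum(w2)))
  pars <- peak_call_params(q_sig = 1e-20, q_link = 0.5)
  q2 <- bh_qvalues(fragment_pvalues(exp2, ctrl, pars))
  expect_gt(q2[31L], pars$q_sig)
  expect_lte(q2[31L], pars$q_link)
  merged <- call_broad_peaks(exp2, ctrl, pars)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$start, m$fragments$start[30L])
  expect_identical(merged$end, m$fragments$end[32L])
})

test_that("null simulations stay calibrated at BH 0.05", {
  for (seed in c(41L, 42L, 43L)) {
    cfg <- sim_config(chromosome_length = 40000L, n_binding_sites = 5L,
                      p_bound = 0.05, p_open = 0.05, n_molecules = 8000L,
                      seed = seed, include_adaptors = FALSE)
    g <- simulate_genome(cfg)
    map <- build_fragment_map(g)
    truth <- simulate_truth(map, cfg)
    counts <- lapply(1:2, function(i) {
      sm <- simulate_sample(g, map, truth, "fusion", cfg, sample_index = i)
      al <- align_exact(sm$reads, g)
      count_fragments(al$alignments, map)
    })
    q <- bh_qvalues(fragment_pvalues(counts[[1L]], counts[[2L]]))
    expect_lte(mean(q <= 0.05), 0.05)
  }
})

test_that("the default threshold ladder satisfies its anchors", {
  thr <- default_fdr_thresholds()
  expect_identical(length(thr), 41L)
  expect_identical(thr[1L], 0L)
  expect_identical(thr[length(thr)], 2000L)
  expect_true(all(c(0:5, seq(10, 100, 10), 125, 1900, 2000) %in% thr))
  expect_false(is.unsorted(thr, strictly = TRUE))
})

test_that("threshold consensus pools, filters and merges", {
  a <- make_peaks("chr1", c(0L, 200L), c(100L, 300L), qValue = c(3, 0.5))
  b <- make_peaks("chr1", 50L, 150L, qValue = 12)
  cons <- threshold_consensus(list(p1 = a, p2 = b),
                              consensus_config(thresholds = c(0, 1, 5)))
  # threshold 0: union of everything, [0,100)+[50,150) merge to [0,150)
  expect_identical(cons[["0"]]$start, c(0L, 200L))
  expect_identical(cons[["0"]]$end, c(150L, 300L))
  # threshold 1: the qValue 0.5 record is dropped
  expect_identical(cons[["1"]]$start, c(0L))
  expect_identical(cons[["1"]]$end, 150L)
  expect_equal(cons[["1"]]$qValue, 12)            # max of constituents
  # threshold 5: only the strong peak remains
  expect_identical(cons[["5"]]$start, 50L)
  expect_error(threshold_consensus(list(p1 = a),
                                   consensus_config(thresholds = numeric(0L))),
               "nonempty")
})

test_that("consensus coverage is nested across increasing thresholds", {
  set.seed(55L)
  sets <- lapply(1:4, function(i) {
    s <- sort(sample(seq(0L, 5000L, by = 10L), 30L))
    make_peaks("chr1", s, s + sample(20:200, 30L, replace = TRUE),
               qValue = stats::rexp(30L, rate = 1 / 20))
  })
  cons <- threshold_consensus(sets, consensus_config())
  covered <- vapply(cons, function(ps) sum(ps$end - ps$start), numeric(1L))
  expect_false(is.unsorted(rev(covered)))   # nonincreasing coverage
  # and interval containment of consecutive levels
  for (i in seq_len(length(cons) - 1L)) {
    hi <- cons[[i + 1L]]
    if (nrow(hi) == 0L) break
    expect_true(all(nanodamr:::peak_overlap_any(hi, cons[[i]]) == 1L))
  }
})

test_that("the 50% reproducibility rule is inclusive at the boundary", {
  cfgc <- consensus_config()
  half <- make_peaks("chr1", 100L, 200L, qValue = 50)
  quarter <- make_peaks("chr1", 1000L, 1100L, qValue = 50)
  absent <- make_peaks("chr1", 5000L, 5100L, qValue = 0.5)
  sets <- list(
    a = rbind(half, quarter), b = half,
    c = absent, d = make_peaks("chr1", 7000L, 7100L, qValue = 50))
  rp <- reproducible_peaks(sets, cfgc, at_threshold = 10)
  # present in 2/4 files (exactly 50%): retained
  expect_true(any(rp$start == 100L))
  # present in 1/4 files (25%): dropped
  expect_false(any(rp$start == 1000L))
  # a peak present in all files survives any fraction <= 1
  all4 <- lapply(1:4, function(i) half)
  expect_identical(nrow(reproducible_peaks(all4, cfgc, 10)), 1L)
  expect_error(reproducible_peaks(list(half), cfgc, 10), "two")
  expect_error(consensus_config(reproducible_fraction = 0), "fraction")
})

test_that("broadPeak files round trip and validate", {
  ps <- make_peaks("chr1", c(10L, 500L), c(200L, 900L),
                   qValue = c(12.3456, 3.21), signalValue = c(1.5, 0.7),
                   pValue = c(15.5, 4.2))
  path <- withr::local_tempfile(fileext = ".broadPeak")
  write_broadpeak(ps, path)
  fields <- strsplit(readLines(path)[1L], "\t")[[1L]]
  expect_identical(length(fields), 9L)
  expect_identical(fields[9L], "12.3456")          # >= 4 significant digits
  back <- read_broadpeak(path)
  expect_equal(as.data.frame(back), as.data.frame(ps), tolerance = 1e-6)

  writeLines("chr1\t1\t2\tx", path)
  expect_error(read_broadpeak(path), "9 columns")
  writeLines(c("chr1\t500\t900\tb\t32\t.\t0.7\t4.2\t3.21",
               "chr1\t10\t200\ta\t123\t.\t1.5\t15.5\t12.3"), path)
  expect_error(read_broadpeak(path), "sorted")

  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, bed)
  expect_identical(strsplit(readLines(bed)[1L], "\t")[[1L]][1:3],
                   c("chr1", "10", "200"))
})
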