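# brute-force complexity oracle: enumerate all size-n subsets of the reads
enum_expected_distinct <- function(counts, n) {
  reads <- rep(seq_along(counts), counts)
  subsets <- utils::combn(seq_along(reads), n)
  mean(apply(subsets, 2L, function(ix) length(unique(reads[ix]))))
}

test_that("correlation matrices are symmetric with unit diagonal", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  cm <- correlation_matrix(m)
  expect_equal(cm["a", "a"], 1)
  expect_equal(cm["a", "b"], 1)          # perfect linearity
  expect_equal(cm["a", "c"], -1)         # negation
  expect_equal(cm, t(cm))
  flat <- cbind(a = c(1, 2, 3), z = c(5, 5, 5))
  expect_identical(attr(correlation_matrix(flat), "flagged_constant"), "z")
  expect_error(correlation_matrix(m[, 1L, drop = FALSE]), "two")
})

test_that("flag_libraries applies the inclusive 0.9 / 0.8 rules", {
  samples <- c("tf_1", "tf_2", "tf_3", "dam_1", "ratio_1", "ratio_2")
  cm <- diag(1, 6L)
  dimnames(cm) <- list(samples, samples)
  cm["tf_1", "tf_2"] <- cm["tf_2", "tf_1"] <- 0.95
  cm["tf_1", "tf_3"] <- cm["tf_3", "tf_1"] <- 0.95
  cm["tf_2", "tf_3"] <- cm["tf_3", "tf_2"] <- 0.70   # tf_3 vs tf_2 low
  cm["ratio_1", "ratio_2"] <- cm["ratio_2", "ratio_1"] <- 0.80
  groups <- c(tf_1 = "fusion", tf_2 = "fusion", tf_3 = "fusion",
              dam_1 = "damonly", ratio_1 = "ratio", ratio_2 = "ratio")
  fl <- flag_libraries(cm, groups, kind = c(ratio = "comparison"))
  dec <- stats::setNames(fl$decision, fl$sample)
  expect_identical(dec[["tf_1"]], "keep")             # median 0.95 >= 0.9
  expect_identical(dec[["dam_1"]], "insufficient_replicates")
  expect_identical(dec[["ratio_1"]], "keep")          # exactly 0.8 kept

  # drive a fusion replicate below threshold everywhere
  cm2 <- cm
  cm2["tf_3", c("tf_1", "tf_2")] <- 0.7
  cm2[c("tf_1", "tf_2"), "tf_3"] <- 0.7
  fl2 <- flag_libraries(cm2, groups, kind = c(ratio = "comparison"))
  expect_identical(fl2$decision[fl2$sample == "tf_3"], "flag")
  # and a ratio track just below its threshold
  cm2["ratio_1", "ratio_2"] <- cm2["ratio_2", "ratio_1"] <- 0.79
  fl3 <- flag_libraries(cm2, groups, kind = c(ratio = "comparison"))
  expect_identical(fl3$decision[fl3$sample == "ratio_2"], "flag")
})

test_that("complexity curve equals the exact hypergeometric expectation", {
  # {a, a, b}: hand enumeration gives 1, 5/3, 2
  cc <- complexity_curve(c("a", "a", "b"), n_points = 3L)
  expect_equal(cc$total_reads, 1:3)
  expect_equal(cc$expected_distinct, c(1, 5 / 3, 2))

  # exhaustive subset enumeration for every multiset profile of <= 8 reads
  profiles <- list()
  part <- function(n, max) {
    if (n == 0L) return(list(integer(0L)))
    unlist(lapply(seq_len(min(n, max)), function(k) {
      lapply(part(n - k, k), function(rest) c(k, rest))
    }), recursive = FALSE)
  }
  for (N in 1:8) profiles <- c(profiles, part(N, N))
  for (counts in profiles) {
    N <- sum(counts)
    keys <- rep(letters[seq_along(counts)], counts)
    cc <- complexity_curve(keys, n_points = N)
    for (j in seq_along(cc$total_reads)) {
      n <- cc$total_reads[j]
      expect_equal(cc$expected_distinct[j], enum_expected_distinct(counts, n))
    }
  }
})

test_that("complexity curve limiting cases", {
  uniq <- complexity_curve(as.character(1:40), n_points = 8L)
  expect_equal(uniq$expected_distinct, uniq$total_reads)   # d(n) == n
  dup <- complexity_curve(rep("x", 30L), n_points = 5L)
  expect_equal(dup$expected_distinct, rep(1, 5L))          # d(n) == 1
  expect_error(complexity_curve(character(0L)), "empty")
  # monotone, bounded by n, exact at full depth
  cc <- complexity_curve(c(rep("a", 4L), "b", "b", "c"), n_points = 7L)
  expect_false(is.unsorted(cc$expected_distinct))
  expect_true(all(cc$expected_distinct <= cc$total_reads + 1e-12))
  expect_equal(cc$expected_distinct[7L], 3)
})

test_that("fingerprint curves rank bins and end at (1, 1)", {
  fp <- fingerprint_curve(c(0, 0, 10))
  expect_equal(fp$rank_fraction, c(1, 2, 3) / 3)
  expect_equal(fp$read_fraction, c(0, 0, 1))

  unif <- fingerprint_curve(rep(4, 10L))
  expect_equal(unif$read_fraction, unif$rank_fraction)     # diagonal

  set.seed(9L)
  r <- fingerprint_curve(stats::rpois(50L, 5))
  expect_equal(r$read_fraction[50L], 1)
  expect_false(is.unsorted(r$read_fraction))
  # convexity of the sorted cumulative curve
  expect_true(all(diff(diff(r$read_fraction)) >= -1e-12))
  expect_error(fingerprint_curve(c(0, 0)), "zero")
})

test_that("enrichment profiles average the track around peak centers", {
  m <- toy_map()
  const <- dam_track(m$fragments, c(2, 2, 2))
  pk <- make_peaks("chr_toy", 6L, 14L, qValue = 10)
  prof <- enrichment_profile(const, pk, half_width = 8L, n_positions = 17L)
  expect_equal(prof$mean_signal, rep(2, 17L))              # flat track
  expect_identical(attr(prof, "n_peaks"), 1L)
  expect_true(all(prof$offset == -rev(prof$offset)))       # symmetric grid

  spike <- dam_track(m$fragments, c(0, 1, 0))
  prof2 <- enrichment_profile(spike, pk, half_width = 8L, n_positions = 17L)
  center <- prof2$mean_signal[prof2$offset == 0]
  expect_equal(center, 1)
  expect_gte(center, max(prof2$mean_signal))

  # linearity: profile of an averaged track == mean of profiles
  t1 <- dam_track(m$fragments, c(1, 3, 1))
  t2 <- dam_track(m$fragments, c(0, 1, 2))
  avg <- average_tracks(list(t1, t2))
  pa <- enrichment_profile(avg, pk, half_width = 6L, n_positions = 13L)
  p1 <- enrichment_profile(t1, pk, half_width = 6L, n_positions = 13L)
  p2 <- enrichment_profile(t2, pk, half_width = 6L, n_positions = 13L)
  expect_equal(pa$mean_signal, (p1$mean_signal + p2$mean_signal) / 2)
  expect_error(enrichment_profile(const, pk[0L, ]), "empty")
})

test_that("the pooling calculator applies the printed formulas", {
  one <- pooling_plan(300, 30)
  expect_equal(one$libraries$molarity_nM, 150)    # (1500/300) * 30

  three <- pooling_plan(rep(300, 3L), rep(30, 3L))
  expect_equal(three$libraries$volume_uL, rep(2.22222222, 3L),
               tolerance = 1e-6)
  expect_equal(three$water_uL, 50 - 3 * (20 / 150) * (50 / 3) ,
               tolerance = 1e-9)
  expect_equal(three$water_uL, 43.3333333, tolerance = 1e-6)
  expect_equal(three$achieved_nM, 20)             # mass balance

  expect_error(pooling_plan(300, 0.1), "infeasible")
  expect_error(pooling_plan(numeric(0L), numeric(0L)), "length")
})
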