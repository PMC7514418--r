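test_that("the per-instance hit estimator and mass split are correct", {
  expect_equal(repeat_prob(7, 1), 0.8)
  expect_equal(repeat_prob(0, 0), 0.5)
  d <- repeat_distribution("G", 0.8)
  expect_equal(unname(d), c(0.2 / 3, 0.2 / 3, 0.8, 0.2 / 3))
  expect_equal(sum(d), 1)
  # deactivation threshold arithmetic from the estimator
  expect_lt(repeat_prob(0, 2), 0.5)
  expect_gte(repeat_prob(1, 1), 0.5)
})

test_that("the k-mer index stores following-positions with a FIFO bound", {
  cfg <- repeat_config(k = 4, rpn = 4, max_positions = 2)
  tr <- repeat_tracker(cfg, seed = 1)
  # ACGT appears at positions 0, 8 and 16 in this stream
  s <- "ACGTAAAAACGTAAAAACGTAAAA"
  for (b in strsplit(s, "")[[1]]) repeat_step(tr, b)
  # stored position = position of the base following each occurrence,
  # bounded at 2 with the oldest evicted
  expect_identical(repeat_positions(tr, "ACGT"), c(12L, 20L))
  expect_identical(repeat_positions(tr, "GGGG"), integer(0))
})

test_that("instances spawn on k-mer matches, predict the copied base, and die on poor performance", {
  cfg <- repeat_config(k = 4, rpn = 1, a_hit = 1, a_miss = 1,
                       deactivate_below = 0.3, ir = FALSE)
  tr <- repeat_tracker(cfg, seed = 1)
  # every 4-mer unique except ACGT at positions 0 and 6
  for (b in strsplit("ACGTCCACGT", "")[[1]]) repeat_step(tr, b)
  inst <- repeat_instances(tr)
  expect_identical(nrow(inst), 1L)
  expect_identical(inst$ptr, 4) # continuation of the first ACGT occurrence
  # next base copied from position 4 is "C", offered with q = 1/2
  st <- repeat_step(tr, "C")
  expect_identical(st$n_active, 1L)
  expect_equal(st$dist, unname(repeat_distribution("C", repeat_prob(0, 0))))
  expect_identical(repeat_instances(tr)$hits, 1)
  # mismatches drive q = (h+1)/(h+f+2) below 0.3: 2/4, 2/5, 2/6, then 2/7
  for (b in c("G", "T", "G", "T")) repeat_step(tr, b)
  expect_identical(nrow(repeat_instances(tr)), 0L)
})

test_that("the rpn bound caps simultaneous instances", {
  cfg <- repeat_config(k = 4, rpn = 1, deactivate_below = 0.05, ir = FALSE)
  tr <- repeat_tracker(cfg, seed = 1)
  x <- gen_dna("tandem", unit = "ACGTGTCA", copies = 10)
  for (b in strsplit(x, "")[[1]]) st <- repeat_step(tr, b)
  expect_lte(max(repeat_scan(x, cfg, seed = 1)$n_active), 1L)
})

test_that("spawn trajectories are reproducible under the seed", {
  x <- gen_dna("dispersed", n = 4000, unit_len = 60, copies = 15, seed = 9)
  cfg <- repeat_config(k = 8, rpn = 8)
  a <- repeat_scan(x, cfg, seed = 123)
  b <- repeat_scan(x, cfg, seed = 123)
  c <- repeat_scan(x, cfg, seed = 124)
  expect_identical(a, b)
  expect_false(identical(a$bits, c$bits)) # different stochastic starts
})

test_that("stored positions never reach beyond the coded prefix", {
  x <- gen_dna("tandem", unit = "ACGTGTCAAC", copies = 12)
  cfg <- repeat_config(k = 5, rpn = 4, max_positions = 16)
  tr <- repeat_tracker(cfg, seed = 2)
  chars <- strsplit(x, "")[[1]]
  for (i in seq_along(chars)) {
    repeat_step(tr, chars[i])
    if (i >= 10) {
      pos <- repeat_positions(tr, substr(x, i - 4, i))
      expect_true(all(pos <= i)) # causality: decoder can always follow
    }
  }
})

test_that("the repeat class alone drives an exact tandem array below 0.1 bits/base", {
  x <- gen_dna("tandem", unit_len = 50, copies = 2000, seed = 5)
  sc <- repeat_scan(x, repeat_config(k = 11, rpn = 16, a_hit = 2, a_miss = 1), seed = 1)
  expect_lt(mean(sc$bits[101:100000]), 0.1)
})

test_that("inverted-repeat walking codes a reverse-complement copy; disabled it cannot", {
  S <- gen_dna("random", n = 2000, seed = 13) # |S| >= 10 * k
  x <- paste0(S, reverse_complement(S))
  half <- (nchar(S) + 1):(2 * nchar(S))
  on <- repeat_scan(x, repeat_config(k = 11, rpn = 16, ir = TRUE), seed = 1)
  off <- repeat_scan(x, repeat_config(k = 11, rpn = 16, ir = FALSE), seed = 1)
  expect_lt(mean(on$bits[half]), 0.5)
  expect_gt(mean(off$bits[half]), 1.9)
  # an inverted-repeat instance predicts the complement of the copied base
  expect_equal(mean(off$bits), 2, tolerance = 0.1) # random + RC is incompressible forward-only
})

test_that("with no active instances the class mixture is uniform", {
  sc <- repeat_scan("ACGTACGTAC", repeat_config(k = 8, rpn = 2), seed = 1)
  expect_true(all(abs(sc$bits - 2) < 1e-12)) # uniform -> 2 bits everywhere
})
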