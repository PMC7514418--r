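test_that("the alpha estimator balances uniform and frequency distributions", {
  expect_equal(cm_estimate(c(0, 0, 0, 0), 1), rep(0.25, 4))
  expect_equal(cm_estimate(c(3, 1, 0, 0), 1), c(0.5, 0.25, 0.125, 0.125))
  expect_equal(cm_estimate(c(5, 0, 0, 0), 1 / 1000)[1], 5.001 / 5.004)
  # distributions are proper for any counts
  with_seed(1, {
    for (r in 1:20) {
      d <- cm_estimate(sample(0:255, 4, replace = TRUE), runif(1, 0.001, 5))
      expect_equal(sum(d), 1, tolerance = 1e-12)
      expect_true(all(d > 0))
    }
  })
})

test_that("counter update halves all four counters at saturation", {
  expect_identical(counter_update(c(255, 10, 3, 0), "A"), c(128L, 5L, 1L, 0L))
  expect_identical(counter_update(c(0, 0, 0, 0), "C"), c(0L, 1L, 0L, 0L))
  # halving preserves the count ordering within a context
  with_seed(2, {
    for (r in 1:20) {
      cc <- sort(sample(0:255, 4), decreasing = TRUE)
      up <- counter_update(cc, 0L)
      expect_false(is.unsorted(rev(up[2:4])))
      expect_true(up[1] >= up[2])
    }
  })
})

test_that("dense table and cache-hash storage agree when nothing is evicted", {
  a <- counter_store(4, "table")
  b <- counter_store(4, "cache_hash", hash_bits = 12, max_collisions = 8)
  with_seed(3, {
    ctxs <- replicate(40, paste(sample(BASES, 4, replace = TRUE), collapse = ""))
    for (i in seq_along(ctxs)) {
      s <- sample(0:3, 1)
      store_update(a, ctxs[i], s)
      store_update(b, ctxs[i], s)
    }
    for (ctx in unique(ctxs)) {
      expect_identical(store_counts(a, ctx), store_counts(b, ctx))
    }
  })
})

test_that("cache-hash buckets evict the oldest entry (FIFO)", {
  # one bucket (hash_bits = 0) holding at most two contexts
  s <- counter_store(3, "cache_hash", hash_bits = 0, max_collisions = 2)
  store_update(s, "AAA", "A")
  store_update(s, "CCC", "C")
  expect_identical(store_counts(s, "AAA"), c(1L, 0L, 0L, 0L))
  store_update(s, "GGG", "G") # third insert: AAA (oldest) evicted
  expect_identical(store_counts(s, "AAA"), c(0L, 0L, 0L, 0L))
  expect_identical(store_counts(s, "CCC"), c(0L, 1L, 0L, 0L))
  expect_identical(store_counts(s, "GGG"), c(0L, 0L, 1L, 0L))
})

test_that("inverted-repeat events map windows onto the opposite strand", {
  expect_identical(ir_event("AAC"), list(context = "GT", symbol = "T"))
  expect_identical(ir_event("AT"), list(context = "A", symbol = "T"))
  expect_identical(ir_event("AC"), list(context = "G", symbol = "T"))
  # consistency with the string-level reverse complement
  with_seed(4, {
    for (k in c(1, 3, 6)) {
      w <- paste(sample(BASES, k + 1, replace = TRUE), collapse = "")
      ev <- ir_event(w)
      expect_identical(ev$context, o_rc(substr(w, 2, k + 1)))
      expect_identical(ev$symbol, o_rc(substr(w, 1, 1)))
    }
  })
})

test_that("streamed context models match a brute-force recount oracle", {
  with_seed(5, {
    for (case in 1:6) {
      k <- sample(1:3, 1)
      alpha <- sample(c(1, 0.5, 1 / 16), 1)
      mode <- c("forward", "ir_only", "both")[1 + (case %% 3)]
      s <- paste(sample(BASES, 120, replace = TRUE), collapse = "")
      got <- cm_scan(s, cm_config(k = k, alpha = alpha, gamma = 0.5, ir_mode = mode))
      want <- o_cm_scan(s, k, alpha, mode)
      expect_equal(unname(got), want, tolerance = 1e-12)
    }
  })
})

test_that("inverted-repeat modes compress a reverse-complement copy, forward does not", {
  S <- gen_dna("random", n = 2000, seed = 5)
  x <- paste0(S, reverse_complement(S))
  sy <- o_codes(x) + 1L
  half <- (nchar(S) + 20):(2 * nchar(S))
  bits <- function(mode) {
    m <- cm_scan(x, cm_config(k = 8, alpha = c(1, 4), gamma = 0.9, ir_mode = mode))
    mean(-log2(m[cbind(half, sy[half])]))
  }
  expect_gt(bits("forward"), 1.9)
  expect_lt(bits("ir_only"), 1.0)
  expect_lt(bits("both"), 1.0)
})

test_that("an order-2 model approaches 2 bits/base on uniform random data", {
  x <- gen_dna("random", n = 100000, seed = 8)
  m <- cm_scan(x, cm_config(k = 2, alpha = 1, gamma = 0.8))
  sy <- o_codes(x) + 1L
  bits <- mean(-log2(m[cbind(seq_along(sy), sy)]))
  expect_equal(bits, 2.0, tolerance = 0.01)
})

test_that("tolerant-model state transitions follow the edit and gating rules", {
  cfg <- cm_config(k = 3, alpha = 1, gamma = 0.8,
                   stcm = stcm_config(max_subs = 2, t = 3, l = 8))
  tr <- stcm_tracker(cfg)
  with_seed(9, {
    prev <- list(edited_context = "AAA", subs_left = 2L)
    x <- c(strsplit(gen_dna("tandem", unit = "ACGTT", copies = 30), "")[[1]],
           strsplit(gen_dna("random", n = 50, seed = 2), "")[[1]])
    hist <- character(0)
    for (b in x) {
      s <- stcm_step(tr, b)
      hist <- c(hist, b)
      expect_equal(sum(s$dist), 1, tolerance = 1e-12)
      if (!s$active) expect_equal(s$dist, rep(0.25, 4)) # off -> uniform output
      expect_identical(s$active_after, s$fails_in_window <= 3)
      if (s$hit) {
        # hit appends the true symbol to the edited context
        expect_identical(s$edited_context,
                         paste0(substr(prev$edited_context, 2, 3), b))
      } else if (prev$subs_left > 0) {
        # fail with budget: model's own top symbol substituted in
        expect_identical(s$edited_context,
                         paste0(substr(prev$edited_context, 2, 3), BASES[s$top + 1]))
        expect_identical(s$subs_left, prev$subs_left - 1L)
      } else {
        # budget exhausted: resynchronize on the true history, refill budget
        expect_identical(s$edited_context,
                         paste(tail(hist, 3), collapse = ""))
        expect_identical(s$subs_left, 2L)
      }
      prev <- s
    }
  })
})

test_that("a freshly initialized tolerant model is active and uniform", {
  cfg <- cm_config(k = 2, alpha = 1, stcm = stcm_config(max_subs = 1, t = 4, l = 8))
  tr <- stcm_tracker(cfg)
  s <- stcm_step(tr, "A")
  expect_true(s$active)
  expect_equal(s$dist, rep(0.25, 4))
})
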