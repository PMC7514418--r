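test_that("single bases and tiny sequences survive every preset", {
  for (lev in c(1, 5, 10, 15)) {
    for (b in BASES) {
      z <- dna_compress(b, level = lev, seed = 3)
      expect_identical(dna_decompress(z), b)
    }
    expect_identical(dna_decompress(dna_compress("ACGTT", level = lev, seed = 1)),
                     "ACGTT")
  }
})

test_that("invalid inputs are rejected with explicit errors", {
  expect_error(dna_compress("", level = 1), "empty")
  expect_error(level_preset(0), "level")
  expect_error(level_preset(16), "level")
  expect_error(codec_config(), "at least one model")
  expect_error(config_without_repeats(codec_config(rms = list(repeat_config()))),
               "no models")
})

test_that("the container header round-trips every configuration field", {
  cfg <- codec_config(
    cms = list(cm_config(k = 3, alpha = c(2, 7), gamma = 0.625, ir_mode = "both"),
               cm_config(k = 13, alpha = c(1, 32), gamma = 0.95,
                         storage = "cache_hash", hash_bits = 14,
                         max_collisions = 3,
                         stcm = stcm_config(max_subs = 4, t = 6, l = 24))),
    rms = list(repeat_config(k = 9, rpn = 5, a_hit = 3, a_miss = 2,
                             deactivate_below = 0.42, gamma = 0.125,
                             ir = FALSE, max_positions = 7)),
    cpcm_order = 11, cpcm_alpha = c(1, 3))
  z <- dna_compress("ACGTACGTACGTAAAT", config = cfg, seed = 987654321)
  h <- parse_container_header(z)
  expect_identical(h$length, 16)
  expect_identical(h$seed, 987654321)
  expect_identical(h$cpcm_k, 11L)
  expect_identical(h$cpcm_alpha_den, 3)
  m <- h$cms[[1]]
  expect_identical(c(m$k, m$alpha_num, m$alpha_den, m$gamma_pm, m$ir_mode),
                   c(3, 2, 7, 625, 2))
  s <- h$cms[[2]]$stcm
  expect_identical(c(s$max_subs, s$t, s$l), c(4L, 6L, 24L))
  r <- h$rms[[1]]
  expect_identical(c(r$k, r$rpn, r$a_hit_num, r$a_miss_num, r$deact_pm,
                     r$gamma_pm, r$max_pos), c(9, 5, 3, 2, 420, 125, 7))
  expect_false(r$ir)
})

test_that("tampered or truncated containers are rejected", {
  z <- as.raw(dna_compress(gen_dna("random", n = 500, seed = 1), level = 2, seed = 1))
  bad <- z
  bad[10] <- xor(bad[10], as.raw(0x40)) # flip a header bit
  expect_error(dna_decompress(bad), "checksum|magic|truncated")
  expect_error(dna_decompress(z[1:20]), "truncated")
  expect_error(dna_decompress(z[1:(length(z) - 60)]), "truncated")
  nomagic <- z
  nomagic[1] <- as.raw(0x58)
  expect_error(dna_decompress(nomagic), "magic")
})

test_that("compression reports expose sane metrics", {
  x <- gen_dna("tandem", unit_len = 40, copies = 100, seed = 6)
  z <- dna_compress(x, level = 4, seed = 2)
  r <- compression_report(z)
  expect_identical(r$length, 4000)
  expect_identical(r$bytes, length(z))
  expect_gt(r$bps, 0)
  expect_lte(r$bps, 8)
  expect_equal(sum(r$class_use), 1, tolerance = 1e-9)
  expect_equal(sum(r$win_rate), 1, tolerance = 1e-9)
  # a tandem array is dominated by the repeat class
  expect_gt(r$class_use[["repeat_models"]], 0.5)
})

test_that("preset resources grow monotonically with the level", {
  n_models <- max_k <- rpn <- hashb <- integer(15)
  for (lev in 1:15) {
    cfg <- level_preset(lev)
    n_stcm <- sum(vapply(cfg$cms, function(m) !is.null(m$stcm), TRUE))
    n_models[lev] <- length(cfg$cms) + n_stcm + length(cfg$rms)
    max_k[lev] <- max(vapply(cfg$cms, function(m) m$k, 0L))
    rpn[lev] <- max(vapply(cfg$rms, function(m) m$rpn, 0L))
    hashb[lev] <- max(vapply(cfg$cms, function(m) m$hash_bits, 0L))
  }
  expect_false(is.unsorted(n_models))
  expect_false(is.unsorted(max_k))
  expect_false(is.unsorted(rpn))
  expect_false(is.unsorted(hashb))
  # substitution-tolerant companions appear from level 5
  expect_true(all(vapply(5:15, function(l) {
    any(vapply(level_preset(l)$cms, function(m) !is.null(m$stcm), TRUE))
  }, TRUE)))
})

test_that("compressor and decompressor states agree at every checkpoint", {
  x <- gen_dna("dispersed", n = 60000, unit_len = 150, copies = 40, seed = 14)
  z <- dna_compress(x, level = 6, seed = 5, details = TRUE, checkpoint_every = 10000)
  y <- dna_decompress(z, details = TRUE, checkpoint_every = 10000)
  expect_identical(unclass(y)[1], x)
  cks <- attr(z, "details")$checkpoints
  expect_identical(length(cks), 6L)
  expect_identical(cks, attr(y, "details")$checkpoints)
})

test_that("decoder instrumentation reproduces the encoder's exactly", {
  x <- gen_dna("mutated", unit_len = 60, copies = 200, sub_rate = 0.03, seed = 15)
  z <- dna_compress(x, level = 5, seed = 7, details = TRUE)
  y <- dna_decompress(z, details = TRUE)
  dz <- attr(z, "details"); dy <- attr(y, "details")
  expect_identical(dz$bits, dy$bits)
  expect_identical(dz$selected, dy$selected)
  expect_identical(dz$winner, dy$winner)
})
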