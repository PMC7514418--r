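test_that("quantization hits worked examples exactly", {
  expect_identical(quantize_distribution(rep(0.25, 4)), rep(16384L, 4))
  # largest-remainder: 0.5875*65536 = 38502.4 gets the leftover unit
  expect_identical(quantize_distribution(c(0.5875, 0.1375, 0.1375, 0.1375)),
                   c(38503L, 9011L, 9011L, 9011L))
  # floor-at-1 takes from the dominant symbol
  e <- 1e-12
  expect_identical(quantize_distribution(c(1 - 3 * e, e, e, e)),
                   c(65533L, 1L, 1L, 1L))
  # remainder ties resolved in symbol code order
  expect_identical(quantize_distribution(c(0.3, 0.3, 0.2, 0.2)),
                   c(19661L, 19661L, 13107L, 13107L))
})

test_that("quantized tables always total 2^16 with minimum 1 and small loss", {
  with_seed(21, {
    for (r in 1:200) {
      p <- runif(4, 1e-4, 1)
      p <- p / sum(p)
      f <- quantize_distribution(p)
      expect_identical(sum(f), 65536L)
      expect_gte(min(f), 1L)
      expect_identical(f, o_quantize(p))
      # expected codelength loss (KL of the true distribution against the
      # quantized one) below 0.001 bits/symbol when min probability >= 1e-4
      loss <- sum(p * (log2(p) - log2(f / 65536)))
      expect_gte(loss, 0)
      expect_lt(loss, 0.001)
    }
  })
})

test_that("the range coder inverts exactly under shared tables", {
  with_seed(22, {
    for (n in c(1, 2, 7, 500)) {
      syms <- sample(0:3, n, replace = TRUE)
      fq <- t(vapply(seq_len(n), function(i) {
        p <- runif(4, 0.02, 1); quantize_distribution(p / sum(p))
      }, integer(4)))
      b <- arith_encode(syms, fq)
      expect_identical(arith_decode(b, fq, n), as.integer(syms))
    }
    # empty message: a flush-only stream decodes to nothing
    empty <- arith_encode(integer(0), matrix(integer(0), 0, 4))
    expect_identical(arith_decode(empty, matrix(integer(0), 0, 4), 0), integer(0))
  })
})

test_that("payload length stays within 64 bits of the ideal codelength", {
  with_seed(23, {
    n <- 10000
    syms <- sample(0:3, n, replace = TRUE)
    fq <- matrix(rep(16384L, 4 * n), ncol = 4)
    bits <- 8 * length(arith_encode(syms, fq))
    expect_gte(bits, 2 * n)
    expect_lte(bits, 2 * n + 64)

    # skewed table on an all-A message: about 74 bits of content
    n2 <- 1000
    fq2 <- matrix(rep(c(62259L, 1093L, 1092L, 1092L), n2), ncol = 4, byrow = TRUE)
    ideal <- -n2 * log2(62259 / 65536)
    bits2 <- 8 * length(arith_encode(rep(0L, n2), fq2))
    expect_lte(bits2, ideal + 64)
    expect_gte(bits2, ideal)

    # general tables: total output tracks sum(-log2 f/F)
    fq3 <- t(vapply(seq_len(n), function(i) {
      p <- runif(4, 0.05, 1); quantize_distribution(p / sum(p))
    }, integer(4)))
    ideal3 <- sum(-log2(fq3[cbind(seq_len(n), syms + 1)] / 65536))
    bits3 <- 8 * length(arith_encode(syms, fq3))
    expect_lte(bits3, ideal3 + 64)
    expect_gte(bits3, ideal3 - 1)
  })
})

test_that("encoding is bit-exact deterministic", {
  with_seed(24, {
    syms <- sample(0:3, 400, replace = TRUE)
    fq <- t(vapply(seq_len(400), function(i) {
      p <- runif(4, 0.05, 1); quantize_distribution(p / sum(p))
    }, integer(4)))
    expect_identical(arith_encode(syms, fq), arith_encode(syms, fq))
  })
})
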