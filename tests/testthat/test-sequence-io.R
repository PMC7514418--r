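test_that("two-bit packing follows the documented byte layout", {
  p <- pack_dna("ACGT")
  expect_identical(as.integer(p$data), 228L) # 0 | 1<<2 | 2<<4 | 3<<6
  expect_identical(length(p), 4L)

  e <- pack_dna("")
  expect_identical(length(e$data), 0L)
  expect_identical(length(e), 0L)

  a <- pack_dna("AAAAA")
  expect_identical(as.integer(a$data), c(0L, 0L))
  expect_identical(length(a), 5L)

  expect_identical(pack_dna("acgt")$data, pack_dna("ACGT")$data)
  expect_error(pack_dna("ACGN"), "non-ACGT")
})

test_that("pack/unpack is bijective and size is ceiling(n/4)", {
  with_seed(42, {
    for (n in c(0L, 1L, 2L, 3L, 4L, 5L, 63L, 64L, 65L, sample(6:1000, 12))) {
      s <- paste(sample(BASES, n, replace = TRUE), collapse = "")
      p <- pack_dna(s)
      expect_identical(unpack_dna(p), s)
      expect_identical(length(p$data), as.integer(ceiling(n / 4)))
    }
  })
})

test_that("random access matches the unpacked string", {
  with_seed(7, {
    s <- paste(sample(BASES, 200, replace = TRUE), collapse = "")
    p <- pack_dna(s)
    idx <- sample(200, 50)
    expect_identical(dna_at(p, idx),
                     paste(strsplit(s, "")[[1]][idx], collapse = ""))
  })
})

test_that("reading truncates the alphabet to ACGT and reports the removal", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGNNT"), f)
  s <- read_dna(f)
  rep <- filter_report(s)
  expect_identical(rep$kept, 4)
  expect_identical(rep$removed, 2)
  expect_identical(unpack_dna(s), "ACGT")

  # filtering is order-preserving: kept subsequence == input minus non-ACGT
  raw <- tempfile()
  messy <- "acGT-NRYswK tGc\naN-tt"
  writeLines(messy, raw)
  got <- unpack_dna(read_dna(raw, format = "raw"))
  want <- gsub("[^ACGT]", "", toupper(gsub("[ \n]", "", messy)))
  expect_identical(got, want)
})

test_that("multi-record FASTA concatenates records in file order", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACG", "T", ">b desc", "GGTT"), f)
  expect_identical(unpack_dna(read_dna(f)), "ACGTGGTT")
})

test_that("malformed or empty inputs raise explicit errors", {
  f <- tempfile()
  writeLines("ACGT", f)
  expect_error(read_dna(f, format = "fasta"), "malformed FASTA")
  writeLines("NNNN---", f)
  expect_error(read_dna(f, format = "raw"), "no ACGT bases")
  expect_error(read_dna(tempfile()), "not found")
})

test_that("write_dna round-trips in both formats and wraps FASTA lines", {
  f <- tempfile(fileext = ".fa")
  write_dna("ACGT", f, format = "fasta", line_width = 2)
  expect_identical(readLines(f), c(">sequence", "AC", "GT"))

  with_seed(3, {
    s <- paste(sample(BASES, 10000, replace = TRUE), collapse = "")
    for (fmt in c("fasta", "raw")) {
      write_dna(s, f, format = fmt)
      expect_identical(unpack_dna(read_dna(f)), s)
    }
  })

  r <- tempfile()
  write_dna("ACGT", r, format = "raw")
  expect_identical(readLines(r), "ACGT")
})
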