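#' Deterministic synthetic DNA with compressor-relevant structure
#'
#' Generates test sequences exhibiting the statistical structures the two
#' model classes target, fully determined by `seed` through the same portable
#' generator the codec uses:
#'
#' * `"random"` -- i.i.d. uniform ACGT (incompressible; the 2 bits/base floor).
#' * `"tandem"` -- a unit repeated back to back (`unit` or a random unit of
#'   `unit_len`), truncated to `n`.
#' * `"dispersed"` -- random background with `copies` copies of the unit
#'   overwritten at random positions.
#' * `"inverted"` -- `S` followed by its reverse complement.
#' * `"mutated"` -- tandem with substitution noise (`sub_rate`, default 5%).
#'
#' `sub_rate > 0` applies i.i.d. substitutions (each hit position gets a
#' uniformly chosen *different* base) to any kind.
#'
#' @param kind One of `"random"`, `"tandem"`, `"dispersed"`, `"inverted"`,
#'   `"mutated"`.
#' @param n Total length; for `"tandem"`/`"mutated"` it defaults to
#'   `unit_len * copies`.
#' @param unit_len Repeat-unit length (ignored when `unit` is given).
#' @param copies Number of unit copies.
#' @param sub_rate Substitution probability in `[0, 1]`.
#' @param seed Generator seed.
#' @param unit Optional explicit ACGT unit.
#' @return ACGT string of length `n`.
#' @examples
#' gen_dna("tandem", unit = "ACGT", copies = 5)
#' gen_dna("inverted", unit = "AAC")   # "AACGTT"
#' @export
gen_dna <- function(kind = c("random", "tandem", "dispersed", "inverted",
                             "mutated"),
                    n = NULL, unit_len = 50, copies = NULL, sub_rate = 0,
                    seed = 1, unit = NULL) {
  kind <- match.arg(kind)
  if (kind == "mutated") {
    kind <- "tandem"
    if (sub_rate == 0) sub_rate <- 0.05
  }
  if (!is.null(unit)) unit_len <- nchar(unit)
  if (kind %in% c("tandem")) {
    if (is.null(copies)) {
      if (is.null(n)) stop("give n or copies for tandem sequences", call. = FALSE)
      copies <- ceiling(n / unit_len)
    }
    if (is.null(n)) n <- unit_len * copies
  }
  if (is.null(n)) stop("n is required", call. = FALSE)
  if (sub_rate < 0 || sub_rate > 1) stop("sub_rate must be in [0,1]", call. = FALSE)
  cpp_gen_fixture(kind, as.numeric(n), if (is.null(unit)) "" else unit,
                  as.integer(unit_len), as.integer(if (is.null(copies)) 0 else copies),
                  as.numeric(sub_rate), as.numeric(seed))
}

#' Apply i.i.d. substitution noise to a sequence
#'
#' Each position is independently replaced, with probability `sub_rate`, by a
#' uniformly chosen different base; `sub_rate = 1` changes every base.
#'
#' @param x ACGT string or `packed_dna`.
#' @param sub_rate Substitution probability in `[0, 1]`.
#' @param seed Generator seed.
#' @return The mutated ACGT string.
#' @export
mutate_dna <- function(x, sub_rate, seed = 1) {
  s <- if (inherits(x, "packed_dna")) unpack_dna(x) else x
  cpp_mutate(s, as.numeric(sub_rate), as.numeric(seed))
}

#' Reverse complement
#'
#' @param x ACGT string.
#' @return The reverse-complemented string (A<->T, C<->G).
#' @export
reverse_complement <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
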