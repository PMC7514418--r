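#' Deterministic integer frequency quantization
#'
#' Maps a 4-symbol probability vector to integer frequencies summing to
#' exactly 2^16 by largest-remainder rounding (ties broken by symbol code
#' order), with every frequency floored at 1. The coder only ever sees these
#' integers, which is what makes the bitstream identical across platforms.
#'
#' @param p Probability vector of length 4, positive, summing to 1.
#' @return Integer vector of 4 frequencies, `sum == 65536`, `min >= 1`.
#' @examples
#' quantize_distribution(rep(0.25, 4))  # 16384 x 4
#' @export
quantize_distribution <- function(p) cpp_quantize(as.numeric(p))

#' Range-code a symbol stream under known frequency tables
#'
#' Byte-wise carry-propagating range coder (32-bit range) over the 4-letter
#' DNA alphabet. `arith_encode()` and `arith_decode()` are exact inverses
#' given the same frequency tables; the payload stays within a small constant
#' of the ideal codelength \eqn{\sum_i -\log_2(f_i / 2^{16})}.
#'
#' @param symbols Bases (letters or codes 0..3).
#' @param freqs Integer matrix, one row per symbol, 4 columns, each row
#'   summing to 65536 (see [quantize_distribution()]).
#' @return `arith_encode()`: raw vector. `arith_decode()`: integer symbol
#'   codes.
#' @export
arith_encode <- function(symbols, freqs) {
  if (is.character(symbols) && length(symbols) == 1L && nchar(symbols) > 1L) {
    symbols <- strsplit(symbols, "")[[1]]
  }
  cpp_rc_encode(.sym_code(symbols), freqs)
}

#' @rdname arith_encode
#' @param bytes Raw vector produced by `arith_encode()`.
#' @param n Number of symbols to decode.
#' @export
arith_decode <- function(bytes, freqs, n) {
  cpp_rc_decode(bytes, freqs, as.integer(n))
}
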