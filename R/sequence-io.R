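#' Pack a DNA string into two bits per base
#'
#' Stores a sequence over the alphabet A, C, G, T at two bits per base
#' (A=0, C=1, G=2, T=3), a factor-of-four saving over one byte per base.
#' Base `j` (0-based) occupies bits `2*(j %% 4)` and `2*(j %% 4) + 1` of byte
#' `j %/% 4` (least-significant bits first). Lowercase input is accepted and
#' upcased; any other character is an error -- use [read_dna()] to filter
#' arbitrary input.
#'
#' @param x A character scalar over ACGT (case-insensitive), or a
#'   `packed_dna` object (returned unchanged).
#' @return A `packed_dna` object: a list with `data` (raw vector of
#'   `ceiling(n/4)` bytes) and `length` (base count).
#' @examples
#' p <- pack_dna("ACGT")
#' as.integer(p$data)   # 228 == 0xE4
#' unpack_dna(p)
#' @seealso [unpack_dna()], [read_dna()]
#' @export
pack_dna <- function(x) {
  if (inherits(x, "packed_dna")) return(x)
  if (!is.character(x) || length(x) != 1L) {
    stop("x must be a single character string", call. = FALSE)
  }
  p <- cpp_pack(x)
  structure(list(data = p$data, length = p$length), class = "packed_dna")
}

#' Unpack a packed DNA sequence back to a string
#'
#' @param p A `packed_dna` object.
#' @return A character scalar over ACGT; `unpack_dna(pack_dna(s))` is
#'   identical to `toupper(s)` for every ACGT string `s`.
#' @export
unpack_dna <- function(p) {
  stopifnot(inherits(p, "packed_dna"))
  cpp_unpack(p$data, p$length)
}

#' @export
as.character.packed_dna <- function(x, ...) unpack_dna(x)

#' @export
length.packed_dna <- function(x) as.integer(x$length)

#' @export
print.packed_dna <- function(x, ...) {
  n <- x$length
  head <- if (n > 0) dna_at(x, seq_len(min(n, 60))) else ""
  cat(sprintf("packed_dna: %s bases (%d bytes)\n", format(n, big.mark = ","),
              length(x$data)))
  if (n > 0) cat(" ", head, if (n > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Random access into a packed sequence
#'
#' @param p A `packed_dna` object.
#' @param i 1-based base positions.
#' @return A character scalar with the bases at `i`, in order.
#' @export
dna_at <- function(p, i) {
  stopifnot(inherits(p, "packed_dna"))
  cpp_get_bases(p$data, p$length, as.numeric(i))
}

#' Read a DNA sequence, truncating the alphabet to ACGT
#'
#' Reads FASTA or raw text. Lowercase bases are upcased; every character that
#' is not A, C, G or T after that (N runs, IUPAC ambiguity codes, gaps, ...)
#' is deleted and counted, so the sequence the compressor sees -- and the only
#' thing it reproduces losslessly -- is the filtered ACGT stream. Records of a
#' multi-record FASTA are concatenated in file order; headers and record
#' boundaries are not preserved.
#'
#' @param path Path to the input file.
#' @param format `"fasta"`, `"raw"` (plain text, whitespace ignored) or
#'   `"auto"` (FASTA iff the first non-whitespace character is `>`).
#' @return A `packed_dna` object with attribute `filter_report`, a list with
#'   `kept`, `removed` and `source_name`; retrieve it with [filter_report()].
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGNNT"), f)
#' s <- read_dna(f)
#' filter_report(s)   # kept 4, removed 2
#' @export
read_dna <- function(path, format = c("auto", "fasta", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  stripped <- sub("^\\s+", "", lines)
  if (format == "auto") {
    first <- stripped[stripped != ""][1]
    format <- if (!is.na(first) && startsWith(first, ">")) "fasta" else "raw"
  }
  if (format == "fasta") {
    if (!any(startsWith(stripped, ">"))) {
      stop("malformed FASTA: no '>' header in ", path, call. = FALSE)
    }
    lines <- lines[!startsWith(stripped, ">")]
  }
  txt <- gsub("[ \t\r]", "", paste(lines, collapse = ""))
  f <- cpp_filter_acgt(txt)
  if (f$length == 0) {
    stop("no ACGT bases left after filtering ", path, call. = FALSE)
  }
  structure(list(data = f$data, length = f$length),
            class = "packed_dna",
            filter_report = list(kept = f$length, removed = f$removed,
                                 source_name = path))
}

#' @rdname read_dna
#' @param x A `packed_dna` returned by [read_dna()].
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' Write a DNA sequence as FASTA or raw text
#'
#' @param x A `packed_dna` object or an ACGT string.
#' @param path Output path.
#' @param format `"fasta"` (single record) or `"raw"` (one line).
#' @param line_width Body line width for FASTA output.
#' @param name FASTA record name.
#' @return `path`, invisibly. `read_dna(write_dna(x, path))` round-trips.
#' @export
write_dna <- function(x, path, format = c("fasta", "raw"), line_width = 70,
                      name = "sequence") {
  format <- match.arg(format)
  s <- if (inherits(x, "packed_dna")) unpack_dna(x) else pack_dna(x) |> unpack_dna()
  if (format == "raw") {
    writeLines(s, path)
  } else {
    if (line_width < 1) stop("line_width must be >= 1", call. = FALSE)
    starts <- seq(1L, nchar(s), by = line_width)
    body <- substring(s, starts, pmin(starts + line_width - 1L, nchar(s)))
    writeLines(c(paste0(">", name), body), path)
  }
  invisible(path)
}
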