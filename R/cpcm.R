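#' Competitive prediction context model
#'
#' A binary context model of order `k` over the history of which model class
#' predicted each past base best (0 = context-model class, 1 = repeat-model
#' class). Before coding a base the class with the higher estimated
#' probability given the last `k` winner bits is selected and only its mixed
#' distribution reaches the coder; after the base is known the actual winner
#' is recorded. The winner is computable from the decoded symbol, so both
#' codec sides maintain identical histories. Start-of-sequence context is
#' zero-padded; ties select class 0.
#'
#' @param k Context order over winner bits.
#' @param alpha Estimator parameter (scalar or `c(num, den)`).
#' @return A `cpcm` handle.
#' @export
cpcm_model <- function(k, alpha = 1) {
  a <- .as_rational(alpha)
  structure(list(ptr = cpp_cpcm_new(as.integer(k), a[["num"]], a[["den"]]),
                 k = as.integer(k)),
            class = "cpcm")
}

#' @rdname cpcm_model
#' @param m A `cpcm` handle.
#' @return `cpcm_select()`: list with the selected `class` and the two class
#'   probabilities `p0`, `p1`.
#' @export
cpcm_select <- function(m) {
  stopifnot(inherits(m, "cpcm"))
  cpp_cpcm_select(m$ptr)
}

#' @rdname cpcm_model
#' @param winner Class (0 or 1) that actually predicted the base best.
#' @export
cpcm_record <- function(m, winner) {
  stopifnot(inherits(m, "cpcm"))
  cpp_cpcm_record(m$ptr, as.integer(winner))
  invisible(m)
}

#' @rdname cpcm_model
#' @return `cpcm_context()`: the current winner-bit context as a 0/1 string
#'   (oldest bit first).
#' @export
cpcm_context <- function(m) {
  stopifnot(inherits(m, "cpcm"))
  cpp_cpcm_context(m$ptr)
}

#' @rdname cpcm_model
#' @param context A 0/1 string of length `k`.
#' @return `cpcm_counts()`: the two winner counts stored for `context`.
#' @export
cpcm_counts <- function(m, context) {
  stopifnot(inherits(m, "cpcm"))
  cpp_cpcm_counts(m$ptr, context)
}

#' Which class won a coded base
#'
#' @param p_cm_true,p_rm_true Probability each class mixture assigned to the
#'   realised base.
#' @return 1 if the repeat class predicted strictly better, else 0 (ties to
#'   the context-model class).
#' @export
determine_winner <- function(p_cm_true, p_rm_true) {
  cpp_winner(p_cm_true, p_rm_true)
}
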