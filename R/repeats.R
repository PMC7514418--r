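#' Configure a group of stochastic repeat models
#'
#' A repeat model (copy expert) is a pointer into the already-coded sequence
#' that predicts the next base as the base at the pointer -- complemented and
#' walking backward for inverted repeats. A group maintains a k-mer position
#' index over the coded history; whenever the current k-mer has been seen
#' before and a slot is free (at most `rpn` simultaneous instances), a new
#' instance spawns at one of the stored positions chosen *uniformly at
#' random* from the seeded generator both codec sides share -- so no position
#' index needs to be transmitted. Each instance predicts its copied base with
#' probability \eqn{q = (h + a_h) / (h + f + a_h + a_m)} (hits `h`, fails
#' `f`), the remaining mass split evenly, and is switched off when `q` drops
#' below `deactivate_below` or its pointer leaves the coded region.
#'
#' @param k K-mer size of the position index (>= 4).
#' @param rpn Maximum simultaneously active instances in this group.
#' @param a_hit,a_miss Positive pseudo-counts of the per-instance hit
#'   estimator.
#' @param deactivate_below Performance threshold in (0, 1).
#' @param gamma Shared forgetting factor of the instance weights; kept small
#'   so the mixture re-weights quickly.
#' @param ir Also spawn inverted-repeat instances (reverse-complement k-mer
#'   lookup, pointer walks backward, predictions complemented)?
#' @param max_positions Stored positions per k-mer (FIFO replacement).
#' @return A `repeat_config` list.
#' @export
repeat_config <- function(k = 11, rpn = 16, a_hit = 1, a_miss = 1,
                          deactivate_below = 0.5, gamma = 0.2, ir = TRUE,
                          max_positions = 16) {
  k <- as.integer(k)
  if (k < 4) stop("repeat k-mer size must be >= 4", call. = FALSE)
  if (rpn < 1) stop("rpn must be >= 1", call. = FALSE)
  ah <- .as_rational(a_hit, den = 1000L)
  am <- .as_rational(a_miss, den = 1000L)
  structure(list(
    k = k, rpn = as.integer(rpn),
    a_hit_num = ah[["num"]], a_hit_den = ah[["den"]],
    a_miss_num = am[["num"]], a_miss_den = am[["den"]],
    deact_pm = .permille(deactivate_below, "deactivate_below", lo = 1),
    gamma_pm = .permille(gamma, "gamma"),
    ir = isTRUE(ir),
    max_pos = as.integer(max_positions)
  ), class = "repeat_config")
}

#' Per-instance hit probability and predictive distribution
#'
#' @param hits,fails Outcome counts since the instance spawned.
#' @param a_hit,a_miss Pseudo-counts.
#' @return `repeat_prob()`: the hit probability `q`. `repeat_distribution()`:
#'   the 4-probability vector with mass `q` on `predicted` and `(1-q)/3` on
#'   each other base.
#' @examples
#' repeat_prob(7, 1)                  # 0.8
#' repeat_distribution("G", 0.8)      # 0.0667 0.0667 0.8 0.0667
#' @export
repeat_prob <- function(hits, fails, a_hit = 1, a_miss = 1) {
  (hits + a_hit) / (hits + fails + a_hit + a_miss)
}

#' @rdname repeat_prob
#' @param predicted The copied base (letter or code).
#' @param q Hit probability.
#' @export
repeat_distribution <- function(predicted, q) {
  d <- rep((1 - q) / 3, 4)
  d[.sym_code(predicted) + 1L] <- q
  names(d) <- c("A", "C", "G", "T")
  d
}

#' Step a repeat-model group base by base
#'
#' Mirrors the repeat-class side of the codec exactly: per base it returns
#' the group mixture *before* the update, then tallies hit/fail, advances
#' pointers, deactivates poor instances (their slot frees on the next step),
#' updates the k-mer index with the position following the current k-mer, and
#' attempts to spawn (forward first, then inverted-repeat).
#'
#' @param config A [repeat_config()].
#' @param seed Seed of the portable generator shared with the decompressor.
#' @return `repeat_tracker()`: a tracker handle.
#' @export
repeat_tracker <- function(config, seed = 0) {
  stopifnot(inherits(config, "repeat_config"))
  structure(list(ptr = cpp_rm_new(unclass(config), as.numeric(seed))),
            class = "repeat_tracker")
}

#' @rdname repeat_tracker
#' @param tracker A `repeat_tracker`.
#' @param base The true next base.
#' @return `repeat_step()`: list with the class `dist` (before update) and
#'   `n_active`.
#' @export
repeat_step <- function(tracker, base) {
  stopifnot(inherits(tracker, "repeat_tracker"))
  cpp_rm_step(tracker$ptr, base)
}

#' @rdname repeat_tracker
#' @param kmer ACGT string of the group's k-mer size.
#' @return `repeat_positions()`: stored positions (0-based, position of the
#'   base following each occurrence), oldest first.
#' @export
repeat_positions <- function(tracker, kmer) {
  stopifnot(inherits(tracker, "repeat_tracker"))
  cpp_rm_positions(tracker$ptr, kmer)
}

#' @rdname repeat_tracker
#' @return `repeat_instances()`: data frame of live instances (pointer, hits,
#'   fails, weight, current `q`, orientation).
#' @export
repeat_instances <- function(tracker) {
  stopifnot(inherits(tracker, "repeat_tracker"))
  as.data.frame(cpp_rm_instances(tracker$ptr))
}

#' Repeat-class-only codelength over a sequence
#'
#' @param x ACGT string or `packed_dna`.
#' @param config A [repeat_config()].
#' @param seed Generator seed.
#' @return List with `bits` (per-base `-log2` mixture probability of the true
#'   base) and `n_active` (live instances at each step).
#' @export
repeat_scan <- function(x, config, seed = 0) {
  stopifnot(inherits(config, "repeat_config"))
  s <- if (inherits(x, "packed_dna")) unpack_dna(x) else x
  cpp_rm_scan(unclass(config), s, as.numeric(seed))
}
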