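#' Configure a finite context model
#'
#' An order-`k` context model predicts the next base from counts conditioned
#' on the previous `k` bases, smoothed by the estimator
#' \deqn{P(s \mid c) = \frac{n(s, c) + \alpha}{\sum_{s'} n(s', c) + 4\alpha},}
#' so `alpha` balances between the frequency distribution (small `alpha`) and
#' the uniform one (large `alpha`). Each model carries a forgetting factor
#' `gamma` used by the class mixer (see [update_mix_weights()]). The
#' inverted-repeat sub-program maps every coded window onto its
#' reverse-complement image: `"both"` trains both the forward and the
#' reverse-complement event (predicting from the forward context), `"ir_only"`
#' predicts and trains on reverse-complement events only.
#'
#' Counts are 8-bit with halve-on-saturation, stored either in a dense table
#' of `4^(k+1)` counters (`storage = "table"`, feasible up to `k = 11`) or in
#' a bounded cache-hash that keeps at most `max_collisions` entries per
#' bucket, evicting the oldest (`storage = "cache_hash"`, for sparse deep
#' contexts).
#'
#' @param k Context order, 1..24.
#' @param alpha Estimator parameter, positive; a scalar or `c(num, den)`.
#' @param gamma Forgetting factor in `[0, 1)`.
#' @param ir_mode `"forward"`, `"ir_only"` or `"both"`.
#' @param storage `"table"` or `"cache_hash"`.
#' @param hash_bits Cache-hash bucket count as a power of two.
#' @param max_collisions Cache-hash bucket capacity.
#' @param counter_max Counter saturation point (default 255 = 8 bits).
#' @param stcm Optional [stcm_config()] attaching a substitution-tolerant
#'   context model that shares this model's counter store.
#' @return A `cm_config` list.
#' @export
cm_config <- function(k, alpha = 1, gamma = 0.8,
                      ir_mode = c("forward", "ir_only", "both"),
                      storage = c("table", "cache_hash"),
                      hash_bits = 16, max_collisions = 4,
                      counter_max = 255, stcm = NULL) {
  ir_mode <- match.arg(ir_mode)
  storage <- match.arg(storage)
  k <- as.integer(k)
  if (k < 1 || k > 24) stop("k must be in 1..24", call. = FALSE)
  if (storage == "table" && k > 12) {
    stop("storage = \"table\" needs 4^(k+1) counters; use cache_hash for k > 12",
         call. = FALSE)
  }
  a <- .as_rational(alpha)
  if (!is.null(stcm) && !inherits(stcm, "stcm_config")) {
    stop("stcm must be an stcm_config()", call. = FALSE)
  }
  structure(list(
    k = k,
    alpha_num = a[["num"]], alpha_den = a[["den"]],
    gamma_pm = .permille(gamma, "gamma"),
    ir_mode = match(ir_mode, c("forward", "ir_only", "both")) - 1L,
    dense = storage == "table",
    hash_bits = as.integer(hash_bits),
    max_coll = as.integer(max_collisions),
    counter_max = as.integer(counter_max),
    stcm = stcm
  ), class = "cm_config")
}

#' @rdname cm_config
#' @param max_subs Substitution budget of the tolerant model (>= 1).
#' @param t Fail threshold: the model switches off while more than `t` of the
#'   last `l` predictions were wrong.
#' @param l Length of the hit/fail history cache, `t <= l`.
#' @export
stcm_config <- function(max_subs = 5, t = 8, l = 32) {
  max_subs <- as.integer(max_subs); t <- as.integer(t); l <- as.integer(l)
  if (max_subs < 1) stop("max_subs must be >= 1", call. = FALSE)
  if (t <= 0 || t > l) stop("need 0 < t <= l", call. = FALSE)
  structure(list(max_subs = max_subs, t = t, l = l), class = "stcm_config")
}

#' Context-model probability estimator
#'
#' @param counts Integer vector of 4 symbol counts for one context
#'   (A, C, G, T order).
#' @param alpha Positive estimator parameter.
#' @return The 4 predictive probabilities `(counts + alpha) / (sum + 4 alpha)`.
#' @examples
#' cm_estimate(c(3, 1, 0, 0), alpha = 1)  # 0.5 0.25 0.125 0.125
#' @export
cm_estimate <- function(counts, alpha = 1) cpp_estimator(as.integer(counts), alpha)

#' Saturating counter update
#'
#' Increments the counter of `symbol`; if that would exceed `counter_max`,
#' all four counters of the context are first halved (integer division).
#'
#' @param counts Integer vector of 4 counts.
#' @param symbol Base ("A".."T") or code (0..3) to credit.
#' @param counter_max Saturation point.
#' @return The updated counts.
#' @export
counter_update <- function(counts, symbol, counter_max = 255) {
  cpp_bump_counts(as.integer(counts), .sym_code(symbol), as.integer(counter_max))
}

#' Stand-alone counter store
#'
#' The storage backend of a context model, exposed directly: a dense
#' `4^(k+1)` table or a bounded cache-hash with per-bucket FIFO eviction.
#' Unseen (or evicted) contexts read as all-zero counts.
#'
#' @param k Context order.
#' @inheritParams cm_config
#' @return A `counter_store` handle.
#' @export
counter_store <- function(k, storage = c("table", "cache_hash"),
                          hash_bits = 16, max_collisions = 4,
                          counter_max = 255) {
  storage <- match.arg(storage)
  h <- cpp_store_new(as.integer(k), storage == "table", as.integer(hash_bits),
                     as.integer(max_collisions), as.integer(counter_max))
  structure(list(ptr = h, k = as.integer(k)), class = "counter_store")
}

#' @rdname counter_store
#' @param store A `counter_store`.
#' @param context ACGT string of length `k`.
#' @param symbol Base or code to credit.
#' @export
store_update <- function(store, context, symbol) {
  stopifnot(inherits(store, "counter_store"))
  cpp_store_bump(store$ptr, context, .sym_code(symbol))
  invisible(store)
}

#' @rdname counter_store
#' @export
store_counts <- function(store, context) {
  stopifnot(inherits(store, "counter_store"))
  cpp_store_counts(store$ptr, context)
}

#' Inverted-repeat image of a coded window
#'
#' A window `x[i-k..i]` read on the opposite strand trains the context
#' `reverse-complement(x[i-k+1..i])` with symbol `complement(x[i-k])`; this
#' returns that (context, symbol) event.
#'
#' @param window ACGT string of length `k + 1`.
#' @return A list with `context` (length-`k` string) and `symbol`.
#' @examples
#' ir_event("AAC")  # context "GT", symbol "T"
#' @export
ir_event <- function(window) cpp_ir_event(window)

#' Stream a single context model over a sequence
#'
#' Runs predict-then-update along `x` (contexts zero-padded at the start,
#' i.e. implicit leading `A`s) and returns the n x 4 matrix of predictive
#' distributions, including the inverted-repeat behaviour of the
#' configuration. The mean of `-log2` of the true-symbol column is the
#' model's ideal codelength in bits per base.
#'
#' @param x ACGT string or `packed_dna`.
#' @param config A [cm_config()].
#' @return Numeric matrix, one row per base, columns A, C, G, T.
#' @export
cm_scan <- function(x, config) {
  stopifnot(inherits(config, "cm_config"))
  s <- if (inherits(x, "packed_dna")) unpack_dna(x) else x
  m <- cpp_cm_scan(unclass(config), s)
  colnames(m) <- c("A", "C", "G", "T")
  m
}

#' Stream the full context-model class mixture over a sequence
#'
#' The exact expert set the compressor uses on the context-model side --
#' every configured context model plus its attached substitution-tolerant
#' model -- blended with the forgetting-factor weight update, without class
#' selection or coding.
#'
#' @param x ACGT string or `packed_dna`.
#' @param cms List of [cm_config()] objects.
#' @return A list with `mixed` (n x 4 matrix of class probabilities) and
#'   `weights` (final expert weights).
#' @export
cm_class_scan <- function(x, cms) {
  s <- if (inherits(x, "packed_dna")) unpack_dna(x) else x
  res <- cpp_cm_class_scan(lapply(cms, unclass), s)
  colnames(res$mixed) <- c("A", "C", "G", "T")
  res
}

#' Step a substitution-tolerant context model
#'
#' Drives a host context model plus its attached tolerant model one base at a
#' time, exposing the tolerant model's internals. The tolerant model predicts
#' from its private *edited* context in the host's counter store; when its own
#' top prediction misses it writes that top symbol into the edited context (a
#' substitution, up to `max_subs`), and once the budget is spent it
#' resynchronizes on the true history. More than `t` fails in the last `l`
#' steps switch the model off (uniform output) until performance recovers.
#'
#' @param config A [cm_config()] with an `stcm` entry.
#' @return `stcm_tracker()`: a tracker handle. `stcm_step()`: a list with the
#'   tolerant model's `dist`, `top` (its argmax, code 0..3, ties to the lowest
#'   code), `active`/`active_after`, `hit`, `subs_left`, `fails_in_window`
#'   and `edited_context`.
#' @export
stcm_tracker <- function(config) {
  stopifnot(inherits(config, "cm_config"))
  if (is.null(config$stcm)) stop("config has no attached STCM", call. = FALSE)
  structure(list(ptr = cpp_stcm_new(unclass(config))), class = "stcm_tracker")
}

#' @rdname stcm_tracker
#' @param tracker An `stcm_tracker`.
#' @param base The true next base.
#' @export
stcm_step <- function(tracker, base) {
  stopifnot(inherits(tracker, "stcm_tracker"))
  cpp_stcm_step(tracker$ptr, base)
}
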