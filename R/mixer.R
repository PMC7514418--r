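#' Soft blending of expert distributions
#'
#' The mixture both model classes use: \eqn{P(x) = \sum_m w_m P_m(x)} with
#' nonnegative weights summing to one.
#'
#' @param dists Numeric matrix, one row per model, 4 columns (A, C, G, T);
#'   a list of 4-vectors is also accepted.
#' @param weights One weight per model.
#' @return The mixed 4-probability vector.
#' @examples
#' mix_distributions(rbind(c(.7, .1, .1, .1), rep(.25, 4)), c(.75, .25))
#' @export
mix_distributions <- function(dists, weights) {
  if (is.list(dists)) dists <- do.call(rbind, dists)
  cpp_mix(dists, as.numeric(weights))
}

#' Forgetting-factor weight update
#'
#' After each coded base the weight of model `m` becomes
#' \deqn{w_m \propto w_m^{\gamma_m} \, P_m(x_{true}),}
#' normalised to sum to one; `gamma_m` in `[0, 1)` is an exponential
#' forgetting factor (0: only the last step counts; near 1: long memory).
#' Weights are floored at 1e-12 before normalisation so no expert dies
#' permanently.
#'
#' @param weights Current weights (nonnegative, summing to 1).
#' @param gammas Per-model forgetting factors in `[0, 1)`.
#' @param p_true Per-model probability assigned to the realised symbol.
#' @return The updated, normalised weights.
#' @examples
#' update_mix_weights(c(.9, .1), c(.5, .5), c(.5, .5))  # 0.75 0.25
#' @export
update_mix_weights <- function(weights, gammas, p_true) {
  if (length(weights) != length(gammas) || length(weights) != length(p_true)) {
    stop("weights, gammas and p_true must have equal length", call. = FALSE)
  }
  cpp_mix_update(as.numeric(weights), as.numeric(gammas), as.numeric(p_true))
}
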