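#' Assemble a full codec configuration
#'
#' A configuration is any number of context models (each optionally carrying
#' a substitution-tolerant model) plus any number of repeat-model groups --
#' at least one model in total -- and the order of the competitive prediction
#' context model that arbitrates between the two classes. All real-valued
#' parameters are held as integer rationals/permille so the container header
#' is platform-exact.
#'
#' @param cms List of [cm_config()] objects (may be empty).
#' @param rms List of [repeat_config()] objects (may be empty).
#' @param cpcm_order Context order of the class selector (winner bits).
#' @param cpcm_alpha Its estimator parameter.
#' @return A `codec_config` object.
#' @seealso [level_preset()] for ready-made configurations.
#' @export
codec_config <- function(cms = list(), rms = list(), cpcm_order = 8,
                         cpcm_alpha = 1) {
  if (inherits(cms, "cm_config")) cms <- list(cms)
  if (inherits(rms, "repeat_config")) rms <- list(rms)
  if (!all(vapply(cms, inherits, TRUE, "cm_config"))) {
    stop("cms must be a list of cm_config objects", call. = FALSE)
  }
  if (!all(vapply(rms, inherits, TRUE, "repeat_config"))) {
    stop("rms must be a list of repeat_config objects", call. = FALSE)
  }
  if (length(cms) + length(rms) == 0) {
    stop("at least one model is required", call. = FALSE)
  }
  a <- .as_rational(cpcm_alpha)
  structure(list(
    cms = lapply(cms, unclass),
    rms = lapply(rms, unclass),
    cpcm_k = as.integer(cpcm_order),
    cpcm_alpha_num = a[["num"]], cpcm_alpha_den = a[["den"]]
  ), class = "codec_config")
}

# per-order defaults: deeper models forget more slowly and smooth less
.preset_gamma <- function(k) {
  if (k <= 2) 0.60
  else if (k <= 5) 0.80
  else if (k == 6) 0.80   # the empirically distinct order-6 band [0.75, 0.85]
  else if (k <= 9) 0.90
  else if (k <= 12) 0.94
  else 0.95
}
.preset_alpha <- function(k) {
  if (k <= 5) c(1, 1)
  else if (k <= 9) c(1, 4)
  else if (k <= 12) c(1, 16)
  else if (k <= 15) c(1, 32)
  else c(1, 64)
}

# context-model orders per level; order 6 present from level 3 up
.preset_cm_orders <- list(
  c(1, 3),
  c(1, 3, 5),
  c(1, 4, 6),
  c(1, 4, 6, 9),
  c(1, 4, 6, 9, 11),
  c(1, 4, 6, 9, 11, 12),
  c(1, 4, 6, 9, 11, 13),
  c(1, 4, 6, 9, 11, 13, 14),
  c(1, 4, 6, 9, 11, 13, 14),
  c(1, 4, 6, 9, 11, 13, 14, 15),
  c(1, 4, 6, 9, 11, 13, 14, 16),
  c(1, 4, 6, 9, 11, 12, 13, 14, 16),
  c(1, 4, 6, 9, 11, 12, 13, 14, 16, 17),
  c(1, 2, 4, 6, 9, 11, 12, 13, 14, 16, 18),
  c(1, 2, 4, 6, 9, 11, 12, 13, 14, 15, 16, 18, 20)
)
.preset_cpcm_order <- c(4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 16, 16, 16, 16)
.preset_hash_bits <- c(15, 15, 15, 15, 16, 16, 16, 17, 17, 18, 18, 18, 18, 18, 18)
.preset_rpn <- c(8, 16, 16, 16, 24, 32, 32, 32, 32, 32, 32, 32, 32, 32, 32)
# repeat-model k-mer sizes per level (extra groups catch longer-range copies)
.preset_rm_orders <- list(
  11, 11, 11, 12, 12, 12, 12,
  c(12, 16), c(12, 16), c(12, 16), c(12, 16),
  c(12, 16, 20), c(12, 16, 20), c(12, 16, 20), c(12, 16, 20)
)

#' Preset codec configurations, levels 1 to 15
#'
#' Ready-made running modes trading resources for compression: model count,
#' maximum context order, cache sizes, simultaneous repeat instances and the
#' class-selector order all grow (weakly) with the level. Low levels suit
#' short sequences, high levels large genomes. From level 3 up every preset
#' contains an order-6 context model with forgetting factor 0.80 (order 6
#' behaves best in the 0.75-0.85 band, plausibly reflecting DNA period
#' multiplicity), and from level 5 up the deepest context model carries a
#' substitution-tolerant companion (the two deepest from level 9 up). The
#' selector order rises from 4 to 16; e.g. level 2 uses order 5 and level 12
#' order 16, matching the observation that longer sequences want a higher
#' selector order.
#'
#' @param level Integer 1..15.
#' @return A [codec_config()].
#' @export
level_preset <- function(level) {
  level <- as.integer(level)
  if (length(level) != 1 || is.na(level) || level < 1 || level > 15) {
    stop("level must be an integer in 1..15", call. = FALSE)
  }
  ks <- .preset_cm_orders[[level]]
  deepest <- sort(ks, decreasing = TRUE)
  stcm_ks <- if (level >= 9) deepest[1:2] else if (level >= 5) deepest[1] else integer()
  cms <- lapply(ks, function(k) {
    a <- .preset_alpha(k)
    cm_config(
      k = k, alpha = a, gamma = .preset_gamma(k),
      ir_mode = if (k >= 6) "both" else "forward",
      storage = if (k <= 11) "table" else "cache_hash",
      hash_bits = .preset_hash_bits[level], max_collisions = 4,
      stcm = if (k %in% stcm_ks) stcm_config(max_subs = 5, t = 8, l = 32) else NULL
    )
  })
  rms <- lapply(.preset_rm_orders[[level]], function(kr) {
    repeat_config(k = kr, rpn = .preset_rpn[level], a_hit = 2, a_miss = 1,
                  deactivate_below = 0.5, gamma = 0.2, ir = TRUE,
                  max_positions = 16)
  })
  codec_config(cms = cms, rms = rms,
               cpcm_order = .preset_cpcm_order[level], cpcm_alpha = 1)
}

.as_config <- function(config, level) {
  if (is.null(config)) level_preset(level)
  else if (inherits(config, "codec_config")) config
  else stop("config must be a codec_config()", call. = FALSE)
}

#' Compress a DNA sequence
#'
#' Runs the per-base pipeline: both model classes predict, the competitive
#' prediction context model selects a class, the selected mixture is
#' quantized and the base range-coded; then every model is updated with the
#' true base. The output container carries a self-describing header (magic
#' `CPD1`, sequence length, generator seed, full integer-encoded model
#' configuration, CRC-checked) so [dna_decompress()] needs nothing else.
#'
#' @param x ACGT string or `packed_dna` (use [read_dna()] for files).
#' @param level Preset 1..15, used when `config` is NULL.
#' @param config Optional explicit [codec_config()].
#' @param seed Seed of the shared deterministic generator driving the
#'   stochastic repeat starts; stored in the header.
#' @param details Collect per-base instrumentation (coded bits, selected
#'   class, winner class, periodic model-state checksums)?
#' @param checkpoint_every Base interval of the state checksums.
#' @return Raw vector of class `cpdna_compressed` with attribute
#'   `header_bytes`; when `details = TRUE` also attribute `details`.
#' @examples
#' x <- gen_dna("tandem", unit_len = 50, copies = 40, seed = 7)
#' z <- dna_compress(x, level = 4)
#' identical(dna_decompress(z), x)
#' compression_report(z)$bps
#' @export
dna_compress <- function(x, level = 7, config = NULL, seed = 0,
                         details = FALSE, checkpoint_every = 10000) {
  cfg <- .as_config(config, level)
  p <- pack_dna(x)
  if (p$length < 1) stop("cannot compress an empty sequence", call. = FALSE)
  res <- cpp_compress(unclass(cfg), p$data, p$length, as.numeric(seed),
                      isTRUE(details), as.integer(checkpoint_every))
  out <- res$stream
  attr(out, "header_bytes") <- res$header_bytes
  if (isTRUE(details)) attr(out, "details") <- res$details
  class(out) <- c("cpdna_compressed", "raw")
  out
}

#' Decompress a container back to the original sequence
#'
#' Symmetric inverse of [dna_compress()]: the decoder rebuilds the identical
#' model pipeline from the header (including the generator seed for the
#' stochastic repeat starts) and reproduces the ACGT stream exactly.
#'
#' @param stream Raw vector produced by [dna_compress()].
#' @param as Return type: `"character"` or `"packed"`.
#' @inheritParams dna_compress
#' @return The decoded sequence; with `details = TRUE` the instrumentation is
#'   attached as attribute `details`.
#' @export
dna_decompress <- function(stream, as = c("character", "packed"),
                           details = FALSE, checkpoint_every = 10000) {
  as <- match.arg(as)
  res <- cpp_decompress(as.raw(stream), isTRUE(details),
                        as.integer(checkpoint_every))
  out <- if (as == "packed") {
    structure(list(data = res$data, length = res$length), class = "packed_dna")
  } else {
    cpp_unpack(res$data, res$length)
  }
  if (isTRUE(details)) attr(out, "details") <- res$details
  out
}

#' Parse a container header
#'
#' @param stream Raw vector produced by [dna_compress()].
#' @return List with the sequence length, seed, full model configuration and
#'   header size in bytes. Errors on bad magic, version or checksum.
#' @export
parse_container_header <- function(stream) cpp_parse_header(as.raw(stream))

#' Summarise a compressed container
#'
#' Re-runs the (deterministic) decoder with instrumentation and reports
#' compression metrics. BPS is bits per symbol: `8 * payload_bytes / length`,
#' header excluded.
#'
#' @param stream Raw vector produced by [dna_compress()].
#' @return List: `length`, `bytes` (total), `payload_bytes`, `bps`,
#'   `class_use` (fraction of bases coded by each class),
#'   `win_rate` (fraction each class actually predicted best) and
#'   `mean_coded_bits` (mean ideal codelength of the coded distributions).
#' @export
compression_report <- function(stream) {
  hdr <- parse_container_header(stream)
  dec <- dna_decompress(stream, as = "packed", details = TRUE)
  det <- attr(dec, "details")
  payload <- length(stream) - hdr$header_bytes
  sel <- tabulate(det$selected + 1L, nbins = 2L) / hdr$length
  win <- tabulate(det$winner + 1L, nbins = 2L) / hdr$length
  list(
    length = hdr$length,
    bytes = length(stream),
    payload_bytes = payload,
    bps = 8 * payload / hdr$length,
    class_use = c(context_models = sel[1], repeat_models = sel[2]),
    win_rate = c(context_models = win[1], repeat_models = win[2]),
    mean_coded_bits = mean(det$bits)
  )
}

#' Ablation helpers: strip a feature from a configuration
#'
#' Convenience editors used to quantify what each component buys:
#' `config_without_repeats()` drops every repeat-model group,
#' `config_without_stcm()` detaches every substitution-tolerant model and
#' `config_without_ir()` disables the inverted-repeat sub-programs in both
#' classes (context models fall back to forward-only; repeat groups stop
#' spawning inverted-repeat instances).
#'
#' @param config A [codec_config()].
#' @return The edited `codec_config`.
#' @export
config_without_repeats <- function(config) {
  stopifnot(inherits(config, "codec_config"))
  config$rms <- list()
  if (length(config$cms) == 0) stop("config would have no models", call. = FALSE)
  config
}

#' @rdname config_without_repeats
#' @export
config_without_stcm <- function(config) {
  stopifnot(inherits(config, "codec_config"))
  config$cms <- lapply(config$cms, function(m) { m$stcm <- NULL; m })
  config
}

#' @rdname config_without_repeats
#' @export
config_without_ir <- function(config) {
  stopifnot(inherits(config, "codec_config"))
  config$cms <- lapply(config$cms, function(m) { m$ir_mode <- 0L; m })
  config$rms <- lapply(config$rms, function(m) { m$ir <- FALSE; m })
  config
}
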