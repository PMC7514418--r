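# Independent R reference implementations used as oracles. These recount
# and recompute everything directly from definitions (strings, environments,
# O(n * k) per step) and share no code with the package internals.

BASES <- c("A", "C", "G", "T")

o_rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

o_codes <- function(s) match(strsplit(s, "")[[1]], BASES) - 1L

o_estimator <- function(counts, alpha) (counts + alpha) / (sum(counts) + 4 * alpha)

# largest-remainder quantization to total 2^16, min 1, ties by symbol order
o_quantize <- function(p) {
  s <- p * 65536
  f <- floor(s)
  rem <- s - f
  give <- 65536 - sum(f)
  ord <- order(-rem, seq_along(rem))
  i <- 0
  while (give > 0) { j <- ord[(i %% 4) + 1]; f[j] <- f[j] + 1; i <- i + 1; give <- give - 1 }
  while (give < 0) { j <- which.max(f); f[j] <- f[j] - 1; give <- give + 1 }
  for (j in 1:4) if (f[j] == 0) { big <- which.max(f); f[big] <- f[big] - 1; f[j] <- 1 }
  as.integer(f)
}

o_mix_update <- function(w, gamma, p_true) {
  v <- pmax(w^gamma * p_true, 1e-12)
  v / sum(v)
}

# --- brute-force single context model (all ir modes), counts in an env -----

o_cm_scan <- function(seq, k, alpha, ir_mode = "forward", counter_max = 255) {
  sym <- o_codes(seq)
  n <- length(sym)
  counts <- new.env(parent = emptyenv())
  getc <- function(ctx) {
    v <- counts[[ctx]]
    if (is.null(v)) numeric(4) else v
  }
  bump <- function(ctx, s) {
    v <- getc(ctx)
    if (v[s + 1] + 1 > counter_max) v <- v %/% 2
    v[s + 1] <- v[s + 1] + 1
    counts[[ctx]] <- v
  }
  padded <- c(rep(0L, k), sym) # zero ('A') padding at the start
  out <- matrix(0, n, 4)
  for (i in seq_len(n) - 1L) {
    fctx <- paste(BASES[padded[(i + 1):(i + k)] + 1], collapse = "")
    if (ir_mode == "ir_only") {
      if (i < k) {
        out[i + 1, ] <- rep(0.25, 4)
      } else {
        sc <- numeric(4)
        prev <- sym[i - k + 1] # x_{i-k} (sym is 1-based over 0-based positions)
        mid <- if (k > 1) sym[(i - k + 2):i] else integer(0) # x_{i-k+1..i-1}
        for (s in 0:3) {
          win <- paste(c(BASES[mid + 1], BASES[s + 1]), collapse = "")
          qctx <- o_rc(win)
          sc[s + 1] <- getc(qctx)[(3 - prev) + 1]
        }
        out[i + 1, ] <- (sc + alpha) / (sum(sc) + 4 * alpha)
      }
    } else {
      out[i + 1, ] <- o_estimator(getc(fctx), alpha)
    }
    # update: forward event always; IR event for ir-capable modes once real
    bump(fctx, sym[i + 1])
    if (ir_mode != "forward" && i >= k) {
      win <- paste(BASES[sym[(i - k + 1):(i + 1)] + 1], collapse = "") # x_{i-k..i}
      irctx <- o_rc(substr(win, 2, k + 1))
      irsym <- 3 - sym[i - k + 1]
      bump(irctx, irsym)
    }
  }
  out
}

# --- brute-force CM-class mixture (forward-only experts, no STCM) ----------

o_cm_class_scan <- function(seq, ks, alphas, gammas) {
  sym <- o_codes(seq)
  n <- length(sym)
  M <- length(ks)
  counts <- lapply(seq_len(M), function(i) new.env(parent = emptyenv()))
  getc <- function(m, ctx) {
    v <- counts[[m]][[ctx]]
    if (is.null(v)) numeric(4) else v
  }
  w <- rep(1 / M, M)
  padded <- c(rep(0L, max(ks)), sym)
  off <- max(ks)
  mixed <- matrix(0, n, 4)
  for (i in seq_len(n) - 1L) {
    dists <- matrix(0, M, 4)
    for (m in seq_len(M)) {
      k <- ks[m]
      ctx <- paste(BASES[padded[(off + i - k + 1):(off + i)] + 1], collapse = "")
      dists[m, ] <- o_estimator(getc(m, ctx), alphas[m])
    }
    mixed[i + 1, ] <- colSums(dists * w)
    w <- o_mix_update(w, gammas, dists[, sym[i + 1] + 1])
    for (m in seq_len(M)) {
      k <- ks[m]
      ctx <- paste(BASES[padded[(off + i - k + 1):(off + i)] + 1], collapse = "")
      v <- getc(m, ctx)
      v[sym[i + 1] + 1] <- v[sym[i + 1] + 1] + 1
      counts[[m]][[ctx]] <- v
    }
  }
  list(mixed = mixed, weights = w)
}

# deterministic local RNG so fixtures in tests do not disturb global state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
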