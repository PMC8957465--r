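# Internal helpers shared across the pipeline.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic per-stage seed derived from a master seed and a label, so any
# single stage (or single joint) can be replayed in isolation. Plain 31-bit
# multiplicative hash; no cryptographic intent.
derive_seed <- function(master, label) {
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Replicate-pad a matrix by `r` rows/columns on every side.
pad_replicate <- function(m, r) {
  if (r < 1) return(m)
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
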