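# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is restored afterwards so package functions never
# perturb user-level randomness. `seed = NULL` uses the current stream.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Mixed-radix index of parent configurations: column j of `x` holds 1-based
# state indices of the j-th parent (cards[j] states); the first parent
# varies fastest, matching expand.grid() and the CPT row layout.
config_index <- function(x, cards) {
  if (length(cards) == 0L) return(rep(1L, NROW(x)))
  x <- as.matrix(x)
  idx <- rep(1, nrow(x))
  stride <- 1
  for (j in seq_along(cards)) {
    idx <- idx + (x[, j] - 1) * stride
    stride <- stride * cards[j]
  }
  as.integer(idx)
}

# expand.grid over state indices, first variable fastest.
config_grid <- function(cards) {
  as.matrix(expand.grid(lapply(cards, seq_len), KEEP.OUT.ATTRS = FALSE))
}

log2_sum_exp2 <- function(l) {
  m <- max(l)
  if (!is.finite(m)) return(m)
  m + log2(sum(2^(l - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
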