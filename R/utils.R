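# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, restoring the
# caller's RNG state afterwards. All user-facing stochastic operations funnel
# through this so identical seed + config => bit-identical output.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive a reproducible substream seed from a parent seed and an integer salt,
# kept inside the 32-bit signed range.
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) * 48271 + salt * 7919) %% 2147483647L)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

# Shannon entropy (base 2) of a probability vector, with 0 * log 0 = 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
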