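# Internal helpers: seeded RNG scoping and small utilities.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards. Keeps every exported
# stochastic operation deterministic without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from (seed, k) staying inside 32-bit integer range.
# Park-Miller style multiplicative step; good enough to decorrelate streams.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483646) + 1
  k <- as.double(k) %% 2147483646
  as.integer(((s * 48271 + k * 16807) %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# IQR-style quartiles with the conventional type-7 interpolation.
quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE, type = 7)
}
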