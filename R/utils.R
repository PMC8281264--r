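# shared internal helpers

# Run expr with a local RNG stream so simulators are reproducible without
# clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Hann taper of length n (periodic form used for spectral estimation).
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

# Tukey (tapered-cosine) window: flat over the central 1-alpha fraction,
# raised-cosine over alpha/2 at each edge. alpha = 1 gives Hann, 0 gives
# rectangular.
tukey_window <- function(n, alpha = 0.25) {
  if (alpha <= 0) return(rep(1, n))
  if (alpha >= 1) return(hann_window(n))
  t <- (seq_len(n) - 1L) / (n - 1L)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

# Evaluate polynomial with coefficients c(b0, b1, b2, ...) at x.
polyval_asc <- function(coefs, x) {
  out <- numeric(length(x))
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^(k - 1L)
  out
}

# Half-open interval overlap length: [a1, a2) vs [b1, b2).
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
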