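# Internal numeric helpers shared across modules.

# Round half away from zero (base round() rounds half to even, which would
# make gene arithmetic like round(10.5) depend on parity).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log of probabilities, mapping 0 -> -Inf without warnings
safe_log <- function(p) {
  out <- rep(-Inf, length(p))
  pos <- p > 0
  out[pos] <- log(p[pos])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
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
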