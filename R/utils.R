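# Seed handling: every stochastic operation takes an explicit seed and
# restores the caller's RNG state afterwards, so pipeline stages cannot
# perturb one another.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Named sub-streams derived from one master seed; keeps independent stages
# on independent (and individually reproducible) streams. Kept below 2^31.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629) + 1L
}

# Largest-remainder rounding: integer vector with sum == total,
# proportional to w.
allocate_integer <- function(w, total) {
  if (total == 0 || sum(w) == 0) return(integer(length(w)))
  raw <- w / sum(w) * total
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out)
}

vec_pairs <- function(m) m[lower.tri(m)]
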