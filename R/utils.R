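# internal helpers shared across modules

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific seed from a master seed; keeps results independent
# across stages while funnelling all randomness through one user-facing seed.
# Stays below 2^31 - 1.
deriveSeed <- function(seed, stage) {
  h <- digest::digest(list(as.integer(seed), as.character(stage)), algo = "crc32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483647L)
}

stopifnotScalarCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(name, " must be a single integer >= ", min, call. = FALSE)
}

# largest-remainder apportionment of n into parts proportional to fractions;
# earlier parts win remainder ties, so part 1 receives ceiling(frac1 * n)
# in the two-part case.
apportion <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, seq_along(raw), decreasing = c(TRUE, FALSE),
                 method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# zero-length-safe id generation (paste0 recycles length-0 to one element)
idSeq <- function(prefix, n) {
  if (n > 0) paste0(prefix, seq_len(n)) else character(0)
}
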