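# Run expr under a temporary RNG seed, restoring global RNG state afterwards.
# Keeps all package randomness off the user's random stream.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-spectrum seed from (master seed, level index, replicate).
# Values stay in [1, 2^31 - 2] so they remain valid 32-bit R integers.
deriveSeed <- function(master, levelIndex, replicate) {
  m <- 2147483629
  s <- (as.double(master) %% m)
  s <- (s * 48271 + as.double(levelIndex) * 69621 +
        as.double(replicate) * 16807) %% m
  as.integer(s + 1)
}
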