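# Internal RNG helpers.
#
# All stochastic operations take an explicit integer seed and run inside
# with_seed(), which restores the caller's RNG state afterwards, so package
# functions never perturb the global random stream.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based derivation of per-sample / per-stage seeds from a master
# seed, so any one sample can be regenerated in isolation. Kept below 2^31.
derive_seed <- function(seed, index) {
  v <- ((as.numeric(seed) %% 100000) * 69069 + as.numeric(index) * 7919 +
          12345) %% 2147483647
  as.integer(v) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
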