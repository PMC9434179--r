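# Seed plumbing: evaluate code under a temporary seed, restoring the caller's
# RNG state afterwards, and derive reproducible per-replicate seeds from a
# master seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  code
}

# k replicate seeds, a deterministic function of the master seed alone
# (independent of draw order elsewhere), each below 2^31.
derive_seeds <- function(master_seed, k) {
  with_seed(as.integer(master_seed),
            sample.int(.Machine$integer.max - 1L, k, replace = TRUE))
}
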