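# Small parameter sets used across tests.

tiny_params <- function(...) {
  sim_params(N = 200, G = 20, mu = 1e-3, n = 5, sample_size = 5, ...)
}

# A final-state count vector for given class counts, remainder in RES.
state_with <- function(params, ...) {
  counts <- stats::setNames(integer(params$n + 3L), genotype_labels(params))
  given <- c(...)
  counts[names(given)] <- given
  counts[["RES"]] <- params$N - sum(given)
  stopifnot(counts[["RES"]] >= 0L)
  counts
}
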