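#' Simulation parameters for the post-sweep reversion/compensation model
#'
#' Bundles every constant needed for one simulated population: the population
#' follows `N` haploid cells for `G` discrete generations after a costly
#' resistance mutation has fixed and the environment has reverted, so that the
#' resistance now carries cost `c`. Reversal to wild type and each of `n`
#' compensatory mutations occur at the per-cell per-generation rate `mu`; an
#' ordinary compensatory mutation removes a proportion `p` of the cost, while
#' the first `m` compensatory targets are fully compensating (fitness equal to
#' wild type while retaining resistance).
#'
#' @param N Positive integer; census (= effective) population size.
#' @param G Positive integer; generations simulated after fixation of the
#'   resistant allele.
#' @param mu Per-site per-generation mutation rate, one rate shared by the
#'   reversal target and each compensatory target. Must satisfy
#'   `(n + 1) * mu <= 1` so the per-cell mutation probabilities are valid.
#' @param c Fitness cost of the resistance mutation in the original
#'   environment; strictly between 0 and 1.
#' @param p Proportion of the cost removed by an ordinary compensatory
#'   mutation, in `[0, 1]`.
#' @param n Non-negative integer; number of distinct compensatory mutational
#'   targets.
#' @param m Non-negative integer `<= n`; how many of the `n` targets are fully
#'   compensating. The fully compensating targets are canonically indices
#'   `1..m`.
#' @param allow_second_mutation Logical; may compensated cells acquire a
#'   subsequent reversal mutation (becoming compensated-reverted, "CR")?
#' @param presence_threshold Positive integer; minimum final count for a
#'   genotype class (or class group) to be called "present". The default 10 is
#'   0.1% of the default `N`.
#' @param sample_size Positive integer; clones sampled per replicate for
#'   experiment-style output.
#' @param seed Optional integer RNG seed for a single replicate; `NULL` uses
#'   the current RNG state.
#'
#' @return A validated object of class `"sim_params"` (a named list).
#' @seealso [validate_params()], [build_fitness()], [run_replicate()],
#'   [params_for_supply()]
#' @examples
#' sim_params()                      # the default parameterization
#' sim_params(mu = 1e-3, m = 3)      # high mutation supply, 3 full compensators
#' @export
sim_params <- function(N = 10000, G = 100, mu = 1e-5, c = 0.15, p = 0.5,
                       n = 100, m = 0, allow_second_mutation = TRUE,
                       presence_threshold = 10, sample_size = 10,
                       seed = NULL) {
  params <- structure(
    list(
      N = as.integer(N),
      G = as.integer(G),
      mu = as.numeric(mu),
      c = as.numeric(c),
      p = as.numeric(p),
      n = as.integer(n),
      m = as.integer(m),
      allow_second_mutation = isTRUE(allow_second_mutation),
      presence_threshold = as.integer(presence_threshold),
      sample_size = as.integer(sample_size),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "sim_params"
  )
  validate_params(params)
}

#' Validate a parameter set
#'
#' Checks every invariant of a [sim_params()] object and returns it unchanged
#' if all hold. In particular the total per-cell mutation probability
#' `(n + 1) * mu` must not exceed 1 (a resistant cell has `n + 1` mutational
#' destinations each at rate `mu`).
#'
#' @param params A `"sim_params"` object, or a bare named list with the same
#'   fields.
#' @return The validated `"sim_params"` object.
#' @export
validate_params <- function(params) {
  if (!inherits(params, "sim_params")) {
    if (!is.list(params)) stop("`params` must be a sim_params object")
    params <- do.call(sim_params, params[!vapply(params, is.null, logical(1))])
    return(params)
  }
  with(params, {
    if (is.na(N) || N < 1L) stop("`N` must be a positive integer")
    if (is.na(G) || G < 1L) stop("`G` must be a positive integer")
    if (is.na(mu) || mu < 0) stop("`mu` must be non-negative")
    if (is.na(c) || c <= 0 || c >= 1) stop("`c` must lie strictly in (0, 1)")
    if (is.na(p) || p < 0 || p > 1) stop("`p` must lie in [0, 1]")
    if (is.na(n) || n < 0L) stop("`n` must be a non-negative integer")
    if (is.na(m) || m < 0L || m > n) stop("`m` must satisfy 0 <= m <= n")
    if ((n + 1) * mu > 1 + 1e-12) {
      stop(sprintf(
        "total per-cell mutation probability (n + 1) * mu = %g exceeds 1",
        (n + 1) * mu
      ))
    }
    if (is.na(presence_threshold) || presence_threshold < 1L ||
        presence_threshold > N) {
      stop("`presence_threshold` must lie in 1..N")
    }
    if (is.na(sample_size) || sample_size < 1L || sample_size > N) {
      stop("`sample_size` must lie in 1..N")
    }
  })
  params
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Post-sweep reversion/compensation parameters\n",
      "  N = %d cells, G = %d generations, mu = %g  (N*mu = %g)\n",
      "  cost c = %g, compensatory effect p = %g\n",
      "  n = %d compensatory targets (%d fully compensating)\n",
      "  second (Com -> CR) mutations %s; presence threshold %d cells;",
      " sample size %d\n"
    ),
    x$N, x$G, x$mu, x$N * x$mu, x$c, x$p, x$n, x$m,
    if (x$allow_second_mutation) "allowed" else "disabled",
    x$presence_threshold, x$sample_size
  ))
  invisible(x)
}

#' Genotype class labels
#'
#' The model tracks `n + 3` genotype classes in a fixed order: `RES` (the
#' resistant, uncompensated starting genotype), `COM1..COMn` (resistant plus
#' one compensatory mutation; targets `1..m` are the fully compensating ones),
#' `WT` (reverted wild type), and `CR` (compensated reversal: a compensatory
#' mutation plus a subsequent reversal).
#'
#' @param params A [sim_params()] object.
#' @return Character vector of length `n + 3`.
#' @export
genotype_labels <- function(params) {
  c("RES",
    if (params$n > 0L) paste0("COM", seq_len(params$n)),
    "WT", "CR")
}

# Fixed index layout shared by every kernel: 1 = RES, 2..(n+1) = COM1..COMn,
# n+2 = WT, n+3 = CR.
class_indices <- function(params) {
  n <- params$n
  list(
    res = 1L,
    com = if (n > 0L) 2L:(n + 1L) else integer(0),
    com_full = if (params$m > 0L) 1L + seq_len(params$m) else integer(0),
    com_partial = if (n > params$m) (2L + params$m):(n + 1L) else integer(0),
    wt = n + 2L,
    cr = n + 3L
  )
}

#' Map genotype labels to class groups
#'
#' Collapses the per-target compensatory labels (`COM1`, `COM2`, ...) into the
#' single group `COM`, leaving `RES`, `WT`, and `CR` unchanged.
#'
#' @param labels Character vector of genotype labels.
#' @return Factor with levels `RES`, `COM`, `WT`, `CR`.
#' @export
class_group <- function(labels) {
  factor(sub("^COM[0-9]+$", "COM", labels),
         levels = c("RES", "COM", "WT", "CR"))
}

#' Is a genotype label a fully compensating mutant?
#'
#' Under the canonical indexing the fully compensating compensatory targets
#' are `COM1..COMm`.
#'
#' @param labels Character vector of genotype labels.
#' @param params A [sim_params()] object (supplies `m`).
#' @return Logical vector: `TRUE` for `COMi` with `i <= m`, else `FALSE`.
#' @export
is_fully_compensating <- function(labels, params) {
  i <- suppressWarnings(as.integer(sub("^COM", "", labels)))
  !is.na(i) & grepl("^COM[0-9]+$", labels) & i <= params$m
}

#' Parameters realizing a target mutation supply
#'
#' The composite that controls the dynamics is the mutation supply
#' `N * mu` (expected new mutations per target per generation). This helper
#' builds a parameter set for a requested supply at a given population size.
#' If the implied `mu` would exceed `mu_max` (by default `1e-3`, above which
#' `(n + 1) * mu` approaches 1 for the default `n = 100`), the population size
#' is raised instead, holding the supply fixed: a supply of 100 at the default
#' settings is realized as `N = 100,000`, `mu = 1e-3`.
#'
#' @param Nmu Target mutation supply `N * mu`.
#' @param N Preferred population size.
#' @param mu_max Largest admissible per-site mutation rate (must be passed by
#'   full name).
#' @param ... Further arguments passed to [sim_params()].
#' @return A `"sim_params"` object with `N * mu == Nmu`.
#' @export
params_for_supply <- function(Nmu, N = 10000, ..., mu_max = 1e-3) {
  stopifnot(Nmu > 0, mu_max > 0)
  mu <- Nmu / N
  if (mu > mu_max) {
    N <- ceiling(Nmu / mu_max)
    mu <- Nmu / N
  }
  sim_params(N = N, mu = mu, ...)
}

# Replace fields of a sim_params and re-validate. The first formal is
# dot-prefixed so that field names passed by callers (p, n, m, ...) can never
# partially match it.
update_params <- function(.params, ...) {
  new <- list(...)
  new <- new[!vapply(new, is.null, logical(1))]
  fields <- unclass(.params)
  fields[names(new)] <- new
  do.call(sim_params, fields[!vapply(fields, is.null, logical(1))])
}
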