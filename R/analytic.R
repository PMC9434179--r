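#' Deterministic haploid selection trajectory
#'
#' Iterates the deterministic Wright-Fisher recursion for an invader at
#' frequency `x` against a resident:
#' `x' = x * w_i / (x * w_i + (1 - x) * w_r)`.
#' Used for the illustrative pre-fixation rise of the resistant allele and as
#' the deterministic compensatory sweep inside
#' [p_reversal_before_fixation()].
#'
#' @param w_invader,w_resident Positive relative fitnesses.
#' @param x0 Initial invader frequency, strictly inside (0, 1).
#' @param G Number of generations to iterate.
#' @return Numeric vector of length `G + 1`: frequencies at generations
#'   `0..G`.
#' @examples
#' deterministic_sweep(1, 0.85, 0.5, 1)[2]  # 0.5405405...
#' @export
deterministic_sweep <- function(w_invader, w_resident, x0, G) {
  stopifnot(w_invader > 0, w_resident > 0, x0 > 0, x0 < 1, G >= 0)
  x <- numeric(G + 1)
  x[1] <- x0
  for (t in seq_len(G)) {
    xi <- x[t]
    x[t + 1] <- xi * w_invader / (xi * w_invader + (1 - xi) * w_resident)
  }
  x
}

#' Fixation probability of a new mutant (diffusion approximation)
#'
#' Kimura's diffusion result for a haploid Wright-Fisher population:
#' `(1 - exp(-2s)) / (1 - exp(-2Ns))`, continuous at `s = 0` where it equals
#' the neutral value `1/N`. For the selection coefficients used here
#' (`s <= ~0.2`) it is close to, but better behaved than, the classic `2s`
#' branching-process approximation.
#'
#' @param s Selection coefficient(s) of the mutant relative to the resident
#'   population (vectorized).
#' @param N Population size.
#' @return Fixation probabilities in `[0, 1]`.
#' @examples
#' fixation_probability(0, 100)        # 1/N = 0.01
#' fixation_probability(0.15, 10000)   # ~ 1 - exp(-0.3) = 0.259
#' @export
fixation_probability <- function(s, N) {
  stopifnot(N >= 1)
  out <- ifelse(
    abs(s) < 1e-12,
    1 / N,
    (1 - exp(-2 * s)) / (1 - exp(-2 * N * s))
  )
  pmin(pmax(out, 0), 1)
}

#' Probability that a reversal establishes before compensation fixes
#'
#' The simplified analytic counterpart of the simulated race between a rare
#' wild-type reversal mutation and the (common) compensatory mutations, in the
#' setting where compensated cells cannot revert (`m = 0`, second mutations
#' off). The approximation rests on two assumptions: at any time only the
#' compensatory class is sweeping, and a new reversal's fate is decided by its
#' selection coefficient in the generation it arises.
#'
#' The construction:
#' \enumerate{
#'   \item The pooled compensatory class is treated deterministically as the
#'     infinite-population limit of the simulator's own two-class dynamics:
#'     starting from frequency 0 it receives a mutational inflow of
#'     `n * mu * x_res(t)` per generation and is advanced by the
#'     deterministic selection recursion (fitness `1 - c(1-p)` against
#'     `1 - c`). Driving the class by its ongoing inflow, rather than by a
#'     one-off seed, matters: compensatory mutations keep arising every
#'     generation, and their cumulative supply is what sets the speed of the
#'     compensatory sweep.
#'   \item Compensation is deemed fixed at the first generation `t_fix_com`
#'     where the residual resistant frequency drops below
#'     `presence_threshold / N`, mirroring the simulator's presence rule.
#'   \item In each generation `t < t_fix_com` the hazard of a successful
#'     reversal is `h_t = N * x_res(t) * mu * fixation_probability(s_t, N)`
#'     with `s_t = 1/wbar_t - 1`, the advantage of the wild type over the
#'     mean fitness `wbar_t` in the generation the mutation arises.
#'   \item `p_wt_wins = 1 - exp(-sum(h_t))`.
#' }
#'
#' As expected of this class of approximation, it tracks simulation closely at
#' low mutation supply and overestimates at high supply, where clonal
#' interference (other mutations sweeping at the same time) lowers the true
#' fixation probability below the value implied by the origin-generation
#' selection coefficient.
#'
#' @param params A [sim_params()] object with `m = 0` (the race setting).
#' @return A `"race_approximation"`: list with `p_wt_wins`, `t_fix_com`
#'   (generations), `hazard` (per-generation establishment rates up to
#'   `t_fix_com`), and `x_com` (the deterministic compensatory trajectory at
#'   generations `0..G`).
#' @export
p_reversal_before_fixation <- function(params) {
  params <- validate_params(params)
  if (params$m != 0L) {
    stop("the race approximation is defined for m = 0 (no fully compensating targets)")
  }
  N <- params$N
  mu <- params$mu
  G <- params$G
  w_res <- 1 - params$c
  w_com <- 1 - params$c * (1 - params$p)
  inflow <- params$n * mu

  x_com <- numeric(G + 1)  # generations 0..G, x_com[1] = 0
  for (t in seq_len(G)) {
    x <- x_com[t]
    x_sel <- if (x > 0) x * w_com / (x * w_com + (1 - x) * w_res) else 0
    x_com[t + 1] <- min(x_sel + (1 - x_sel) * inflow, 1)
  }
  x_res <- 1 - x_com
  fixed <- which(x_res < params$presence_threshold / N)
  t_fix <- if (length(fixed)) fixed[1L] - 1L else G

  hazard <- numeric(0)
  p <- 0
  if (mu > 0 && t_fix > 0L) {
    gens <- seq_len(t_fix)  # generations 0 .. t_fix - 1
    wbar <- x_res[gens] * w_res + x_com[gens] * w_com
    s_t <- 1 / wbar - 1
    hazard <- N * x_res[gens] * mu * fixation_probability(s_t, N)
    p <- 1 - exp(-sum(hazard))
  }
  structure(
    list(p_wt_wins = p, t_fix_com = as.integer(t_fix), hazard = hazard,
         x_com = x_com, params = params),
    class = "race_approximation"
  )
}

#' @export
print.race_approximation <- function(x, ...) {
  cat(sprintf(
    "reversal-vs-compensation race: P(reversal wins) = %.4f (compensation fixes at generation %d)\n",
    x$p_wt_wins, x$t_fix_com
  ))
  invisible(x)
}

#' Analytic race curve over a mutation-rate grid
#'
#' Evaluates [p_reversal_before_fixation()] over a grid of mutation rates,
#' producing the analytic overlay for simulated race experiments.
#'
#' @param mu Vector of mutation rates.
#' @param N,c,p,n,G,presence_threshold Model constants (see [sim_params()]).
#' @return Data frame with columns `mu`, `Nmu`, `p_wt_analytic`,
#'   `t_fix_com`.
#' @export
reversal_race_curve <- function(mu, N = 10000, c = 0.15, p = 0.5, n = 100,
                                G = 500, presence_threshold = 10) {
  rows <- lapply(mu, function(m) {
    res <- p_reversal_before_fixation(sim_params(
      N = N, G = G, mu = m, c = c, p = p, n = n, m = 0,
      allow_second_mutation = FALSE,
      presence_threshold = presence_threshold
    ))
    data.frame(mu = m, Nmu = N * m, p_wt_analytic = res$p_wt_wins,
               t_fix_com = res$t_fix_com)
  })
  do.call(rbind, rows)
}

#' Long-run reversal share with fully compensating competitors
#'
#' When `m` fully compensating mutations (fitness 1, mutation rate `mu` each)
#' compete with the reversal mutation (also fitness 1, rate `mu`) under high
#' mutation supply, all `m + 1` lineages establish essentially immediately and
#' sweep together; by exchangeability each is expected to reach share
#' `1 / (m + 1)`. With `m = 3` the expected number of reverted clones in a
#' sample of 10 is therefore 2.5.
#'
#' @param m Number of fully compensating mutations (vectorized,
#'   non-negative).
#' @return Expected long-run population share of the reversal lineage,
#'   `1 / (m + 1)`.
#' @examples
#' expected_reversal_share(c(0, 1, 3))  # 1, 0.5, 0.25
#' @export
expected_reversal_share <- function(m) {
  stopifnot(all(m >= 0))
  1 / (m + 1)
}
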