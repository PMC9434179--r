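# Exact finite-state analysis of tiny instances. The population state is a
# composition of N into n + 3 class counts; the mutation kernel and the
# multinomial reproduction kernel are composed into one dense row-stochastic
# transition matrix which is then applied G times to the all-RES start.
# Tractable only for tiny N and n; used as an independent correctness oracle
# for the stochastic engine.

# All compositions of N into k non-negative parts, one per row
# (choose(N + k - 1, k - 1) rows).
compositions <- function(N, k) {
  if (k == 1L) {
    return(matrix(as.integer(N), 1L, 1L))
  }
  parts <- lapply(0:N, function(i) {
    cbind(as.integer(i), compositions(N - i, k - 1L))
  })
  do.call(rbind, parts)
}

# Exact post-mutation distribution from one state: a list with a matrix of
# reachable states (rows) and their probabilities. Matches mutate_step: the
# Com -> CR binomials act on the cells present at the start of the generation
# (at most one mutational step per cell), then the RES cells split over
# (stay, WT, COM1..COMn).
mutation_distribution <- function(counts, params) {
  n <- params$n
  mu <- params$mu
  k <- n + 3L
  states <- matrix(as.integer(counts), 1L, k)
  prob <- 1

  if (params$allow_second_mutation && mu > 0 && n > 0L) {
    # convolve each COM class with its binomial Com -> CR moves
    for (i in seq_len(n)) {
      col <- 1L + i
      ci <- counts[[col]]
      if (ci == 0L) next
      new_states <- vector("list", nrow(states))
      new_prob <- vector("list", nrow(states))
      for (s in seq_len(nrow(states))) {
        moved <- 0:ci
        block <- matrix(rep(states[s, ], each = ci + 1L), ci + 1L, k)
        block[, col] <- ci - moved
        block[, k] <- block[, k] + moved
        new_states[[s]] <- block
        new_prob[[s]] <- prob[s] * stats::dbinom(moved, ci, mu)
      }
      states <- do.call(rbind, new_states)
      prob <- unlist(new_prob)
      keep <- prob > 0
      states <- states[keep, , drop = FALSE]
      prob <- prob[keep]
    }
  }

  r <- counts[[1L]]
  if (mu > 0 && r > 0L) {
    # split RES cells over (stay, WT, COM1..COMn)
    split <- compositions(r, n + 2L)
    p <- c(1 - (n + 1) * mu, rep.int(mu, n + 1L))
    lp <- lgamma(r + 1) - rowSums(lgamma(split + 1))
    for (j in seq_len(ncol(split))) {
      if (p[j] > 0) {
        lp <- lp + split[, j] * log(p[j])
      } else {
        lp[split[, j] > 0L] <- -Inf
      }
    }
    split_prob <- exp(lp)
    keep <- split_prob > 0
    split <- split[keep, , drop = FALSE]
    split_prob <- split_prob[keep]
    new_states <- vector("list", nrow(states))
    new_prob <- vector("list", nrow(states))
    for (s in seq_len(nrow(states))) {
      block <- matrix(rep(states[s, ], each = nrow(split)), nrow(split), k)
      block[, 1L] <- split[, 1L]
      block[, n + 2L] <- block[, n + 2L] + split[, 2L]
      if (n > 0L) {
        block[, 2L:(n + 1L)] <- block[, 2L:(n + 1L), drop = FALSE] +
          split[, 3L:(n + 2L), drop = FALSE]
      }
      new_states[[s]] <- block
      new_prob[[s]] <- prob[s] * split_prob
    }
    states <- do.call(rbind, new_states)
    prob <- unlist(new_prob)
  }
  list(states = states, prob = prob)
}

state_keys <- function(S) apply(S, 1L, paste, collapse = ",")

#' Exact outcome distribution for tiny instances
#'
#' Computes, by dense transition-matrix composition, the exact probability
#' distribution over population states at generation `G` for the same model
#' the stochastic engine simulates: the mutation kernel of [mutate_step()]
#' composed with the multinomial reproduction kernel of
#' [selection_drift_step()], started from the all-`RES` state. Intended as an
#' independent test oracle; the state space (all compositions of `N` into
#' `n + 3` classes) must stay below `max_states`.
#'
#' @param params A [sim_params()] object (tiny `N` and `n`).
#' @param max_states Refuse instances with more states than this.
#' @return A `"wf_oracle"`: list with `states` (matrix, one composition per
#'   row), `prob` (probabilities at generation `G`), `labels`, and `params`.
#' @examples
#' o <- exact_small_oracle(sim_params(N = 4, G = 3, mu = 0.05, n = 1,
#'                                    sample_size = 1, presence_threshold = 1))
#' oracle_presence_probability(o, "WT", 1)
#' @export
exact_small_oracle <- function(params, max_states = 5000) {
  params <- validate_params(params)
  k <- params$n + 3L
  n_states <- choose(params$N + k - 1, k - 1)
  if (n_states > max_states) {
    stop(sprintf(
      "state space has %.0f compositions, above the cap of %d",
      n_states, max_states
    ))
  }
  S <- compositions(params$N, k)
  keys <- state_keys(S)
  index <- stats::setNames(seq_along(keys), keys)
  ns <- nrow(S)

  mut <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    md <- mutation_distribution(S[s, ], params)
    mut[s, index[state_keys(md$states)]] <- md$prob
  }

  w <- unname(build_fitness(params))
  lconst <- lgamma(params$N + 1) - rowSums(lgamma(S + 1))
  rep_k <- matrix(0, ns, ns)
  for (s in seq_len(ns)) {
    q <- S[s, ] * w
    q <- q / sum(q)
    lp <- lconst
    for (j in seq_len(k)) {
      if (q[j] > 0) {
        lp <- lp + S[, j] * log(q[j])
      } else {
        lp[S[, j] > 0L] <- -Inf
      }
    }
    rep_k[s, ] <- exp(lp)
  }

  step <- mut %*% rep_k
  v <- numeric(ns)
  start <- rep.int(0L, k)
  start[1L] <- params$N
  v[index[paste(start, collapse = ",")]] <- 1
  v <- matrix(v, 1L, ns)
  for (g in seq_len(params$G)) {
    v <- v %*% step
  }
  structure(
    list(states = S, prob = as.vector(v),
         labels = genotype_labels(params), params = params),
    class = "wf_oracle"
  )
}

#' Exact presence probability from an oracle distribution
#'
#' @param oracle A `"wf_oracle"` from [exact_small_oracle()].
#' @param class A genotype label (`"WT"`, `"RES"`, `"CR"`, `"COM3"`, ...) or
#'   the pooled group `"COM"`.
#' @param min_count Presence cutoff; defaults to the parameter set's
#'   `presence_threshold`.
#' @return `P(count of class >= min_count)` at generation `G`.
#' @export
oracle_presence_probability <- function(oracle, class = "WT",
                                        min_count = NULL) {
  stopifnot(inherits(oracle, "wf_oracle"))
  if (is.null(min_count)) min_count <- oracle$params$presence_threshold
  counts <- if (identical(class, "COM")) {
    idx <- class_indices(oracle$params)$com
    if (length(idx) == 0L) return(0)
    rowSums(oracle$states[, idx, drop = FALSE])
  } else {
    j <- match(class, oracle$labels)
    if (is.na(j)) stop(sprintf("unknown genotype class '%s'", class))
    oracle$states[, j]
  }
  sum(oracle$prob[counts >= min_count])
}

#' @export
print.wf_oracle <- function(x, ...) {
  cat(sprintf(
    "exact state distribution: %d states, N = %d, G = %d (total prob %.6f)\n",
    nrow(x$states), x$params$N, x$params$G, sum(x$prob)
  ))
  invisible(x)
}
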