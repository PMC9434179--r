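#' Define a replicate grid over a parameter sweep
#'
#' A grid is the cartesian product of swept parameter values, each cell run
#' for a fixed number of replicates. Every replicate receives its own RNG
#' seed, derived deterministically from `master_seed` before any run starts,
#' so grids are reproducible and independent of execution order.
#'
#' @param base_params A [sim_params()] object providing all unswept values.
#' @param sweep Named list of value vectors for any subset of
#'   `N, G, mu, c, p, n, m, allow_second_mutation`.
#' @param replicates Replicates per cell.
#' @param master_seed Integer master seed.
#' @return An `"experiment_grid"`: list with `base_params`, `cells` (one data
#'   frame row per parameter cell), `replicates`, `master_seed`, and the
#'   per-replicate `seeds` matrix (cells x replicates).
#' @export
experiment_grid <- function(base_params, sweep = list(), replicates = 100,
                            master_seed = 1) {
  base_params <- validate_params(base_params)
  allowed <- c("N", "G", "mu", "c", "p", "n", "m", "allow_second_mutation")
  if (length(sweep) && (is.null(names(sweep)) ||
                        !all(names(sweep) %in% allowed))) {
    stop("sweep names must be among: ", paste(allowed, collapse = ", "))
  }
  cells <- if (length(sweep)) {
    expand.grid(sweep, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame(row.names = 1L)[1L, , drop = FALSE]
  }
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  seeds <- matrix(derive_seeds(master_seed, nrow(cells) * replicates),
                  nrow = nrow(cells), ncol = replicates)
  structure(
    list(base_params = base_params, cells = cells, replicates = replicates,
         master_seed = as.integer(master_seed), seeds = seeds),
    class = "experiment_grid"
  )
}

#' Run every replicate of a grid and tabulate outcomes
#'
#' Runs [run_replicate()] for each (cell, replicate) pair under its
#' pre-derived seed, classifies the final state with [classify_outcome()],
#' and (optionally, under the same seed) draws a clone sample with
#' [sample_clones()]. One row per replicate.
#'
#' @param grid An [experiment_grid()].
#' @param sample Draw a clone sample per replicate (default `TRUE`).
#' @param count_cr_as_reverted Should sampled `CR` clones (compensated *and*
#'   reverted) count toward `reverted_sampled`? Default `FALSE`: a "reverted
#'   clone" carries the reversal allele without a compensatory mutation.
#' @return Data frame (the outcome table): parameter echo (`N`, `G`, `mu`,
#'   `Nmu`, `c`, `p`, `n`, `m`, `allow_second_mutation`), `cell`,
#'   `replicate`, `seed`, final class-group counts, presence flags, outcome
#'   `label`, and sampled-clone tallies.
#' @export
run_grid <- function(grid, sample = TRUE, count_cr_as_reverted = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  cells <- grid$cells
  n_cells <- nrow(cells)
  R <- grid$replicates
  total <- n_cells * R

  num <- function() numeric(total)
  int <- function() integer(total)
  lgl <- function() logical(total)
  out <- list(
    cell = int(), replicate = int(), seed = int(),
    N = int(), G = int(), mu = num(), Nmu = num(), c = num(), p = num(),
    n = int(), m = int(), allow_second_mutation = lgl(),
    res_count = int(), com_partial_count = int(), com_full_count = int(),
    com_count = int(), wt_count = int(), cr_count = int(),
    wt_present = lgl(), cr_present = lgl(), com_present = lgl(),
    res_present = lgl(), two_background_reversal = lgl(),
    label = character(total),
    sampled_res = int(), sampled_com_partial = int(),
    sampled_com_full = int(), sampled_wt = int(), sampled_cr = int(),
    reverted_sampled = int()
  )

  row <- 0L
  for (ci in seq_len(n_cells)) {
    cp <- if (ncol(cells)) {
      do.call(update_params, c(list(grid$base_params), as.list(cells[ci, ,
                                                          drop = FALSE])))
    } else {
      grid$base_params
    }
    idx <- class_indices(cp)
    thr <- cp$presence_threshold
    for (r in seq_len(R)) {
      row <- row + 1L
      seed <- grid$seeds[ci, r]
      res <- with_seed(seed, {
        fin <- run_replicate_impl(cp, record = FALSE)
        picked <- if (sample) {
          pool <- rep.int(seq_along(fin), fin)
          pool[sample.int(length(pool), cp$sample_size)]
        } else {
          integer(0)
        }
        list(fin = fin, picked = picked)
      })
      fin <- res$fin
      out$cell[row] <- ci
      out$replicate[row] <- r
      out$seed[row] <- seed
      out$N[row] <- cp$N
      out$G[row] <- cp$G
      out$mu[row] <- cp$mu
      out$Nmu[row] <- cp$N * cp$mu
      out$c[row] <- cp$c
      out$p[row] <- cp$p
      out$n[row] <- cp$n
      out$m[row] <- cp$m
      out$allow_second_mutation[row] <- cp$allow_second_mutation

      res_ct <- fin[[idx$res]]
      com_full <- sum(fin[idx$com_full])
      com_part <- sum(fin[idx$com_partial])
      wt_ct <- fin[[idx$wt]]
      cr_ct <- fin[[idx$cr]]
      out$res_count[row] <- res_ct
      out$com_full_count[row] <- com_full
      out$com_partial_count[row] <- com_part
      out$com_count[row] <- com_full + com_part
      out$wt_count[row] <- wt_ct
      out$cr_count[row] <- cr_ct

      wt_p <- wt_ct >= thr
      cr_p <- cr_ct >= thr
      com_p <- (com_full + com_part) >= thr
      res_p <- res_ct >= thr
      out$wt_present[row] <- wt_p
      out$cr_present[row] <- cr_p
      out$com_present[row] <- com_p
      out$res_present[row] <- res_p
      out$two_background_reversal[row] <- wt_p && cr_p
      out$label[row] <- if (wt_p && cr_p) "soft_reversal"
        else if (wt_p && !com_p) "reversion"
        else if (com_p && !wt_p && !cr_p) "compensation"
        else if (res_p && !wt_p && !cr_p && !com_p) "persistence"
        else "mixed"

      if (sample) {
        pk <- res$picked
        s_res <- sum(pk == idx$res)
        s_full <- sum(pk %in% idx$com_full)
        s_part <- sum(pk %in% idx$com_partial)
        s_wt <- sum(pk == idx$wt)
        s_cr <- sum(pk == idx$cr)
        out$sampled_res[row] <- s_res
        out$sampled_com_full[row] <- s_full
        out$sampled_com_partial[row] <- s_part
        out$sampled_wt[row] <- s_wt
        out$sampled_cr[row] <- s_cr
        out$reverted_sampled[row] <-
          s_wt + if (count_cr_as_reverted) s_cr else 0L
      } else {
        out$sampled_res[row] <- NA_integer_
        out$sampled_com_full[row] <- NA_integer_
        out$sampled_com_partial[row] <- NA_integer_
        out$sampled_wt[row] <- NA_integer_
        out$sampled_cr[row] <- NA_integer_
        out$reverted_sampled[row] <- NA_integer_
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Per-cell summary of an outcome table
#'
#' Collapses an outcome table to one row per parameter cell: outcome
#' probabilities as means of 0/1 flags with binomial standard errors,
#' mean sampled reverted-clone counts with 2.5/97.5 percentile intervals of
#' the replicate distribution, and mean final class-group shares.
#'
#' @param table An outcome table from [run_grid()].
#' @param by Grouping column names; by default every parameter column that
#'   varies in `table` (all rows form one group if none does).
#' @return Data frame with one row per cell: `n_replicates`, `p_wt`,
#'   `se_wt`, `p_soft`, `se_soft` (two-background reversal), sampled-clone
#'   statistics (`mean_reverted`, `reverted_q025`, `reverted_q975`), and mean
#'   final shares (`share_wt`, `share_cr`, `share_reversal_allele` = WT + CR,
#'   `share_com_full`, `share_com_partial`, `share_res`).
#' @export
summarize_outcomes <- function(table, by = NULL) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  if (is.null(by)) {
    candidates <- c("N", "G", "mu", "Nmu", "c", "p", "n", "m",
                    "allow_second_mutation")
    candidates <- intersect(candidates, names(table))
    by <- candidates[vapply(candidates,
                            function(v) length(unique(table[[v]])) > 1L,
                            logical(1))]
  }
  groups <- if (length(by)) {
    split(seq_len(nrow(table)), table[by], drop = TRUE)
  } else {
    list(all = seq_len(nrow(table)))
  }
  binom_se <- function(x) sqrt(mean(x) * (1 - mean(x)) / length(x))
  rows <- lapply(groups, function(i) {
    g <- table[i, , drop = FALSE]
    key <- if (length(by)) g[1L, by, drop = FALSE] else NULL
    rev <- g$reverted_sampled[!is.na(g$reverted_sampled)]
    stats <- data.frame(
      n_replicates = nrow(g),
      p_wt = mean(g$wt_present),
      se_wt = binom_se(g$wt_present),
      p_soft = mean(g$two_background_reversal),
      se_soft = binom_se(g$two_background_reversal),
      mean_reverted = if (length(rev)) mean(rev) else NA_real_,
      reverted_q025 = if (length(rev)) {
        unname(stats::quantile(rev, 0.025, type = 7))
      } else {
        NA_real_
      },
      reverted_q975 = if (length(rev)) {
        unname(stats::quantile(rev, 0.975, type = 7))
      } else {
        NA_real_
      },
      share_wt = mean(g$wt_count / g$N),
      share_cr = mean(g$cr_count / g$N),
      share_reversal_allele = mean((g$wt_count + g$cr_count) / g$N),
      share_com_full = mean(g$com_full_count / g$N),
      share_com_partial = mean(g$com_partial_count / g$N),
      share_res = mean(g$res_count / g$N)
    )
    if (is.null(key)) stats else cbind(key, stats)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(by)) out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The reversion-vs-compensation race experiment
#'
#' Reproduces the race setting: compensated clones cannot acquire a second
#' mutation, no fully compensating targets, 500 generations, and the
#' probability that the reverted wild type is present (>= threshold cells) at
#' the end is estimated per cell. The matching analytic curve
#' ([p_reversal_before_fixation()]) is joined onto the summary.
#'
#' @param mu Mutation-rate grid.
#' @param p,n Compensatory effect(s) and target count(s); vectors are swept.
#' @param N,c,G,presence_threshold,sample_size Model constants.
#' @param replicates Replicates per cell.
#' @param master_seed Master seed for the grid.
#' @param with_analytic Join the analytic race curve (default `TRUE`).
#' @return List with `outcomes` (per-replicate table) and `summary` (per-cell
#'   table, including `p_wt_analytic` when requested).
#' @export
run_reversion_race <- function(mu = 10^seq(-7, -3, by = 1), p = 0.5, n = 100,
                               N = 10000, c = 0.15, G = 500,
                               presence_threshold = 10, sample_size = 10,
                               replicates = 200, master_seed = 1,
                               with_analytic = TRUE) {
  sweep <- list(mu = mu)
  if (length(p) > 1L) sweep$p <- p
  if (length(n) > 1L) sweep$n <- n
  base <- sim_params(
    N = N, G = G, mu = mu[1L], c = c, p = p[1L], n = n[1L], m = 0,
    allow_second_mutation = FALSE, presence_threshold = presence_threshold,
    sample_size = sample_size
  )
  grid <- experiment_grid(base, sweep, replicates, master_seed)
  outcomes <- run_grid(grid, sample = FALSE)
  summary <- summarize_outcomes(outcomes,
                                by = intersect(c("mu", "p", "n", "Nmu"),
                                               c(names(sweep), "Nmu")))
  if (with_analytic) {
    summary$p_wt_analytic <- mapply(function(mui, pi, ni) {
      p_reversal_before_fixation(update_params(
        base, mu = mui, p = pi, n = ni
      ))$p_wt_wins
    },
    summary$mu,
    if ("p" %in% names(summary)) summary$p else base$p,
    if ("n" %in% names(summary)) summary$n else base$n)
  }
  list(outcomes = outcomes, summary = summary)
}

#' The two-background (soft) reversal experiment
#'
#' Second mutations are allowed, so the wild-type phenotype can arise both
#' directly (`RES -> WT`) and on a compensated background (`COM -> CR`). Per
#' cell, estimates the probability that both backgrounds are present (>=
#' threshold cells) at the end of `G = 100` generations.
#'
#' @inheritParams run_reversion_race
#' @param G Generations (100 in the canonical setting).
#' @return List with `outcomes` and `summary` (`p_soft` is the two-background
#'   reversal probability).
#' @export
run_two_background_reversal <- function(mu = 10^seq(-7, -3, by = 1), p = 0.5,
                                        n = 100, N = 10000, c = 0.15, G = 100,
                                        presence_threshold = 10,
                                        sample_size = 10, replicates = 200,
                                        master_seed = 1) {
  sweep <- list(mu = mu)
  if (length(p) > 1L) sweep$p <- p
  if (length(n) > 1L) sweep$n <- n
  base <- sim_params(
    N = N, G = G, mu = mu[1L], c = c, p = p[1L], n = n[1L], m = 0,
    allow_second_mutation = TRUE, presence_threshold = presence_threshold,
    sample_size = sample_size
  )
  grid <- experiment_grid(base, sweep, replicates, master_seed)
  outcomes <- run_grid(grid, sample = FALSE)
  summary <- summarize_outcomes(outcomes,
                                by = intersect(c("mu", "p", "n", "Nmu"),
                                               c(names(sweep), "Nmu")))
  list(outcomes = outcomes, summary = summary)
}

#' Experiment-scale clone panels
#'
#' Emulates a laboratory study: for each mutation-supply value, evolve a small
#' number of independent populations for `G` generations and sequence
#' `sample_size` clones from each. Returns the tidy clone-label table (the
#' in-silico analogue of picking colonies).
#'
#' @param Nmu Mutation-supply values, one panel each.
#' @param populations Independent populations per panel.
#' @param N,G,c,p,n,m,sample_size,presence_threshold Model constants; supply
#'   values whose implied `mu` exceeds `1e-3` are realized by enlarging `N`
#'   (see [params_for_supply()]).
#' @param master_seed Master seed.
#' @return Data frame with one row per sampled clone: `Nmu`, `population`,
#'   `clone`, `label`, `group`, `fully_compensating`.
#' @export
run_clone_panels <- function(Nmu = c(0.001, 0.01, 0.1, 1, 10),
                             populations = 10, N = 10000, G = 100, c = 0.15,
                             p = 0.5, n = 100, m = 0, sample_size = 10,
                             presence_threshold = 10, master_seed = 1) {
  seeds <- matrix(derive_seeds(master_seed, length(Nmu) * populations),
                  nrow = length(Nmu))
  rows <- list()
  for (i in seq_along(Nmu)) {
    params <- params_for_supply(
      Nmu[i], N = N, G = G, c = c, p = p, n = n, m = m,
      allow_second_mutation = TRUE, sample_size = sample_size,
      presence_threshold = presence_threshold
    )
    for (pop in seq_len(populations)) {
      sc <- with_seed(seeds[i, pop], {
        fin <- run_replicate_impl(params, record = FALSE)
        sample_clones(fin, params, replicate_id = pop)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        Nmu = Nmu[i],
        population = pop,
        clone = seq_len(sample_size),
        label = sc$labels,
        group = as.character(class_group(sc$labels)),
        fully_compensating = sc$fully_compensating,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reversal under fully compensating competition
#'
#' Sweeps the number `m` of fully compensating compensatory targets across
#' mutation-supply values and summarizes the number of reverted clones in a
#' sample of `sample_size` per replicate (mean and 2.5/97.5 percentiles
#' across replicates) together with final class-group shares. At high
#' mutation supply the `m + 1` equally fit, equally mutable lineages (the
#' reversal plus the `m` fully compensating mutations) are each expected to
#' reach share `1 / (m + 1)` ([expected_reversal_share()]); with `m = 3` the
#' expected number of reverted clones in a sample of 10 is 2.5.
#'
#' By default the `Com -> CR` second-mutation channel is disabled
#' (`allow_second_mutation = FALSE`): the `1/(m+1)` partition describes the
#' pure competition between the reversal lineage and the fully compensating
#' lineages, and holds only while compensated genotypes cannot themselves
#' revert. With the channel enabled, compensated-reverted (`CR`) lineages —
#' also at wild-type fitness — establish from the large early pool of
#' partially compensated cells and take a substantial share at high supply,
#' pushing the wild-type-only share well below `1/(m+1)` (and the combined
#' reversal-allele share above it).
#'
#' @param m Values of the fully-compensating target count (swept).
#' @param Nmu Mutation-supply values (swept; large supplies are realized by
#'   enlarging `N`, see [params_for_supply()]).
#' @param N,G,c,p,n,sample_size,presence_threshold Model constants.
#' @param replicates Replicates per (supply, m) cell.
#' @param master_seed Master seed.
#' @param allow_second_mutation Enable the `Com -> CR` channel (default
#'   `FALSE`, see Details).
#' @param count_cr_as_reverted Count sampled `CR` clones as reverted (default
#'   `FALSE`: reverted = reversal allele without a compensatory mutation).
#' @return List with `outcomes` (per-replicate table) and `summary` (one row
#'   per `(Nmu, m)` with `mean_reverted`, percentile interval, shares, and
#'   `expected_share = 1 / (m + 1)`).
#' @export
run_full_compensation <- function(m = c(0, 1, 3, 5, 10),
                                  Nmu = c(0.1, 1, 10), N = 10000, G = 100,
                                  c = 0.15, p = 0.5, n = 100,
                                  sample_size = 10, presence_threshold = 10,
                                  replicates = 200, master_seed = 1,
                                  allow_second_mutation = FALSE,
                                  count_cr_as_reverted = FALSE) {
  seeds <- derive_seeds(master_seed, length(Nmu))
  parts <- lapply(seq_along(Nmu), function(i) {
    base <- params_for_supply(
      Nmu[i], N = N, G = G, c = c, p = p, n = n, m = m[1L],
      allow_second_mutation = allow_second_mutation,
      sample_size = sample_size,
      presence_threshold = presence_threshold
    )
    grid <- experiment_grid(base, list(m = m), replicates,
                            master_seed = seeds[i])
    run_grid(grid, sample = TRUE,
             count_cr_as_reverted = count_cr_as_reverted)
  })
  outcomes <- do.call(rbind, parts)
  summary <- summarize_outcomes(outcomes, by = c("Nmu", "m"))
  summary$expected_share <- expected_reversal_share(summary$m)
  list(outcomes = outcomes, summary = summary)
}
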