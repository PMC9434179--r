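#' One generation of mutation
#'
#' Applies the mutation kernel to a vector of genotype-class counts. Each
#' resistant (`RES`) cell mutates to one of its `n + 1` destinations — the
#' wild type (reversal) or any of the `n` compensatory targets — each with
#' probability `mu`, staying `RES` with probability `1 - (n + 1) * mu`; the
#' fate of all `RES` cells is a single multinomial draw. If second mutations
#' are allowed, each compensated (`COMi`) cell independently acquires a
#' reversal with probability `mu`, moving to `CR` (one binomial draw per
#' occupied compensatory class). `WT` and `CR` cells never mutate, compensated
#' cells never switch compensatory targets, and a cell takes at most one
#' mutational step per generation. Total count is conserved.
#'
#' @param counts Integer vector of length `n + 3` in [genotype_labels()]
#'   order.
#' @param params A [sim_params()] object.
#' @return Integer vector of post-mutation counts (names preserved if
#'   present).
#' @export
mutate_step <- function(counts, params) {
  n <- params$n
  mu <- params$mu
  if (length(counts) != n + 3L) {
    stop("`counts` must have length n + 3")
  }
  if (mu <= 0) {
    return(counts)
  }
  # Com -> CR draws act on the cells present at the start of the generation:
  # a cell takes at most one mutational step per generation, so cells arriving
  # from RES this generation are not exposed.
  if (params$allow_second_mutation && n > 0L) {
    ci <- counts[2L:(n + 1L)]
    occupied <- which(ci > 0L)
    if (length(occupied)) {
      to_cr <- stats::rbinom(length(occupied), ci[occupied], mu)
      counts[1L + occupied] <- ci[occupied] - to_cr
      counts[[n + 3L]] <- counts[[n + 3L]] + sum(to_cr)
    }
  }
  r <- counts[[1L]]
  if (r > 0L) {
    fate <- stats::rmultinom(
      1L, r, c(1 - (n + 1) * mu, rep.int(mu, n + 1L))
    )[, 1L]
    counts[[1L]] <- fate[[1L]]
    counts[[n + 2L]] <- counts[[n + 2L]] + fate[[2L]]
    if (n > 0L) {
      counts[2L:(n + 1L)] <- counts[2L:(n + 1L)] + fate[3L:(n + 2L)]
    }
  }
  counts
}

#' One generation of selection and drift
#'
#' Wright-Fisher reproduction: the next generation is a single multinomial
#' draw of `N` offspring with class probabilities proportional to
#' `counts * fitness`.
#'
#' @param counts Integer vector of length `n + 3` of class counts.
#' @param fitness Relative fitness vector from [build_fitness()].
#' @param params A [sim_params()] object (supplies `N`).
#' @return Integer vector of next-generation counts (named after `fitness`).
#' @export
selection_drift_step <- function(counts, fitness, params) {
  weight <- counts * fitness
  if (all(weight == 0)) {
    stop("all-zero weight vector: no individuals to reproduce")
  }
  stats::rmultinom(1L, params$N, weight)[, 1L]
}

#' Simulate one replicate population
#'
#' Starts from the all-resistant state (the moment the costly adaptive
#' mutation has just fixed and the environment has reverted) and iterates
#' mutation ([mutate_step()]) followed by fitness-weighted multinomial
#' reproduction ([selection_drift_step()]) for `G` generations.
#'
#' If `params$seed` is set the replicate is bit-reproducible and the caller's
#' RNG state is left untouched; otherwise the current RNG stream is used.
#'
#' @param params A [sim_params()] object.
#' @param record If `TRUE` (default) return the full trajectory; if `FALSE`
#'   return only the final generation's counts (much lighter for large
#'   replicate grids).
#' @return With `record = TRUE`, a `"wf_trajectory"` object: a list with
#'   elements `params` and `counts`, the latter a `(G + 1) x (n + 3)` integer
#'   matrix with one row per generation `0..G`. With `record = FALSE`, the
#'   named final count vector with attribute `generation = G`.
#' @examples
#' traj <- run_replicate(sim_params(N = 500, G = 50, mu = 1e-3, n = 5,
#'                                  seed = 1))
#' final_state(traj)
#' @export
run_replicate <- function(params, record = TRUE) {
  params <- validate_params(params)
  if (!is.null(params$seed)) {
    with_seed(params$seed, run_replicate_impl(params, record))
  } else {
    run_replicate_impl(params, record)
  }
}

run_replicate_impl <- function(params, record) {
  k <- params$n + 3L
  labels <- genotype_labels(params)
  w <- unname(build_fitness(params))
  counts <- integer(k)
  counts[1L] <- params$N
  if (record) {
    traj <- matrix(0L, nrow = params$G + 1L, ncol = k,
                   dimnames = list(0:params$G, labels))
    traj[1L, ] <- counts
  }
  for (g in seq_len(params$G)) {
    counts <- mutate_step(counts, params)
    counts <- selection_drift_step(counts, w, params)
    if (record) traj[g + 1L, ] <- counts
  }
  if (record) {
    structure(list(params = params, counts = traj), class = "wf_trajectory")
  } else {
    structure(stats::setNames(counts, labels), generation = params$G)
  }
}

#' Final population state of a trajectory
#'
#' @param trajectory A `"wf_trajectory"` object.
#' @return Named integer count vector with attribute `generation`.
#' @export
final_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "wf_trajectory"))
  counts <- trajectory$counts[nrow(trajectory$counts), ]
  structure(counts, generation = trajectory$params$G)
}

#' @export
print.wf_trajectory <- function(x, ...) {
  cat(sprintf(
    "Wright-Fisher trajectory: %d generations, N = %d, %d genotype classes\n",
    x$params$G, x$params$N, ncol(x$counts)
  ))
  fin <- final_state(x)
  fin <- fin[fin > 0L]
  cat("final state:",
      paste(sprintf("%s=%d", names(fin), fin), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy long-format view of a trajectory
#'
#' @param x A `"wf_trajectory"` object.
#' @param row.names,optional Ignored (base generic signature).
#' @param replicate_id Optional replicate identifier column.
#' @param drop_zero Drop rows with zero count (default `TRUE`; the matrix is
#'   sparse in the class dimension).
#' @param ... Unused.
#' @return A data frame with columns `replicate_id` (if given), `generation`,
#'   `class_label`, `count`.
#' @export
as.data.frame.wf_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                        replicate_id = NULL,
                                        drop_zero = TRUE, ...) {
  m <- x$counts
  out <- data.frame(
    generation = rep.int(as.integer(rownames(m)), ncol(m)),
    class_label = rep(colnames(m), each = nrow(m)),
    count = as.vector(m),
    stringsAsFactors = FALSE
  )
  if (drop_zero) out <- out[out$count > 0L, , drop = FALSE]
  if (!is.null(replicate_id)) {
    out <- cbind(replicate_id = replicate_id, out)
  }
  rownames(out) <- NULL
  out
}

#' Write a trajectory as tidy CSV
#'
#' One observation per row: `(replicate_id, generation, class_label, count)`.
#'
#' @param trajectory A `"wf_trajectory"` object.
#' @param path Output file path.
#' @param replicate_id Replicate identifier written in the first column.
#' @return Invisibly, the data frame written.
#' @export
write_trajectory_csv <- function(trajectory, path, replicate_id = 1L) {
  df <- as.data.frame(trajectory, replicate_id = replicate_id)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
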