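# Coerce a trajectory or count vector to a validated final-state count vector.
as_population_counts <- function(state, params) {
  if (inherits(state, "wf_trajectory")) {
    state <- final_state(state)
  }
  counts <- as.integer(state)
  if (length(counts) != params$n + 3L) {
    stop("state must have one count per genotype class (n + 3)")
  }
  if (any(counts < 0L)) stop("negative class count")
  if (sum(counts) != params$N) {
    stop(sprintf("class counts sum to %d, expected N = %d",
                 sum(counts), params$N))
  }
  stats::setNames(counts, genotype_labels(params))
}

#' Classify the end-of-run outcome of a replicate
#'
#' A genotype class (or class group) is called *present* when its final count
#' is at least `presence_threshold` — by default 10 cells, i.e. 0.1% of the
#' default population, at which point an advantaged lineage is established
#' and expected to fix. The compensated group pools all `COMi` classes.
#' Presence of the reverted wild type on both backgrounds at once
#' (`WT` and `CR`) is the two-background ("soft") reversal signature.
#'
#' Labels are derived sugar over the presence flags:
#' \describe{
#'   \item{soft_reversal}{`WT` and `CR` both present.}
#'   \item{reversion}{`WT` present, no `CR`, no compensated class.}
#'   \item{compensation}{compensated class present, neither `WT` nor `CR`.}
#'   \item{persistence}{only `RES` present.}
#'   \item{mixed}{anything else (e.g. `WT` and `COM` coexisting).}
#' }
#'
#' @param state A `"wf_trajectory"` or a final count vector of length
#'   `n + 3`; counts must sum to `N`.
#' @param params A [sim_params()] object.
#' @return An `"outcome_summary"`: list with logical flags `wt_present`,
#'   `cr_present`, `any_com_present`, `res_present`,
#'   `two_background_reversal`, and the character `label`.
#' @export
classify_outcome <- function(state, params) {
  params <- validate_params(params)
  counts <- as_population_counts(state, params)
  idx <- class_indices(params)
  thr <- params$presence_threshold
  wt <- counts[[idx$wt]] >= thr
  cr <- counts[[idx$cr]] >= thr
  res <- counts[[idx$res]] >= thr
  com <- sum(counts[idx$com]) >= thr
  label <- if (wt && cr) {
    "soft_reversal"
  } else if (wt && !com) {
    "reversion"
  } else if (com && !wt && !cr) {
    "compensation"
  } else if (res && !wt && !cr && !com) {
    "persistence"
  } else {
    "mixed"
  }
  structure(
    list(
      wt_present = wt,
      cr_present = cr,
      any_com_present = com,
      res_present = res,
      two_background_reversal = wt && cr,
      label = label
    ),
    class = "outcome_summary"
  )
}

#' @export
print.outcome_summary <- function(x, ...) {
  present <- c("WT", "CR", "Com", "Res")[c(x$wt_present, x$cr_present,
                                           x$any_com_present, x$res_present)]
  cat(sprintf("outcome: %s (present: %s)\n", x$label,
              if (length(present)) paste(present, collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
as.list.outcome_summary <- function(x, ...) unclass(x)

#' Sample clones from a final population
#'
#' Emulates picking and sequencing `sample_size` colonies from one evolved
#' population: a multivariate hypergeometric draw (sampling cells *without*
#' replacement) from the final class counts.
#'
#' @param state A `"wf_trajectory"` or final count vector.
#' @param params A [sim_params()] object (supplies `sample_size` and `m`).
#' @param replicate_id Optional identifier carried in the result.
#' @return A `"clone_sample"`: list with `replicate_id`, character `labels`
#'   (length `sample_size`), and logical `fully_compensating` flags resolved
#'   from `m`.
#' @export
sample_clones <- function(state, params, replicate_id = NA_integer_) {
  params <- validate_params(params)
  counts <- as_population_counts(state, params)
  pool <- rep.int(seq_along(counts), counts)
  picked <- pool[sample.int(length(pool), params$sample_size)]
  labels <- genotype_labels(params)[picked]
  structure(
    list(
      replicate_id = replicate_id,
      labels = labels,
      fully_compensating = is_fully_compensating(labels, params)
    ),
    class = "clone_sample"
  )
}

#' @export
print.clone_sample <- function(x, ...) {
  cat(sprintf("clone sample (replicate %s): %s\n",
              as.character(x$replicate_id),
              paste(x$labels, collapse = " ")))
  invisible(x)
}
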