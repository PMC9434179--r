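#' Relative fitness of every genotype class
#'
#' Fitness is relative to the wild type in the original (post-reversal)
#' environment: `w[WT] = w[CR] = 1`, the resistant genotype pays the full cost
#' (`w[RES] = 1 - c`), an ordinary compensatory mutation removes a proportion
#' `p` of the cost (`w[COMi] = 1 - c * (1 - p)`), and a fully compensating
#' mutation (targets `i <= m`) restores wild-type fitness exactly
#' (`w[COMi] = 1`). With the defaults `c = 0.15`, `p = 0.5` this gives the
#' canonical triple 0.85 / 0.925 / 1.
#'
#' Entries are computed directly from the closed forms (no accumulation), so
#' they are exact in floating point.
#'
#' @param params A [sim_params()] object.
#' @return Named numeric vector of length `n + 3`, ordered as
#'   [genotype_labels()].
#' @examples
#' w <- build_fitness(sim_params(c = 0.15, p = 0.5, n = 2, m = 1))
#' w[c("RES", "COM1", "COM2", "WT", "CR")]  # 0.85, 1, 0.925, 1, 1
#' @export
build_fitness <- function(params) {
  params <- validate_params(params)
  n <- params$n
  w_com <- 1 - params$c * (1 - params$p)
  com <- if (n > 0L) {
    ifelse(seq_len(n) <= params$m, 1, w_com)
  } else {
    numeric(0)
  }
  stats::setNames(c(1 - params$c, com, 1, 1), genotype_labels(params))
}
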