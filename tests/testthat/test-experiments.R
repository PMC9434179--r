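test_that("grids are reproducible from the master seed alone", {
  base <- sim_params(N = 300, G = 15, mu = 1e-3, n = 4, sample_size = 5)
  g1 <- experiment_grid(base, list(mu = c(5e-4, 1e-3)), replicates = 4,
                        master_seed = 42)
  g2 <- experiment_grid(base, list(mu = c(5e-4, 1e-3)), replicates = 4,
                        master_seed = 42)
  expect_identical(g1$seeds, g2$seeds)
  expect_identical(run_grid(g1), run_grid(g2))

  g3 <- experiment_grid(base, list(mu = c(5e-4, 1e-3)), replicates = 4,
                        master_seed = 43)
  expect_false(identical(g1$seeds, g3$seeds))
})

test_that("the outcome table echoes parameters and respects structure", {
  base <- sim_params(N = 300, G = 15, mu = 1e-3, n = 4, m = 1,
                     sample_size = 5)
  g <- experiment_grid(base, list(mu = c(0, 1e-3)), replicates = 6,
                       master_seed = 1)
  tab <- run_grid(g)
  expect_identical(nrow(tab), 12L)
  expect_setequal(unique(tab$mu), c(0, 1e-3))
  expect_true(all(tab$res_count + tab$com_count + tab$wt_count +
                    tab$cr_count == 300L))
  samp <- tab$sampled_res + tab$sampled_com_full + tab$sampled_com_partial +
    tab$sampled_wt + tab$sampled_cr
  expect_true(all(samp == 5L))

  # mu = 0 cells can never show reversal
  zero <- tab[tab$mu == 0, ]
  expect_true(all(!zero$wt_present))
  expect_true(all(zero$res_count == 300L))
})

test_that("summaries compute binomial errors and percentile intervals", {
  flags <- rep(c(TRUE, FALSE), each = 500)
  tab <- data.frame(
    N = 1000L, G = 10L, mu = 1e-4, Nmu = 0.1, c = 0.15, p = 0.5, n = 10L,
    m = 0L, allow_second_mutation = FALSE,
    wt_present = flags, two_background_reversal = FALSE,
    reverted_sampled = 3L,
    wt_count = 100L, cr_count = 0L, com_full_count = 0L,
    com_partial_count = 400L, res_count = 500L
  )
  s <- summarize_outcomes(tab)
  expect_identical(nrow(s), 1L)
  expect_equal(s$p_wt, 0.5)
  expect_equal(s$se_wt, sqrt(0.25 / 1000), tolerance = 1e-12)
  # a constant statistic collapses to a point interval
  expect_equal(s$reverted_q025, 3)
  expect_equal(s$reverted_q975, 3)
  expect_equal(s$share_reversal_allele, 0.1)
})

test_that("the soft-reversal probability is zero without second mutations", {
  base <- sim_params(N = 500, G = 20, mu = 2e-3, n = 4,
                     allow_second_mutation = FALSE, sample_size = 5)
  tab <- run_grid(experiment_grid(base, replicates = 10, master_seed = 2))
  expect_true(all(!tab$two_background_reversal))
  expect_true(all(tab$cr_count == 0L))
})

test_that("clone panels are tidy population-by-clone tables", {
  panels <- run_clone_panels(Nmu = c(0.01, 1), populations = 3, N = 500,
                             G = 10, n = 4, sample_size = 6, master_seed = 9)
  expect_identical(nrow(panels), 2L * 3L * 6L)
  expect_setequal(unique(panels$Nmu), c(0.01, 1))
  expect_true(all(panels$clone %in% 1:6))
  expect_true(all(panels$group %in% c("RES", "COM", "WT", "CR")))
  # reproducible end to end
  expect_identical(panels,
                   run_clone_panels(Nmu = c(0.01, 1), populations = 3,
                                    N = 500, G = 10, n = 4, sample_size = 6,
                                    master_seed = 9))
})

test_that("the full-compensation driver sweeps m with its expectation", {
  fc <- run_full_compensation(m = c(0, 1), Nmu = c(0.5, 1), N = 500, G = 10,
                              n = 4, replicates = 5, master_seed = 3)
  expect_identical(nrow(fc$summary), 4L)
  expect_equal(fc$summary$expected_share,
               expected_reversal_share(fc$summary$m))
  expect_identical(nrow(fc$outcomes), 2L * 2L * 5L)
  # the default setting has no Com -> CR channel
  expect_true(all(fc$outcomes$cr_count == 0L))
})

test_that("independent seed sets give statistically consistent estimates", {
  run_cell <- function(master_seed) {
    base <- sim_params(N = 500, G = 30, mu = 4e-4, n = 10,
                       allow_second_mutation = FALSE, sample_size = 5)
    tab <- run_grid(experiment_grid(base, replicates = 150,
                                    master_seed = master_seed),
                    sample = FALSE)
    mean(tab$wt_present)
  }
  p1 <- run_cell(101)
  p2 <- run_cell(202)
  # 99% two-sample binomial envelope
  se <- sqrt(p1 * (1 - p1) / 150 + p2 * (1 - p2) / 150)
  expect_lt(abs(p1 - p2), max(2.58 * se, 0.02))
})
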