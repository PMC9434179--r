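test_that("the deterministic sweep follows the selection recursion", {
  # neutrality: the trajectory never moves
  expect_equal(deterministic_sweep(1, 1, 0.3, 10), rep(0.3, 11))

  # one hand-evaluated step: 0.5 / (0.5 + 0.5 * 0.85)
  x <- deterministic_sweep(1, 0.85, 0.5, 1)
  expect_equal(x[2], 0.5 / (0.5 + 0.5 * 0.85), tolerance = 1e-12)

  # an advantaged invader rises monotonically toward fixation
  # (horizon short of double-precision saturation at 1)
  traj <- deterministic_sweep(1, 0.85, 1e-4, 200)
  expect_true(all(diff(traj) > 0))
  expect_gt(traj[201], 0.999)
  expect_true(all(traj > 0 & traj < 1))
})

test_that("fixation probability has the diffusion form", {
  expect_equal(fixation_probability(0, 100), 0.01)
  expect_equal(fixation_probability(0.15, 10000),
               (1 - exp(-0.3)) / (1 - exp(-2 * 10000 * 0.15)),
               tolerance = 1e-12)
  # denominator is ~1 at Ns >> 1, so ~ 1 - exp(-2s)
  expect_equal(fixation_probability(0.15, 10000), 1 - exp(-0.3),
               tolerance = 1e-9)
  # monotone increasing in s, bounded in [0, 1], vanishing for deleterious s
  s_grid <- seq(0.001, 0.3, by = 0.01)
  fp <- fixation_probability(s_grid, 10000)
  expect_true(all(diff(fp) > 0))
  expect_true(all(fp >= 0 & fp <= 1))
  expect_lt(fixation_probability(-0.05, 10000), 1e-9)
  expect_lt(fixation_probability(-0.001, 10000),
            fixation_probability(0, 10000))
  expect_lt(fixation_probability(0, 10000),
            fixation_probability(0.001, 10000))
})

test_that("the race approximation behaves across its parameter space", {
  base <- function(mu, ...) {
    sim_params(N = 10000, G = 500, mu = mu, c = 0.15, p = 0.5, n = 100,
               m = 0, allow_second_mutation = FALSE, ...)
  }
  # zero hazard at zero mutation rate
  expect_equal(p_reversal_before_fixation(base(0))$p_wt_wins, 0)

  # non-decreasing in mu over the canonical grid, always a probability
  pw <- vapply(10^seq(-7, -3, by = 0.5),
               function(mu) p_reversal_before_fixation(base(mu))$p_wt_wins,
               numeric(1))
  expect_true(all(diff(pw) >= 0))
  expect_true(all(pw >= 0 & pw <= 1))

  mu0 <- 1e-5
  ref <- p_reversal_before_fixation(base(mu0))$p_wt_wins
  # more compensatory targets -> compensation fixes sooner -> less reversal
  expect_lt(p_reversal_before_fixation(
    sim_params(N = 10000, G = 500, mu = mu0, c = 0.15, p = 0.5, n = 1000,
               m = 0, allow_second_mutation = FALSE))$p_wt_wins, ref)
  expect_gt(p_reversal_before_fixation(
    sim_params(N = 10000, G = 500, mu = mu0, c = 0.15, p = 0.5, n = 10,
               m = 0, allow_second_mutation = FALSE))$p_wt_wins, ref)
  # stronger compensation -> reversal less likely
  expect_lt(p_reversal_before_fixation(
    sim_params(N = 10000, G = 500, mu = mu0, c = 0.15, p = 0.8, n = 100,
               m = 0, allow_second_mutation = FALSE))$p_wt_wins, ref)
  expect_gt(p_reversal_before_fixation(
    sim_params(N = 10000, G = 500, mu = mu0, c = 0.15, p = 0.2, n = 100,
               m = 0, allow_second_mutation = FALSE))$p_wt_wins, ref)
  # larger populations supply more reversal mutations
  expect_gt(p_reversal_before_fixation(
    sim_params(N = 100000, G = 500, mu = mu0, c = 0.15, p = 0.5, n = 100,
               m = 0, allow_second_mutation = FALSE))$p_wt_wins, ref)

  # the race is only defined without fully compensating targets
  expect_error(p_reversal_before_fixation(
    sim_params(mu = mu0, m = 1, n = 100)), "m = 0")
})

test_that("the analytic race curve is a tidy grid", {
  curve <- reversal_race_curve(mu = 10^seq(-7, -3))
  expect_identical(nrow(curve), 5L)
  expect_named(curve, c("mu", "Nmu", "p_wt_analytic", "t_fix_com"))
  expect_true(all(diff(curve$p_wt_analytic) >= 0))
  expect_true(all(curve$t_fix_com <= 500))
})

test_that("fully compensating competitors partition the population", {
  expect_equal(expected_reversal_share(0), 1)
  expect_equal(expected_reversal_share(1), 0.5)
  expect_equal(expected_reversal_share(3), 0.25)
  # reversal share plus the m competitor shares always sums to one
  for (m in c(0, 1, 3, 5, 10)) {
    expect_equal(expected_reversal_share(m) * (m + 1), 1)
  }
  # a sample of 10 with m = 3 is expected to contain 2.5 reverted clones
  expect_equal(10 * expected_reversal_share(3), 2.5)
})
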