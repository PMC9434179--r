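test_that("a zero mutation rate leaves the population in stasis", {
  p <- sim_params(N = 500, G = 30, mu = 0, n = 5, seed = 1)
  traj <- run_replicate(p)
  expect_true(all(traj$counts[, "RES"] == 500L))
  expect_true(all(traj$counts[, colnames(traj$counts) != "RES"] == 0L))
})

test_that("population size is conserved every generation", {
  for (seed in 1:3) {
    p <- sim_params(N = 1000, G = 50, mu = 1e-3, n = 10, m = 2, seed = seed)
    traj <- run_replicate(p)
    expect_true(all(rowSums(traj$counts) == 1000L))
    expect_identical(nrow(traj$counts), 51L)
    expect_true(all(traj$counts >= 0L))
  }
})

test_that("mutation only flows forward through the class graph", {
  p <- sim_params(N = 2000, mu = 5e-3, n = 4, allow_second_mutation = TRUE)
  set.seed(11)
  for (i in 1:50) {
    before <- as.integer(stats::rmultinom(1, 2000, rep(1, 7)))
    after <- mutate_step(before, p)
    expect_identical(sum(after), sum(before))
    expect_lte(after[[1]], before[[1]])             # RES never gains
    expect_gte(after[[6]], before[[6]])             # WT never loses
    expect_gte(after[[7]], before[[7]])             # CR never loses
  }
})

test_that("mutation counts have the right means", {
  # from an all-RES population: E[new WT] = N*mu, E[new Com total] = N*n*mu
  p <- sim_params(N = 10000, mu = 1e-3, n = 100)
  start <- c(10000L, integer(102))
  set.seed(21)
  draws <- replicate(10000, {
    out <- mutate_step(start, p)
    c(wt = out[[102]], com = sum(out[2:101]))
  })
  se_wt <- sqrt(10000 * 1e-3 * (1 - 1e-3) / 10000)
  expect_lt(abs(mean(draws["wt", ]) - 10), 3 * se_wt)
  se_com <- sqrt(10000 * 0.1 * (1 - 0.1) / 10000)
  expect_lt(abs(mean(draws["com", ]) - 1000), 3 * se_com)
})

test_that("compensated reversal is unreachable when second mutations are off", {
  p <- sim_params(N = 5000, G = 50, mu = 1e-3, n = 20,
                  allow_second_mutation = FALSE, seed = 4)
  traj <- run_replicate(p)
  expect_true(all(traj$counts[, "CR"] == 0L))
})

test_that("replicates are bit-reproducible under a seed", {
  p <- sim_params(N = 1000, G = 40, mu = 1e-3, n = 10, seed = 123)
  t1 <- run_replicate(p)
  t2 <- run_replicate(p)
  expect_identical(t1$counts, t2$counts)
  t3 <- run_replicate(sim_params(N = 1000, G = 40, mu = 1e-3, n = 10,
                                 seed = 124))
  expect_false(identical(t1$counts, t3$counts))

  # the light-weight path returns the same final state
  fin <- run_replicate(p, record = FALSE)
  expect_identical(as.integer(final_state(t1)), as.integer(fin))

  # and the caller's RNG stream is untouched
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(run_replicate(p))
  expect_identical(runif(1), before)
})

test_that("reproduction is fitness-weighted multinomial sampling", {
  # monomorphic states are fixed points
  p <- sim_params(N = 1000, n = 2)
  w <- build_fitness(p)
  mono <- c(0L, 0L, 1000L, 0L, 0L)  # all COM2
  expect_identical(selection_drift_step(mono, unname(w), p), mono)

  # neutral two-class state: next frequency has mean x, variance x(1-x)/N
  pn <- sim_params(N = 10000, n = 0)
  wn <- unname(build_fitness(pn))
  neutral <- c(0L, 5000L, 5000L)  # WT and CR, both fitness 1
  set.seed(31)
  freq <- replicate(10000, selection_drift_step(neutral, wn, pn)[[2]] / 10000)
  expect_lt(abs(mean(freq) - 0.5), 3 * sqrt(0.25 / 10000 / 10000))
  expect_lt(abs(var(freq) - 0.25 / 10000) / (0.25 / 10000), 0.15)

  # selected state: expected frequency q = x*w / sum(x*w)
  ps <- sim_params(N = 10000, n = 0, c = 0.15)
  ws <- unname(build_fitness(ps))
  state <- c(9900L, 100L, 0L)
  q_wt <- 100 * 1 / (100 * 1 + 9900 * 0.85)
  set.seed(32)
  freq_wt <- replicate(10000,
                       selection_drift_step(state, ws, ps)[[2]] / 10000)
  expect_lt(abs(mean(freq_wt) - q_wt),
            3 * sqrt(q_wt * (1 - q_wt) / 10000 / 10000))
})
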