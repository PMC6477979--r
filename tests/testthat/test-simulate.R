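test_that("pure-death SSA matches the binomial thinning closed form", {
  # death rate ln 2 per hour: after 1 h each molecule survives w.p. 1/2
  kern <- point_mass_kernel(1, 0.1)
  net <- make_imm_death_net(0, log(2), kern)
  hist <- trajectory(seq(-1, 0, by = 0.1), rep(10, 11))
  n_rep <- 400
  finals <- vapply(seq_len(n_rep), function(r) {
    tr <- delayed_ssa(net, hist, horizon = 1, seed = 5000 + r,
                      store_step = 0.1)
    tr$counts[nrow(tr$counts), 1]
  }, numeric(1))
  # Binomial(10, 1/2): mean 5, sd sqrt(2.5); 4 MC sigmas
  expect_lt(abs(mean(finals) - 5), 4 * sqrt(10 * 0.25 / n_rep))
  expect_lt(abs(var(finals) - 2.5), 1.0)
})

test_that("immigration-only SSA increments are Poisson", {
  kern <- point_mass_kernel(1, 0.1)
  net <- delayed_network(1, matrix(integer(0), 1, 0), matrix(1L, 1, 1),
                         function(u) numeric(0), function(x) 5,
                         kernels = list(kern))
  hist <- trajectory(seq(-1, 0, by = 0.1), rep(0, 11))
  n_rep <- 300
  finals <- vapply(seq_len(n_rep), function(r) {
    tr <- delayed_ssa(net, hist, horizon = 2, seed = 900 + r,
                      store_step = 0.1)
    tr$counts[nrow(tr$counts), 1]
  }, numeric(1))
  # Poisson(10): mean 10, var 10
  expect_lt(abs(mean(finals) - 10), 4 * sqrt(10 / n_rep))
  expect_lt(abs(var(finals) - 10), 3)
})

test_that("SSA is reproducible and respects preconditions", {
  p <- ttfl_params()
  net <- ttfl_network(p, grid_step = 0.1)
  hist <- trajectory(seq(-30, 0, by = 0.1), rep(100, 301))
  a <- delayed_ssa(net, hist, horizon = 5, seed = 1, store_step = 0.1)
  b <- delayed_ssa(net, hist, horizon = 5, seed = 1, store_step = 0.1)
  expect_identical(a$counts, b$counts)
  expect_error(delayed_ssa(net, hist, horizon = -1, seed = 1), "horizon")
  short <- trajectory(seq(-1, 0, by = 0.1), rep(100, 11))
  expect_error(delayed_ssa(net, short, horizon = 5, seed = 1,
                           store_step = 0.1), "history")
})

test_that("measurement process bins, rescales and injects calibrated noise", {
  tr <- trajectory(seq(0, 10, by = 0.01), rep(1, 1001))
  # constant count 1, no rescale: each 0.5 h bin sums 50 grid points
  os <- corrupt_measurements(tr, exposure = 0.5, snr = Inf, seed = 1,
                             rescale = FALSE)
  expect_equal(os$values, rep(50, 20))
  expect_equal(os$times, seq(0.5, 10, by = 0.5))
  # snr -> Inf reproduces the noise-free binned signal after rescaling
  ds <- quick_dataset(seed = 3, horizon = 40)
  s <- ds[[1]]
  expect_equal(length(s$values), 80)
  # noise sd is sd(signal)/snr by construction
  expect_equal(s$meta$sigma_eps, sd(s$meta$truth) / 100)
  resid <- s$values - s$meta$truth
  expect_lt(abs(sd(resid) / s$meta$sigma_eps - 1), 0.35)
  expect_error(corrupt_measurements(tr, snr = -2, seed = 1), "snr")
})

test_that("detrending inverts a linear decay factor", {
  os <- observed_series(seq(0.5, 120, by = 0.5), rep(10, 240), 0.5)
  expect_equal(detrend_series(os, 0)$values, os$values)
  f <- 1 - 0.3 * os$times / 120
  expect_equal(f[240], 0.7)
  damped <- observed_series(os$times, os$values * f, 0.5)
  expect_equal(detrend_series(damped, 0.3, 120)$values, os$values)
  steep <- observed_series(os$times, os$values, 0.5)
  expect_error(detrend_series(steep, 0.99, 100), "zero")
})

test_that("dataset generation is deterministic and oscillates", {
  d1 <- quick_dataset(n_rep = 2, seed = 21, horizon = 50)
  d2 <- quick_dataset(n_rep = 2, seed = 21, horizon = 50)
  expect_identical(d1[[2]]$values, d2[[2]]$values)
  expect_identical(generate_dataset(ttfl_params(), 0, 100, 1), list())
  # replicates differ from each other
  expect_gt(max(abs(d1[[1]]$values - d1[[2]]$values)), 1)
  # visible oscillation: wide dynamic range relative to the mean level
  expect_gt(max(d1[[1]]$values) / max(1, min(d1[[1]]$values)), 2)
})
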