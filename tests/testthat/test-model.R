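test_that("Hill repression has half-max at threshold and correct limits", {
  h <- hill_function(120, 100, 5)
  expect_equal(hill_transcription(100, h), 60)
  expect_equal(hill_transcription(0, h), 120)
  expect_lt(hill_transcription(1e6, h), 1e-10)
  # strictly decreasing
  u <- seq(0, 500, by = 5)
  expect_true(all(diff(hill_transcription(u, h)) < 0))
  # scale invariance: (u, K) -> (cu, cK)
  h2 <- hill_function(120, 250, 5)
  expect_equal(hill_transcription(2.5 * 40, h2), hill_transcription(40, h))
  expect_error(hill_transcription(-1, h), "u")
})

test_that("Hill gradient matches numerical differentiation", {
  h <- hill_function(87, 140, 3.2)
  for (u in c(0.5, 50, 140, 400)) {
    num <- (hill_transcription(u + 1e-6, h) - hill_transcription(u, h)) / 1e-6
    expect_equal(hill_gradient(u, h), num, tolerance = 1e-4)
  }
  expect_equal(hill_gradient(0, h), 0)
})

test_that("gamma delay kernel is a renormalized lattice density", {
  grid <- expand.grid(mean = c(2, 9.67, 15), sd = c(0.5, 3.56, 8))
  for (i in seq_len(nrow(grid))) {
    k <- make_gamma_kernel(grid$mean[i], grid$sd[i], 30, 0.1)
    expect_equal(sum(k$weights), 1)
    expect_length(k$weights, 301)
    expect_true(all(k$weights >= 0))
  }
  expect_error(make_gamma_kernel(5, 1, 30, 0.13), "divide")
  expect_warning(make_gamma_kernel(35, 1, 30, 0.5), "truncated")
})

test_that("kernel discrete mean matches the truncated-gamma quadrature oracle", {
  # oracle: fine-grid quadrature of the truncated, renormalized Gamma density
  mean <- 9.67; sd <- 3.56; tau_m <- 30
  shape <- (mean / sd)^2; scale <- sd^2 / mean
  xs <- seq(0, tau_m, length.out = 200001)
  dens <- dgamma(xs, shape, scale = scale)
  dens <- dens / (sum(dens) * diff(xs)[1])
  oracle_mean <- sum(xs * dens) * diff(xs)[1]
  for (dt in c(0.5, 0.1)) {
    k <- make_gamma_kernel(mean, sd, tau_m, dt)
    expect_lt(abs(kernel_discrete_mean(k) - oracle_mean), dt)
    expect_lt(abs(kernel_discrete_mean(k) - 9.67), dt)
  }
})

test_that("degenerate (tiny-sd) kernel collapses to the bin nearest the mean", {
  k <- make_gamma_kernel(mean = 4.3, sd = 0.05 / 10, max_lag = 30,
                         grid_step = 0.5)
  expect_equal(which.max(k$weights), round(4.3 / 0.5) + 1)
  expect_gt(max(k$weights), 1 - 1e-12)
  expect_equal(sum(k$weights), 1)
  kp <- point_mass_kernel(30, 0.5)
  expect_equal(kp$weights[1], 1)
  expect_equal(sum(kp$weights), 1)
})

test_that("TTFL network encodes delayed Hill production and linear death", {
  p <- ttfl_params()
  net <- ttfl_network(p, grid_step = 0.5)
  # empty state and empty past: only transcription fires, at R_max
  expect_equal(net$hazards_delayed(0) + net$hazards_plain(0), p$r_max)
  expect_equal(net$hazards_plain(0), 0)
  # drift g + f at state x with past integral u is nu(u) - mu x
  h <- hill_function(p$r_max, p$k_pc, p$n)
  for (x in c(10, 100)) for (u in c(20, 150)) {
    drift <- as.numeric(net$stoich_delayed %*% net$hazards_delayed(u) +
                          net$stoich_plain %*% net$hazards_plain(x))
    expect_equal(drift, hill_transcription(u, h) - p$mu * x)
  }
  expect_equal(ncol(net$stoich_delayed) + ncol(net$stoich_plain), 2)
})

test_that("TTFL drift has a unique positive fixed point found by bisection", {
  p <- ttfl_params()
  xs <- ttfl_fixed_point(p)
  h <- hill_function(p$r_max, p$k_pc, p$n)
  expect_gt(xs, 0)
  expect_equal(hill_transcription(xs, h), p$mu * xs, tolerance = 1e-8)
  # the net drift changes sign exactly once
  x <- seq(1, 300, by = 1)
  s <- sign(hill_transcription(x, h) - p$mu * x)
  expect_equal(sum(diff(s) != 0), 1)
})

test_that("parameter validation rejects non-positive and inconsistent values", {
  expect_error(ttfl_params(mu = -1), "positive")
  expect_error(ttfl_params(delay_mean = 31), "tau_max")
  expect_silent(ttfl_params(var_x0 = 5))
  expect_error(ttfl_params(var_x0 = -5), "var_x0")
})
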