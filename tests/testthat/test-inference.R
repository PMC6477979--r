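test_that("default priors match the documented specification", {
  pr <- default_priors(sigma_eps_center = 0.3)
  expect_identical(prior_logdensity(pr, "delay_mean", 24), -Inf)
  expect_identical(prior_logdensity(pr, "delay_mean", 11), -log(23))
  expect_identical(prior_logdensity(pr, "delay_sd", 21), -Inf)
  # log(n) prior is N(log 1.5, 5^2): mode density on the log scale
  expect_equal(prior_logdensity(pr, "n", 1.5),
               dnorm(log(1.5), log(1.5), 5, log = TRUE) - log(1.5))
  expect_equal(pr$mu$meanlog, log(0.58))
  expect_equal(pr$mu0$sdlog, 0.5)
  expect_equal(pr$sigma_eps$meanlog, log(0.3))
  expect_equal(pr$kappa$sdlog, 20)
  # every model parameter except tau_max is covered exactly once
  expect_setequal(names(pr),
                  setdiff(names(formals(ttfl_params)), "tau_max"))
})

test_that("prior densities integrate to one", {
  pr <- default_priors()
  # quadrature on the natural scale for a moderate-sd lognormal component
  int_mu <- integrate(function(x) exp(prior_logdensity(pr, "mu", x)),
                      0, Inf, rel.tol = 1e-9)$value
  expect_equal(int_mu, 1, tolerance = 1e-6)
  int_dm <- integrate(function(x)
    exp(vapply(x, function(v) prior_logdensity(pr, "delay_mean", v),
               numeric(1))), -5, 30)$value
  expect_equal(int_dm, 1, tolerance = 1e-6)
})

test_that("HPD intervals match closed forms", {
  set.seed(1)
  z <- rnorm(40000)
  h <- hpdi(z, 0.95)
  expect_equal(unname(h), c(-1.96, 1.96), tolerance = 0.05)
  expect_equal(unname(diff(hpdi(runif(20000), 0.95))), 0.95,
               tolerance = 0.01)
  hc <- hpdi(rep(3.3, 200), 0.9)
  expect_equal(unname(hc), c(3.3, 3.3))
  expect_error(hpdi(rnorm(50)), "100")
})

test_that("delayed acceptance with a coarse surrogate targets the fine posterior", {
  # toy conjugate-style posterior: y ~ N(m, exp(2 s)); coarse stage uses an
  # inflated-variance surrogate likelihood
  set.seed(3)
  y <- rnorm(40, 2, 1.5)
  logpost_fine <- function(th)
    sum(dnorm(y, th[1], exp(th[2]), log = TRUE)) +
      dnorm(th[1], 0, 10, log = TRUE) + dnorm(th[2], 0, 2, log = TRUE)
  logpost_coarse <- function(th)
    sum(dnorm(y, th[1], 1.6 * exp(th[2]), log = TRUE)) +
      dnorm(th[1], 0, 10, log = TRUE) + dnorm(th[2], 0, 2, log = TRUE)
  da <- da_sampler(logpost_coarse, logpost_fine, c(0, 0), 60000, seed = 1)
  mh <- da_sampler(logpost_fine, logpost_fine, c(0, 0), 60000, seed = 2)
  qs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  for (j in 1:2) {
    qa <- quantile(da$samples[30001:60000, j], qs)
    qb <- quantile(mh$samples[30001:60000, j], qs)
    expect_equal(unname(qa), unname(qb), tolerance = 0.08)
  }
  expect_gte(da$accept_stage1, da$accept_overall)
  # degenerate two-stage sampler (coarse == fine) never rejects at stage 2
  expect_equal(mh$accept_stage1, mh$accept_overall)
})

test_that("data-free chains recover the prior", {
  ds <- quick_dataset(seed = 5, horizon = 35)
  pr <- default_priors()
  ch <- delayed_acceptance_mcmc(
    ds[[1]], pr, n_iter = 60000, seed = 9, dt_coarse = 0.5, dt_fine = 0.5,
    sample_params = c("delay_mean", "delay_sd", "mu"),
    use_data = FALSE, reparam_kappa = FALSE)
  post <- ch$samples[30001:60000, ]
  # uniform prior on (0, 23): mean 11.5, sd 6.64
  expect_equal(mean(post[, "delay_mean"]), 11.5, tolerance = 0.1)
  expect_equal(sd(post[, "delay_mean"]), 23 / sqrt(12), tolerance = 0.1)
  # lognormal(log 0.58, 0.5) prior on mu: median 0.58
  expect_equal(median(post[, "mu"]), 0.58, tolerance = 0.1)
  expect_equal(sd(log(post[, "mu"])), 0.5, tolerance = 0.1)
})

test_that("chain screening excludes stuck and divergent chains", {
  set.seed(8)
  mk <- function(x, lp = rep(0, length(x))) {
    structure(list(samples = matrix(x, ncol = 1,
                                    dimnames = list(NULL, "mu")),
                   lp_fine = lp), class = "chain_result")
  }
  good1 <- mk(rlnorm(2000, 0, 0.1))
  good2 <- mk(rlnorm(2000, 0, 0.1))
  s <- posterior_summaries(list(good1, good2), burn_in = 0.5)
  expect_length(attr(s, "excluded"), 0)
  expect_equal(s$mean[1], 1, tolerance = 0.05)
  expect_true(all(c("parameter", "mean", "sd", "hpdi_lo", "hpdi_hi")
                  %in% names(s)))
  # a drifting chain (two halves far apart) is flagged by split-Rhat
  drift <- mk(c(rlnorm(1500, 0, 0.1), rlnorm(500, 3, 0.1)))
  s2 <- posterior_summaries(list(good1, good2, drift))
  expect_true(3 %in% attr(s2, "excluded"))
  # a chain stuck at a single point is flagged too
  stuck <- mk(rep(2.5, 2000))
  s3 <- posterior_summaries(list(good1, stuck))
  expect_true(2 %in% attr(s3, "excluded"))
  # a stationary chain in a clearly worse mode is dropped by the
  # mode-agreement rule (lower mean log-posterior)
  minor <- mk(rlnorm(2000, 4, 0.1), lp = rep(-500, 2000))
  s4 <- posterior_summaries(list(good1, good2, minor))
  expect_true(3 %in% attr(s4, "excluded"))
  expect_error(posterior_summaries(list(stuck)), "all chains")
})
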