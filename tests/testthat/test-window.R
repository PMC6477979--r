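make_full_window <- function(M, level, v_last, dt) {
  cov <- matrix(0, M + 1, M + 1)
  cov[M + 1, M + 1] <- v_last
  window_state(seq(-M * dt, 0, by = dt), rep(level, M + 1), cov, 1)
}

test_that("point-mass kernel reduces the window filter to the plain LNA", {
  # 200 propagation steps of the nonlinear feedback model with all delay
  # mass at lag 0 must reproduce the non-delayed moment ODE solution
  p <- ttfl_params()
  dt <- 0.1
  M <- 20
  h <- hill_function(p$r_max, p$k_pc, p$n)
  net <- delayed_network(
    1, matrix(1L, 1, 1), matrix(-1L, 1, 1),
    function(u) hill_transcription(u, h), function(x) p$mu * x,
    kernels = list(point_mass_kernel(M * dt, dt)),
    jac_delayed = function(u) matrix(hill_gradient(u, h), 1, 1),
    jac_plain = function(x) matrix(p$mu, 1, 1))
  mdl <- lna_model(function(x) hill_transcription(x, h) - p$mu * x,
                   function(x) matrix(hill_gradient(x, h) - p$mu, 1, 1),
                   function(x) matrix(hill_transcription(x, h) + p$mu * x,
                                      1, 1))
  w <- make_full_window(M, 50, 4, dt)
  st <- gaussian_state(50, matrix(4, 1, 1))
  for (s in 1:200) {
    w <- propagate_window(w, net, dt)
    st <- lna_propagate(st, mdl, 0, dt, dt)
    i <- M + 1
    expect_equal(w$mean[i], st$mean, tolerance = 1e-8)
    expect_equal(w$cov[i, i], st$cov[1, 1], tolerance = 1e-8)
  }
})

test_that("zero hazards shift the window and leave retained moments unchanged", {
  net <- delayed_network(
    1, matrix(integer(0), 1, 0), matrix(0L, 1, 1),
    function(u) numeric(0), function(x) 0,
    kernels = list(point_mass_kernel(1, 0.25)),
    jac_delayed = function(u) matrix(numeric(0), 0, 1),
    jac_plain = function(x) matrix(0, 1, 1))
  cov0 <- crossprod(matrix(rnorm(25, sd = 0.5), 5, 5)) + diag(5)
  w <- window_state(seq(-1, 0, by = 0.25), 1:5, cov0, 1)
  w2 <- propagate_window(w, net, 0.25)
  expect_equal(w2$mean, c(2, 3, 4, 5, 5))
  expect_equal(w2$cov[1:4, 1:4], cov0[2:5, 2:5], ignore_attr = TRUE)
  expect_equal(w2$cov[5, 1:4], cov0[5, 2:5], ignore_attr = TRUE)
  expect_equal(w2$cov[5, 5], cov0[5, 5])
})

test_that("linear delayed hazard: window recursion equals the augmented Kalman oracle", {
  dt <- 0.25; tau_m <- 2; M <- 8
  kern <- make_gamma_kernel(1, 0.4, tau_m, dt)
  a <- 10; b <- 0.05; mu <- 0.3
  net <- make_linear_delayed_net(a, b, mu, kern)
  L <- 2                      # observation every 0.5 h
  kappa <- 0.7; nv <- 0.4
  fw <- kappa * dt * c(0.5, 1, 0.5)
  f <- c(numeric(M - L), fw)
  set.seed(4)
  y <- rnorm(12, 5, 1)
  m0 <- rep(20, M + 1)
  V0 <- diag(4, M + 1)
  oracle <- kf_affine_oracle(y, steps_per_obs = L,
                             make_step = linear_window_step(M, dt, a, b, mu,
                                                            kern$weights),
                             f = f, nv = nv, m0 = m0, V0 = V0)
  w <- window_state(seq(-tau_m, 0, by = dt), m0, V0, 1)
  ll <- 0
  for (k in seq_along(y)) {
    for (s in 1:L) w <- propagate_window(w, net, dt)
    Pf <- as.numeric(w$cov %*% f)
    S <- sum(f * Pf) + nv
    ll <- ll + dnorm(y[k], sum(f * w$mean), sqrt(S), log = TRUE)
    w <- delayed_kalman_update(w, f, y[k], noise_var = nv)
  }
  expect_equal(ll, oracle$loglik, tolerance = 1e-10)
  expect_equal(w$mean, oracle$filt_mean[[length(y)]], tolerance = 1e-8)
  expect_equal(max(abs(w$cov - oracle$filt_cov[[length(y)]])), 0,
               tolerance = 1e-8)
})

test_that("window update implements exact joint-Gaussian conditioning", {
  set.seed(9)
  A <- matrix(rnorm(36), 6, 6)
  cov0 <- crossprod(A) + diag(6)
  w <- window_state(seq(-2.5, 0, by = 0.5), rnorm(6, 10), cov0, 1)
  # infinite noise: zero gain
  w_inf <- delayed_kalman_update(w, c(0, 0, 0, 0, 0, 1), 25,
                                 noise_var = 1e14)
  expect_equal(w_inf$mean, w$mean, tolerance = 1e-10)
  # observation touching only the trailing state: trailing marginal matches
  # the scalar Kalman restart
  f <- c(0, 0, 0, 0, 0, 1.3)
  y <- 17
  up <- delayed_kalman_update(w, f, y, noise_var = 0.6)
  sc <- kalman_update(gaussian_state(w$mean[6], w$cov[6, 6, drop = FALSE]),
                      measurement_model(matrix(1.3), matrix(0.6)), y)
  expect_equal(up$mean[6], sc$mean, tolerance = 1e-12)
  expect_equal(up$cov[6, 6], sc$cov[1, 1], tolerance = 1e-12)
  # exact scalar observation of the current state: pinning plus Gaussian
  # regression of the past lags
  upe <- delayed_kalman_update(w, c(0, 0, 0, 0, 0, 1), y, noise_var = 0)
  expect_equal(upe$mean[6], y)
  expect_equal(upe$cov[6, 6], 0)
  expect_equal(upe$mean[1:5],
               w$mean[1:5] + w$cov[1:5, 6] / w$cov[6, 6] * (y - w$mean[6]),
               tolerance = 1e-12)
  expect_error(delayed_kalman_update(w, c(0, 0, 0, 0, 0, 0), 1,
                                     noise_var = 0), "innovation")
})

test_that("initial window matches an augmented-state Kalman oracle", {
  # oracle: a fixed-dimension Kalman filter over the full lattice vector
  # (X_0, ..., X_M) in which step s "gives birth" to component s + 1 via the
  # birth-death transition, observations acting through per-bin rows
  p <- ttfl_params(init_rate = 40, mu0 = 0.5, beta = 2, kappa = 0.9,
                   sigma_eps = 0.7, tau_max = 2, delay_mean = 1,
                   delay_sd = 0.4)
  dt <- 0.25; M <- 8; L <- 2; ex <- 0.5
  y <- c(21, 19, 23, 20)
  head <- observed_series(seq(0.5, 2, by = 0.5), y, ex)
  got <- init_window(head, p, dt)
  m0 <- y[1] / (p$kappa * ex)
  v0 <- p$beta * m0
  al <- 1 - p$mu0 * dt
  make_step <- function(m, s) {
    A <- diag(M + 1)
    A[s + 1, s + 1] <- 0
    A[s + 1, s] <- al
    cc <- numeric(M + 1); cc[s + 1] <- p$init_rate * dt
    Q <- matrix(0, M + 1, M + 1)
    Q[s + 1, s + 1] <- (p$init_rate + p$mu0 * max(m[s], 0)) * dt
    list(A = A, c = cc, Q = Q)
  }
  f_rows <- matrix(0, length(y), M + 1)
  for (k in seq_along(y))
    f_rows[k, (k * L - L + 1):(k * L + 1)] <- p$kappa * dt * c(0.5, 1, 0.5)
  mm0 <- c(m0, numeric(M))
  VV0 <- matrix(0, M + 1, M + 1); VV0[1, 1] <- v0
  oracle <- kf_affine_oracle(y, steps_per_obs = L, make_step = make_step,
                             f = f_rows, nv = p$sigma_eps^2,
                             m0 = mm0, V0 = VV0)
  expect_equal(got$loglik, oracle$loglik, tolerance = 1e-10)
  expect_equal(got$window$mean, oracle$filt_mean[[length(y)]],
               tolerance = 1e-8)
  expect_equal(max(abs(got$window$cov - oracle$filt_cov[[length(y)]])), 0,
               tolerance = 1e-8)
})

test_that("with uninformative data the initial window is the prior LNA law", {
  p <- ttfl_params(init_rate = 40, mu0 = 0.5, beta = 2, kappa = 1,
                   sigma_eps = 1e8, tau_max = 2, delay_mean = 1,
                   delay_sd = 0.4)
  head <- observed_series(seq(0.5, 2, by = 0.5), c(10, 10, 10, 10), 0.5)
  got <- init_window(head, p, dt = 0.1)
  m0 <- 10 / 0.5
  mdl <- lna_model(function(x) p$init_rate - p$mu0 * x,
                   function(x) matrix(-p$mu0, 1, 1),
                   function(x) matrix(p$init_rate + p$mu0 * max(x, 0), 1, 1))
  prior <- lna_propagate(gaussian_state(m0, matrix(p$beta * m0, 1, 1)),
                         mdl, 0, 2, 0.1)
  i <- length(got$window$mean)
  expect_equal(got$window$mean[i], prior$mean, tolerance = 1e-6)
  expect_equal(got$window$cov[i, i], prior$cov[1, 1], tolerance = 1e-6)
})

test_that("compiled and reference filters agree to numerical precision", {
  ds <- quick_dataset(seed = 31, horizon = 60)
  s <- ds[[1]]
  pt <- true_params_of(s)
  for (dt in c(0.5, 0.1)) {
    fc <- filter_loglik(s, pt, dt, engine = "cpp")
    fr <- filter_loglik(s, pt, dt, engine = "r")
    expect_equal(fc$loglik, fr$loglik, tolerance = 1e-10)
    expect_equal(fc$predictive$mean, fr$predictive$mean, tolerance = 1e-9)
    expect_equal(fc$predictive$sd_obs, fr$predictive$sd_obs,
                 tolerance = 1e-9)
    expect_equal(fc$smoothing$mean, fr$smoothing$mean, tolerance = 1e-9)
    expect_equal(fc$smoothing$sd, fr$smoothing$sd, tolerance = 1e-9)
  }
})

test_that("window covariance stays symmetric and PSD along a filtered run", {
  ds <- quick_dataset(seed = 13, horizon = 45)
  s <- ds[[1]]
  pt <- true_params_of(s)
  fr <- filter_loglik(s, pt, dt = 0.5, engine = "r")
  W <- fr$window$cov
  expect_equal(W, t(W))
  expect_gt(min(eigen(W, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  # partial smoothing never widens the one-step predictive interval
  post <- fr$predictive$phase == "filter"
  expect_true(all(fr$smoothing$sd[post] <=
                    fr$predictive$sd_signal[post] + 1e-9))
})

test_that("degenerate-kernel filter likelihood equals the plain EKBF", {
  # window machinery with all delay mass at lag 0 and a current-state-only
  # observation row reproduces the non-delayed filter likelihood
  p <- ttfl_params()
  dt <- 0.25; M <- 8
  h <- hill_function(p$r_max, p$k_pc, p$n)
  net <- delayed_network(
    1, matrix(1L, 1, 1), matrix(-1L, 1, 1),
    function(u) hill_transcription(u, h), function(x) p$mu * x,
    kernels = list(point_mass_kernel(M * dt, dt)),
    jac_delayed = function(u) matrix(hill_gradient(u, h), 1, 1),
    jac_plain = function(x) matrix(p$mu, 1, 1))
  mdl <- lna_model(function(x) hill_transcription(x, h) - p$mu * x,
                   function(x) matrix(hill_gradient(x, h) - p$mu, 1, 1),
                   function(x) matrix(hill_transcription(x, h) + p$mu * x,
                                      1, 1))
  set.seed(6)
  y <- rnorm(20, 100, 10)
  series <- observed_series(seq(0.5, 10, by = 0.5), y, 0.5)
  base <- ekbf_loglik(series, mdl,
                      measurement_model(matrix(1, 1, 1), matrix(25, 1, 1)),
                      gaussian_state(100, matrix(50, 1, 1)), dt)
  w <- make_full_window(M, 100, 50, dt)
  f <- c(numeric(M), 1)
  ll <- 0
  for (k in seq_along(y)) {
    for (s in 1:2) w <- propagate_window(w, net, dt)
    S <- as.numeric(f %*% w$cov %*% f) + 25
    ll <- ll + dnorm(y[k], sum(f * w$mean), sqrt(S), log = TRUE)
    w <- delayed_kalman_update(w, f, y[k], noise_var = 25)
  }
  expect_equal(ll, base$loglik, tolerance = 1e-8)
})

test_that("window propagation cost grows superlinearly with window length", {
  p <- ttfl_params()
  step_time <- function(m, dt) {
    net <- ttfl_network(p, grid_step = dt)
    net$kernels[[1]] <- make_gamma_kernel(p$delay_mean, p$delay_sd,
                                          m * dt, dt)
    w <- make_full_window(m, 100, 25, dt)
    t <- vapply(1:30, function(i) {
      t0 <- Sys.time()
      w <<- propagate_window(w, net, dt)
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    }, numeric(1))
    median(t)
  }
  # 101 -> 401 lattice points: linear cost predicts x4, quadratic ~x16
  ratio <- step_time(400, 0.1) / step_time(100, 0.1)
  expect_gt(ratio, 6)
})
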