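# Independent brute-force oracles used to validate the filter machinery.

# Discrete-time affine Kalman filter on a (possibly stacked) state vector.
# make_step(m, s) returns list(A, c, Q) for global propagation step s,
# evaluated at the current mean m (the moment recursions of an
# affine-Gaussian system with mean-dependent process noise). Observation k
# uses row f (a vector, or a matrix with one row per observation) and noise
# variance nv.
kf_affine_oracle <- function(y, steps_per_obs, make_step, f, nv, m0, V0) {
  if (is.null(dim(f))) f <- matrix(f, length(y), length(f), byrow = TRUE)
  m <- m0
  V <- as.matrix(V0)
  ll <- 0
  s_global <- 0L
  pred <- matrix(NA_real_, length(y), 2)
  filt_mean <- vector("list", length(y))
  filt_cov <- vector("list", length(y))
  for (k in seq_along(y)) {
    for (s in seq_len(steps_per_obs)) {
      s_global <- s_global + 1L
      st <- make_step(m, s_global)
      m <- as.numeric(st$A %*% m + st$c)
      V <- st$A %*% V %*% t(st$A) + st$Q
      V <- (V + t(V)) / 2
    }
    fk <- f[k, ]
    mu_y <- sum(fk * m)
    S <- as.numeric(fk %*% V %*% fk) + nv
    ll <- ll + dnorm(y[k], mu_y, sqrt(S), log = TRUE)
    pred[k, ] <- c(mu_y, S)
    Vf <- as.numeric(V %*% fk)
    m <- m + Vf * (y[k] - mu_y) / S
    V <- V - tcrossprod(Vf) / S
    filt_mean[[k]] <- m
    filt_cov[[k]] <- V
  }
  list(loglik = ll, predictive = pred, filt_mean = filt_mean,
       filt_cov = filt_cov)
}

# One-step affine map of the stacked delay-window vector for a single-species
# network with linear delayed hazard a - b*u and linear death mu*x; matches
# the Euler-discretized delayed moment propagation analytically.
linear_window_step <- function(M, dt, a, b, mu, kern_w) {
  kwrev <- rev(kern_w)                       # weight per window position
  arow <- dt * (-b) * kwrev
  arow[M + 1] <- arow[M + 1] + 1 - mu * dt
  A <- rbind(cbind(matrix(0, M, 1), diag(M)), arow)
  cc <- c(numeric(M), a * dt)
  function(m, s) {
    u <- sum(kwrev * m)
    Q <- matrix(0, M + 1, M + 1)
    Q[M + 1, M + 1] <- ((a - b * u) + mu * m[M + 1]) * dt
    list(A = A, c = cc, Q = Q)
  }
}

# linear delayed network: production hazard a - b*u (kept positive on the
# test trajectories), death mu*x
make_linear_delayed_net <- function(a, b, mu, kern) {
  delayed_network(
    n_species = 1,
    stoich_delayed = matrix(1L, 1, 1),
    stoich_plain = matrix(-1L, 1, 1),
    hazards_delayed = function(u) a - b * u,
    hazards_plain = function(x) mu * x,
    kernels = list(kern),
    jac_delayed = function(u) matrix(-b, 1, 1),
    jac_plain = function(x) matrix(mu, 1, 1))
}

# immigration-death network without delays (point-mass kernel)
make_imm_death_net <- function(rate, mu, kern) {
  delayed_network(
    n_species = 1,
    stoich_delayed = matrix(integer(0), 1, 0),
    stoich_plain = matrix(c(1L, -1L), 1, 2),
    hazards_delayed = function(u) numeric(0),
    hazards_plain = function(x) c(rate, mu * x),
    kernels = list(kern),
    jac_delayed = function(u) matrix(numeric(0), 0, 1),
    jac_plain = function(x) matrix(c(0, mu), 2, 1))
}

# small simulated TTFL dataset shared across tests
quick_dataset <- function(n_rep = 1, seed = 11, horizon = 60, snr = 100) {
  generate_dataset(ttfl_params(), n_rep = n_rep, snr = snr, seed = seed,
                   horizon = horizon)
}

true_params_of <- function(series, base = ttfl_params()) {
  do.call(ttfl_params, modifyList(unclass(base),
                                  series$meta[c("kappa", "sigma_eps")]))
}
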