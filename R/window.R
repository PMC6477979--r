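#' Joint Gaussian window state
#'
#' Gaussian summary (mean and full covariance) of the unobserved state over
#' the sliding delay window `[t - tau_m, t]` on a `dt` lattice. With p
#' species and m + 1 lattice points, the mean has length `(m+1) * p` and the
#' covariance is square of that size; lattice point j, species i occupies
#' entry `(j-1)*p + i`, the newest time occupying the trailing block.
#'
#' @param grid_times lattice times (hours), equally spaced, newest last.
#' @param mean stacked mean vector.
#' @param cov stacked covariance matrix (symmetrized).
#' @param p species count.
#' @return Object of class `window_state`.
#' @export
window_state <- function(grid_times, mean, cov, p = 1) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(length(mean) == length(grid_times) * p,
            all(dim(cov) == length(mean)))
  structure(list(grid_times = as.numeric(grid_times), mean = mean,
                 cov = (cov + t(cov)) / 2, p = p), class = "window_state")
}

#' @export
print.window_state <- function(x, ...) {
  cat(sprintf("<window_state> %d lattice points x %d species, t in [%g, %g] h\n",
              length(x$grid_times), x$p, min(x$grid_times), max(x$grid_times)))
  invisible(x)
}

#' Window observation descriptor
#'
#' A single light-intensity observation acting linearly on the window
#' vector: `y = obs_row . window + eps`, `eps ~ N(0, noise_var)`. For the
#' integrated-light model the row is non-zero only on the trailing exposure
#' sub-block.
#'
#' @param obs_row numeric vector over the window (includes the scale kappa).
#' @param noise_var measurement noise variance (intensity^2).
#' @return Object of class `window_measurement`.
#' @export
window_measurement <- function(obs_row, noise_var) {
  stopifnot(noise_var >= 0)
  structure(list(obs_row = as.numeric(obs_row), noise_var = noise_var),
            class = "window_measurement")
}

# integrated-light observation weights over the trailing exposure sub-block:
# kappa * integral_{t-Delta}^{t} X ds discretized on the dt lattice
exposure_weights <- function(kappa, dt, n_sub,
                             scheme = c("trapezoid", "riemann")) {
  scheme <- match.arg(scheme)
  if (scheme == "trapezoid") kappa * dt * c(0.5, rep(1, n_sub - 1), 0.5)
  else c(0, rep(kappa * dt, n_sub)) # right Riemann sum on the same block
}

#' One Euler step of the delayed LNA window propagation
#'
#' Advances the joint Gaussian window law by one lattice step `dt` under the
#' linearized delayed chemical Langevin dynamics. Writing `u` for the
#' kernel-weighted window mean (the discrete delayed integral), the new
#' state's mean is `rho_t + [g(rho_t) + f(u)] dt` and the window evolves
#' under the affine map obtained from first-order expansion of the plain
#' hazards about `rho_t` and of the delayed hazards about `u`, with process
#' noise variance `[l(rho_t) + q(u)] dt`. The new cross-covariance row, the
#' new marginal variance, and (unless `grow = TRUE`) the drop of the oldest
#' lattice point follow.
#'
#' @param w a [window_state()].
#' @param net a [delayed_network()] whose kernels live on the same `dt`
#'   lattice as the window.
#' @param dt lattice step (hours); must equal the window grid step.
#' @param grow keep the oldest point (used while building the initial
#'   window); only valid for networks without delayed reactions.
#' @return The advanced [window_state()].
#' @export
propagate_window <- function(w, net, dt, grow = FALSE) {
  stopifnot(inherits(w, "window_state"), inherits(net, "delayed_network"))
  p <- net$n_species
  stopifnot(p == w$p)
  L <- length(w$grid_times)
  if (L > 1 && abs(diff(w$grid_times)[1] - dt) > 1e-9)
    stop("propagate_window: dt must equal the window grid step")
  n_d <- ncol(net$stoich_delayed)
  if (n_d > 0) {
    ks <- net$kernels[[1]]
    if (abs(ks$grid_step - dt) > 1e-9)
      stop("propagate_window: kernel grid step must equal dt")
    if (L != round(ks$max_lag / dt) + 1)
      stop("propagate_window: window must span the full maximum lag")
    if (grow) stop("propagate_window: cannot grow a delayed window")
  }
  rho <- w$mean
  P <- w$cov
  idx_last <- ((L - 1) * p + 1):(L * p)
  x_t <- rho[idx_last]
  # discrete delayed integral: u_i = sum_j K_i(lag_j) rho_i(t - lag_j)
  if (n_d > 0) {
    u <- vapply(seq_len(p), function(i) {
      wk <- net$kernels[[i]]$weights      # lag order 0..m
      sum(wk * rho[seq.int(L, 1) * p - p + i][seq_len(length(wk))])
    }, numeric(1))
    hd <- pmax(net$hazards_delayed(u), 0)
    Jd <- net$jac_delayed(u)
  } else {
    u <- numeric(0)
    hd <- numeric(0)
  }
  hp <- pmax(net$hazards_plain(x_t), 0)
  Jp <- net$jac_plain(x_t)
  drift <- as.numeric(net$stoich_plain %*% hp) +
    (if (n_d > 0) as.numeric(net$stoich_delayed %*% hd) else 0)
  mean_new <- x_t + drift * dt
  # affine map of the stacked window vector onto the new state
  A <- matrix(0, p, L * p)
  A[, idx_last] <- diag(p) + dt * (net$stoich_plain %*% Jp)
  if (n_d > 0) {
    SJ <- dt * (net$stoich_delayed %*% Jd)       # p x p
    for (i in seq_len(p)) {
      wk <- net$kernels[[i]]$weights
      cols <- (seq.int(L, L - length(wk) + 1) - 1) * p + i
      A[, cols] <- A[, cols] + outer(SJ[, i], wk)
    }
  }
  Q <- dt * (net$stoich_plain %*% (hp * t(net$stoich_plain)))
  if (n_d > 0)
    Q <- Q + dt * (net$stoich_delayed %*% (hd * t(net$stoich_delayed)))
  r <- P %*% t(A)                                # (L p) x p
  v_new <- A %*% r + Q
  mean_full <- c(rho, mean_new)
  cov_full <- rbind(cbind(P, r), cbind(t(r), (v_new + t(v_new)) / 2))
  t_new <- w$grid_times[L] + dt
  if (grow) {
    window_state(c(w$grid_times, t_new), mean_full, cov_full, p)
  } else {
    keep <- (p + 1):((L + 1) * p)
    window_state(c(w$grid_times[-1], t_new), mean_full[keep],
                 cov_full[keep, keep, drop = FALSE], p)
  }
}

#' Window-wide Kalman update
#'
#' Conditions the joint Gaussian window law on one observation, revising
#' every lattice point back to `t - tau_m`: with coefficient of adaptation
#' `C = P f' / (f P f' + noise_var)`, the mean becomes
#' `rho + C (y - f . rho)` and the covariance `P - C (f P)`.
#'
#' @param w a [window_state()].
#' @param m a [window_measurement()] (or a bare numeric `obs_row`, in which
#'   case `noise_var` must be given).
#' @param y scalar observation.
#' @param noise_var measurement noise variance if `m` is a bare vector.
#' @return The updated [window_state()].
#' @export
delayed_kalman_update <- function(w, m, y, noise_var = NULL) {
  stopifnot(inherits(w, "window_state"))
  if (inherits(m, "window_measurement")) {
    f <- m$obs_row
    nv <- m$noise_var
  } else {
    f <- as.numeric(m)
    if (is.null(noise_var)) stop("delayed_kalman_update: noise_var required")
    nv <- noise_var
  }
  stopifnot(length(f) == length(w$mean))
  Pf <- as.numeric(w$cov %*% f)
  S <- sum(f * Pf) + nv
  if (S <= 0)
    stop("delayed_kalman_update: non-positive innovation variance")
  mean_new <- w$mean + Pf * (y - sum(f * w$mean)) / S
  cov_new <- w$cov - tcrossprod(Pf) / S
  window_state(w$grid_times, mean_new, cov_new, w$p)
}

# birth-death initialization network: constant transcription init_rate and
# degradation mu0, no delayed reactions
init_network <- function(init_rate, mu0, tau_max, dt) {
  delayed_network(
    n_species = 1,
    stoich_delayed = matrix(integer(0), 1, 0),
    stoich_plain = matrix(c(1L, -1L), 1, 2),
    hazards_delayed = function(u) numeric(0),
    hazards_plain = function(x) c(init_rate, mu0 * max(x, 0)),
    kernels = list(point_mass_kernel(tau_max, dt)),
    jac_delayed = function(u) matrix(numeric(0), 0, 1),
    jac_plain = function(x) matrix(c(0, if (x >= 0) mu0 else 0), 2, 1))
}

#' Initial window over `[0, tau_m]`
#'
#' Models the initialization stretch as a linear birth-death process with
#' constant (step-function) transcription `init_rate` and degradation `mu0`,
#' starting from a prior with mean `x0_mean` (by default the first
#' observation de-integrated by `kappa * exposure`) and variance
#' `beta * x0_mean` (or `var_x0` if given). The window is grown one lattice
#' point at a time while the head observations are assimilated, accumulating
#' their likelihood contribution and the full joint window covariance at
#' time `tau_m`.
#'
#' @param series_head an [observed_series()] whose times cover exactly
#'   `(0, tau_max]`.
#' @param params a [ttfl_params()].
#' @param dt lattice step (hours); must divide the exposure and `tau_max`.
#' @param obs_scheme discretization of the integrated-light observation row:
#'   `"trapezoid"` (default) or `"riemann"`.
#' @return List with `window` (a [window_state()] at time `tau_max`),
#'   `loglik` (head-data contribution) and `predictive` (per-head-observation
#'   innovation moments).
#' @export
init_window <- function(series_head, params, dt,
                        obs_scheme = c("trapezoid", "riemann")) {
  stopifnot(inherits(series_head, "observed_series"),
            inherits(params, "ttfl_params"))
  obs_scheme <- match.arg(obs_scheme)
  ex <- series_head$exposure
  L <- check_divides(ex, dt, "exposure")
  M <- check_divides(params$tau_max, dt, "tau_max")
  n_head <- round(params$tau_max / ex)
  if (length(series_head$times) < n_head ||
      abs(series_head$times[n_head] - params$tau_max) > 1e-8)
    stop("init_window: series head must cover exactly (0, tau_max]")
  x0_mean <- series_head$values[1] / (params$kappa * ex)
  if (!is.finite(x0_mean) || x0_mean <= 0) x0_mean <- 1e-3
  v0 <- if (is.na(params$var_x0)) params$beta * x0_mean else params$var_x0
  net0 <- init_network(params$init_rate, params$mu0, params$tau_max, dt)
  w <- window_state(0, x0_mean, matrix(v0, 1, 1), 1)
  fw <- exposure_weights(params$kappa, dt, L, obs_scheme)
  nv <- params$sigma_eps^2
  ll <- 0
  pred <- matrix(NA_real_, n_head, 3,
                 dimnames = list(NULL, c("time", "mean", "var")))
  for (s in seq_len(M)) {
    w <- propagate_window(w, net0, dt, grow = TRUE)
    if (s %% L == 0) {
      k <- s %/% L
      f_full <- c(numeric(s + 1 - length(fw)), fw)
      Pf <- as.numeric(w$cov %*% f_full)
      mu_y <- sum(f_full * w$mean)
      S <- sum(f_full * Pf) + nv
      ll <- ll + dnorm(series_head$values[k], mu_y, sqrt(S), log = TRUE)
      pred[k, ] <- c(k * ex, mu_y, S)
      w <- delayed_kalman_update(w, f_full, series_head$values[k],
                                 noise_var = nv)
    }
  }
  list(window = w, loglik = ll, predictive = as.data.frame(pred))
}

check_divides <- function(whole, part, what) {
  r <- whole / part
  if (abs(r - round(r)) > 1e-8)
    stop(sprintf("dt must divide %s (%g / %g)", what, whole, part))
  round(r)
}

#' Delayed LNA filter: marginal likelihood and moment summaries
#'
#' Runs the full delayed extended Kalman-Bucy filter for the TTFL model on
#' an observed series: initialization over `[0, tau_max]` via
#' [init_window()], then, for each subsequent observation, `exposure/dt`
#' window propagation steps, accumulation of the Gaussian innovation
#' log-density (mean `f . rho`, variance `f P f' + sigma_eps^2`) and a
#' window-wide Kalman update. Returns the total marginal log-likelihood,
#' one-step predictive moments per observation, and the partial-smoothing
#' moments of each exposure bin (its moments the last time its lattice
#' points were jointly inside the sliding window).
#'
#' @param series an [observed_series()] spanning more than `tau_max`.
#' @param params a [ttfl_params()]; `kappa` and `sigma_eps` are taken from
#'   here (not from the series metadata).
#' @param dt lattice step (hours); must divide the exposure and `tau_max`.
#'   Working values 0.5 and 0.1; default 0.1.
#' @param engine `"cpp"` (fast compiled path, default) or `"r"` (reference
#'   implementation built on [propagate_window()] /
#'   [delayed_kalman_update()]).
#' @param obs_scheme `"trapezoid"` (default) or `"riemann"` integration
#'   weights for the exposure integral.
#' @return List with elements `loglik`; `predictive` (data frame: `time`,
#'   `mean`, `sd_signal` = predictive SD of the noise-free integrated
#'   signal, `sd_obs` = predictive SD of the observation, `phase` = "init"
#'   or "filter"); and `smoothing` (data frame: `time`, `mean`, `sd` on the
#'   integrated-signal scale).
#' @export
filter_loglik <- function(series, params, dt = 0.1,
                          engine = c("cpp", "r"),
                          obs_scheme = c("trapezoid", "riemann")) {
  stopifnot(inherits(series, "observed_series"),
            inherits(params, "ttfl_params"))
  engine <- match.arg(engine)
  obs_scheme <- match.arg(obs_scheme)
  ex <- series$exposure
  L <- check_divides(ex, dt, "exposure")
  M <- check_divides(params$tau_max, dt, "tau_max")
  n <- length(series$values)
  n_head <- round(params$tau_max / ex)
  if (n <= n_head)
    stop("filter_loglik: series must span more than tau_max")
  if (abs(series$times[1] - ex) > 1e-8)
    stop("filter_loglik: first observation must stamp the end of the first ",
         "exposure bin (time = exposure)")
  if (engine == "cpp") {
    kern <- make_gamma_kernel(params$delay_mean, params$delay_sd,
                              params$tau_max, dt)
    x0_mean <- series$values[1] / (params$kappa * ex)
    if (!is.finite(x0_mean) || x0_mean <= 0) x0_mean <- 1e-3
    v0 <- if (is.na(params$var_x0)) params$beta * x0_mean else params$var_x0
    res <- dlna_filter_cpp(series$values, ex, dt, params$tau_max,
                           params$r_max, params$k_pc, params$n, params$mu,
                           kern$weights, params$kappa, params$sigma_eps,
                           params$init_rate, params$mu0, x0_mean, v0,
                           obs_scheme == "trapezoid")
    pred <- data.frame(time = series$times, mean = res$pred_mean,
                       sd_signal = sqrt(pmax(res$pred_var_signal, 0)),
                       sd_obs = sqrt(pmax(res$pred_var_obs, 0)),
                       phase = ifelse(seq_len(n) <= n_head, "init", "filter"))
    smo <- data.frame(time = series$times, mean = res$smooth_mean,
                      sd = sqrt(pmax(res$smooth_var, 0)))
    return(list(loglik = res$loglik, predictive = pred, smoothing = smo))
  }
  filter_loglik_r(series, params, dt, obs_scheme, L, M, n, n_head)
}

# reference R implementation of the filter loop
filter_loglik_r <- function(series, params, dt, obs_scheme, L, M, n, n_head) {
  ex <- series$exposure
  head_idx <- seq_len(n_head)
  head <- observed_series(series$times[head_idx], series$values[head_idx], ex)
  ini <- init_window(head, params, dt, obs_scheme)
  w <- ini$window
  net <- ttfl_network(params, grid_step = dt)
  fw <- exposure_weights(params$kappa, dt, L, obs_scheme)
  f_full <- c(numeric(M + 1 - length(fw)), fw)
  f_lead <- c(fw, numeric(M + 1 - length(fw)))
  nv <- params$sigma_eps^2
  ll <- ini$loglik
  pred <- matrix(NA_real_, n, 3)
  pred[head_idx, ] <- cbind(ini$predictive$mean,
                            ini$predictive$var - nv, ini$predictive$var)
  smo <- matrix(NA_real_, n, 2)
  # bin 1 leaves the (full) window during the first post-init propagation
  smo[1, ] <- c(sum(f_lead * w$mean),
                as.numeric(f_lead %*% w$cov %*% f_lead))
  for (k in (n_head + 1):n) {
    for (s in seq_len(L)) w <- propagate_window(w, net, dt)
    Pf <- as.numeric(w$cov %*% f_full)
    mu_y <- sum(f_full * w$mean)
    S_sig <- sum(f_full * Pf)
    S <- S_sig + nv
    ll <- ll + dnorm(series$values[k], mu_y, sqrt(S), log = TRUE)
    pred[k, ] <- c(mu_y, S_sig, S)
    w <- delayed_kalman_update(w, f_full, series$values[k], noise_var = nv)
    b <- k - n_head + 1  # oldest complete exposure bin, about to slide out
    smo[b, ] <- c(sum(f_lead * w$mean),
                  as.numeric(f_lead %*% w$cov %*% f_lead))
  }
  for (b in (n - n_head + 2):n) {  # bins still inside the final window
    off <- M - (n - b + 1) * L
    f_b <- c(numeric(off), fw, numeric(M + 1 - off - length(fw)))
    smo[b, ] <- c(sum(f_b * w$mean), as.numeric(f_b %*% w$cov %*% f_b))
  }
  list(loglik = ll,
       predictive = data.frame(
         time = series$times, mean = pred[, 1],
         sd_signal = sqrt(pmax(pred[, 2], 0)),
         sd_obs = sqrt(pmax(pred[, 3], 0)),
         phase = ifelse(seq_len(n) <= n_head, "init", "filter")),
       smoothing = data.frame(time = series$times, mean = smo[, 1],
                              sd = sqrt(pmax(smo[, 2], 0))),
       window = w)
}
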