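#' Gaussian state summary
#'
#' Mean vector and covariance matrix of the linear-noise-approximation state
#' law \eqn{X(t) \sim N(\rho(t), P(t))}.
#'
#' @param mean numeric vector (length p).
#' @param cov p x p covariance matrix (symmetrized on construction).
#' @return Object of class `gaussian_state`.
#' @export
gaussian_state <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  stopifnot(nrow(cov) == length(mean), ncol(cov) == length(mean))
  structure(list(mean = mean, cov = (cov + t(cov)) / 2),
            class = "gaussian_state")
}

#' Continuous-state model for the non-delayed LNA
#'
#' @param drift function(x) -> length-p drift g(x) = S h(x).
#' @param jacobian function(x) -> p x p Jacobian of the drift.
#' @param diffusion function(x) -> p x p diffusion A(x) = S diag(h(x)) S'.
#' @return Object of class `lna_model`.
#' @export
lna_model <- function(drift, jacobian, diffusion) {
  stopifnot(is.function(drift), is.function(jacobian), is.function(diffusion))
  structure(list(drift = drift, jacobian = jacobian, diffusion = diffusion),
            class = "lna_model")
}

#' Measurement model for the linear-Gaussian observation equation
#'
#' Observation `y = F x + eps`, `eps ~ N(0, noise_cov)`.
#'
#' @param obs_matrix q x p matrix F.
#' @param noise_cov q x q symmetric positive semidefinite noise covariance.
#' @return Object of class `measurement_model`.
#' @export
measurement_model <- function(obs_matrix, noise_cov) {
  obs_matrix <- as.matrix(obs_matrix)
  noise_cov <- as.matrix(noise_cov)
  stopifnot(nrow(noise_cov) == ncol(noise_cov),
            nrow(noise_cov) == nrow(obs_matrix))
  if (max(abs(noise_cov - t(noise_cov))) > 1e-10)
    stop("measurement_model: noise_cov must be symmetric")
  structure(list(obs_matrix = obs_matrix, noise_cov = noise_cov),
            class = "measurement_model")
}

# symmetrize and floor negative eigenvalues of a covariance
psd_floor <- function(P, tol = 1e-10) {
  P <- (P + t(P)) / 2
  e <- eigen(P, symmetric = TRUE)
  if (min(e$values) < -tol) {
    v <- pmax(e$values, 0)
    P <- e$vectors %*% (v * t(e$vectors))
    P <- (P + t(P)) / 2
  }
  P
}

#' Propagate LNA moments by Euler integration
#'
#' Integrates the moment ODEs of the linear noise approximation,
#' `d rho = g(rho) dt` and `d P = (J P + P J' + A(rho)) dt`, with Euler
#' steps of size `dt` from `t0` to `t1`. The covariance step is applied in
#' its discrete affine-map form `(I + J dt) P (I + J dt)' + A dt`, which
#' agrees with the continuous form to first order in `dt` but keeps the
#' covariance positive semidefinite by construction and matches the delayed
#' window propagation exactly in the degenerate (no-delay) case.
#'
#' @param state a [gaussian_state()].
#' @param model an [lna_model()].
#' @param t0,t1 start and end times (hours), `t1 >= t0`.
#' @param dt Euler step (hours), `dt <= t1 - t0` (last step shortened to hit
#'   `t1` exactly).
#' @return The propagated [gaussian_state()].
#' @export
lna_propagate <- function(state, model, t0, t1, dt) {
  stopifnot(inherits(state, "gaussian_state"), inherits(model, "lna_model"),
            t1 >= t0, dt > 0)
  rho <- state$mean
  P <- state$cov
  t <- t0
  step_i <- 0L
  while (t < t1 - 1e-12) {
    h <- min(dt, t1 - t)
    step_i <- step_i + 1L
    g <- model$drift(rho)
    J <- model$jacobian(rho)
    A <- model$diffusion(rho)
    Phi <- diag(length(rho)) + J * h
    rho <- rho + g * h
    P <- Phi %*% P %*% t(Phi) + A * h
    P <- (P + t(P)) / 2
    if (any(!is.finite(rho)) || any(!is.finite(P)))
      stop("lna_propagate: non-finite moments at step ", step_i)
    t <- t + h
  }
  gaussian_state(rho, psd_floor(P))
}

#' Kalman restart (measurement update) of the LNA moments
#'
#' Conditions the Gaussian state law on an observation:
#' `C = P F' (F P F' + Sigma_eps)^-1`, `rho* = rho + C (y - F rho)`,
#' `P* = P - C F P` (symmetrized).
#'
#' @param state a [gaussian_state()] (the one-step predictive law).
#' @param m a [measurement_model()].
#' @param y observation vector (length q).
#' @param time optional time stamp used in error messages.
#' @return The filtered [gaussian_state()].
#' @export
kalman_update <- function(state, m, y, time = NA) {
  stopifnot(inherits(state, "gaussian_state"),
            inherits(m, "measurement_model"))
  F <- m$obs_matrix
  P <- state$cov
  S <- F %*% P %*% t(F) + m$noise_cov
  S <- (S + t(S)) / 2
  Ck <- tryCatch(t(solve(S, F %*% P)),
                 error = function(e)
                   stop("kalman_update: singular innovation covariance at ",
                        "observation time ", time))
  rho <- state$mean + as.numeric(Ck %*% (y - F %*% state$mean))
  P_new <- P - Ck %*% F %*% P
  gaussian_state(rho, psd_floor(P_new))
}

#' Extended Kalman-Bucy filter log-likelihood (non-delayed)
#'
#' Alternates LNA moment propagation over each observation interval with a
#' Kalman restart at each observation. The marginal log-likelihood is the
#' sum of the Gaussian log-densities of the innovations, each with mean
#' `F rho` and variance `F P F' + Sigma_eps`.
#'
#' @param series an [observed_series()] (values taken as direct observations
#'   `y = F x + eps` at the stamped times).
#' @param model an [lna_model()].
#' @param m a [measurement_model()].
#' @param init initial [gaussian_state()] at time 0.
#' @param dt Euler step (hours); must divide the observation spacing.
#' @return List with `loglik`, and data frames `predictive` / `filtered`
#'   containing per-observation means and variances (first observed
#'   component).
#' @export
ekbf_loglik <- function(series, model, m, init, dt) {
  stopifnot(inherits(series, "observed_series"))
  state <- init
  t_prev <- 0
  n <- length(series$times)
  F <- m$obs_matrix
  ll <- 0
  pred <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("mean", "var")))
  filt <- pred
  for (k in seq_len(n)) {
    t_k <- series$times[k]
    state <- lna_propagate(state, model, t_prev, t_k, dt)
    mu_y <- as.numeric(F %*% state$mean)
    S <- as.numeric(F %*% state$cov %*% t(F) + m$noise_cov)
    ll <- ll + dnorm(series$values[k], mu_y, sqrt(S), log = TRUE)
    pred[k, ] <- c(mu_y, S)
    state <- kalman_update(state, m, series$values[k], time = t_k)
    filt[k, ] <- c(as.numeric(F %*% state$mean),
                   as.numeric(F %*% state$cov %*% t(F)))
    t_prev <- t_k
  }
  list(loglik = ll, predictive = as.data.frame(pred),
       filtered = as.data.frame(filt), state = state)
}
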