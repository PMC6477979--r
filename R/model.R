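#' Hill repression function
#'
#' Repressive transcription rate as a function of the (possibly
#' delay-weighted) repressor abundance `u`:
#' \deqn{\nu(u) = R_{max} / (1 + (u/K_{pc})^n).}
#' At `u = threshold` the output is half-maximal; the function is strictly
#' decreasing and bounded by `(0, r_max]`.
#'
#' @param r_max maximum transcription rate (molecules/hour), > 0.
#' @param threshold dissociation coefficient \eqn{K_{pc}} (molecules), > 0.
#' @param coefficient Hill coefficient \eqn{n} (dimensionless), > 0.
#' @return An object of class `hill_function`.
#' @examples
#' h <- hill_function(120, 100, 5)
#' hill_transcription(100, h) # half-max: 60
#' @export
hill_function <- function(r_max, threshold, coefficient) {
  stopifnot(is.numeric(r_max), r_max > 0, is.numeric(threshold),
            threshold > 0, is.numeric(coefficient), coefficient > 0)
  structure(list(r_max = r_max, threshold = threshold,
                 coefficient = coefficient), class = "hill_function")
}

#' Evaluate a Hill repression function
#'
#' @param u repressor abundance (molecules), must be >= 0 (vectorized).
#' @param h a [hill_function()].
#' @return transcription rate(s) in `(0, r_max]`.
#' @export
hill_transcription <- function(u, h) {
  stopifnot(inherits(h, "hill_function"))
  if (any(!is.finite(u)) || any(u < 0))
    stop("hill_transcription: repressor abundance 'u' must be finite and >= 0")
  h$r_max / (1 + (u / h$threshold)^h$coefficient)
}

#' Derivative of a Hill repression function
#'
#' @inheritParams hill_transcription
#' @return d nu / d u, <= 0.
#' @export
hill_gradient <- function(u, h) {
  stopifnot(inherits(h, "hill_function"))
  z <- (u / h$threshold)^h$coefficient
  -(h$r_max * h$coefficient / h$threshold) *
    (u / h$threshold)^(h$coefficient - 1) / (1 + z)^2
}

#' Discretized, truncated Gamma delay kernel
#'
#' Builds the delay density K on the filter's lag lattice
#' `0, grid_step, ..., max_lag`. The Gamma distribution is parameterized by
#' its mean and standard deviation (shape = mean^2/sd^2, scale = sd^2/mean),
#' each lattice node receives the probability mass of the bin
#' `[lag - grid_step/2, lag + grid_step/2]` (clipped to `[0, max_lag]`), and
#' the weights are renormalized to sum to one after truncation at `max_lag`,
#' so the kernel remains a probability density on `[0, max_lag]`.
#'
#' @param mean delay mean E\[tau\] (hours), > 0.
#' @param sd delay standard deviation SD\[tau\] (hours), > 0.
#' @param max_lag maximum delay time tau_m (hours); default 30.
#' @param grid_step lag lattice step delta_t (hours); must divide `max_lag`.
#' @return Object of class `delay_kernel` with fields `grid_step`, `max_lag`,
#'   `weights` (length `max_lag/grid_step + 1`, summing to 1), `mean`, `sd`.
#' @examples
#' k <- make_gamma_kernel(9.67, 3.56, 30, 0.1)
#' sum(k$weights) # 1
#' @export
make_gamma_kernel <- function(mean, sd, max_lag = 30, grid_step) {
  stopifnot(mean > 0, sd > 0, max_lag > 0, grid_step > 0)
  m <- max_lag / grid_step
  if (abs(m - round(m)) > 1e-8)
    stop("make_gamma_kernel: grid_step must divide max_lag")
  m <- round(m)
  if (mean >= max_lag)
    warning("make_gamma_kernel: delay mean >= max_lag; most mass truncated")
  lag <- (0:m) * grid_step
  shape <- (mean / sd)^2
  scale <- sd^2 / mean
  w <- if (is.finite(shape) && is.finite(scale) && shape > 0) {
    pgamma(pmin(lag + grid_step / 2, max_lag), shape, scale = scale) -
      pgamma(pmax(lag - grid_step / 2, 0), shape, scale = scale)
  } else {
    numeric(m + 1)  # overflowed shape/scale: treat as a degenerate kernel
  }
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) { # degenerate: bin nearest the mean
    w <- numeric(m + 1)
    w[which.min(abs(lag - mean))] <- 1
  } else {
    w <- w / tot
  }
  structure(list(grid_step = grid_step, max_lag = max_lag, weights = w,
                 mean = mean, sd = sd), class = "delay_kernel")
}

#' Point-mass-at-zero delay kernel
#'
#' Degenerate kernel carried by species without delay dependence: all mass at
#' lag 0, so the delayed machinery reduces exactly to the non-delayed case.
#'
#' @inheritParams make_gamma_kernel
#' @return A `delay_kernel` with weight 1 at lag 0.
#' @export
point_mass_kernel <- function(max_lag = 30, grid_step) {
  m <- round(max_lag / grid_step)
  w <- numeric(m + 1)
  w[1] <- 1
  structure(list(grid_step = grid_step, max_lag = max_lag, weights = w,
                 mean = 0, sd = 0), class = "delay_kernel")
}

#' @export
print.delay_kernel <- function(x, ...) {
  cat(sprintf(
    "<delay_kernel> mean %.3g h, sd %.3g h, truncated at %g h (step %g h)\n",
    x$mean, x$sd, x$max_lag, x$grid_step))
  invisible(x)
}

#' Discrete mean of a delay kernel on its lag lattice
#' @param k a `delay_kernel`.
#' @return mean lag (hours) of the lattice distribution.
#' @export
kernel_discrete_mean <- function(k) {
  lag <- seq(0, k$max_lag, by = k$grid_step)
  sum(lag * k$weights)
}

#' Parameter set for the delayed transcriptional feedback model
#'
#' All inferable quantities of the mRNA negative-feedback loop with a
#' Gamma-distributed self-repression delay, plus the measurement and
#' initial-condition parameters. Defaults are the package's reference
#' simulation-study setting: a circadian oscillator with Hill coefficient 5
#' and delay moments near the values estimated for *Cry1* expression.
#'
#' @param r_max maximum transcription rate (molecules/h).
#' @param k_pc Hill threshold (molecules).
#' @param n Hill coefficient (dimensionless, > 0).
#' @param mu mRNA degradation rate (1/h).
#' @param delay_mean delay mean E\[tau\] (h); must be < `tau_max`.
#' @param delay_sd delay SD (h).
#' @param kappa light intensity per molecule-hour (observation scale).
#' @param sigma_eps measurement noise SD (intensity units).
#' @param init_rate constant (step) transcription rate nu during the
#'   initialization window `[0, tau_max]` (molecules/h).
#' @param mu0 degradation rate during the initialization window (1/h).
#' @param beta initial-condition dispersion: Var\[X_0\] = beta * E\[X_0\]
#'   unless `var_x0` is supplied.
#' @param var_x0 optional explicit initial variance (molecules^2); `NA` means
#'   use `beta * E[X_0]`.
#' @param tau_max maximum delay time tau_m (h).
#' @return Object of class `ttfl_params` (a validated named list).
#' @examples
#' p <- ttfl_params()
#' p$r_max
#' @export
ttfl_params <- function(r_max = 120, k_pc = 100, n = 5, mu = 0.58,
                        delay_mean = 9.67, delay_sd = 3.56, kappa = 1,
                        sigma_eps = 1, init_rate = 60, mu0 = 0.58,
                        beta = 1, var_x0 = NA_real_, tau_max = 30) {
  p <- list(r_max = r_max, k_pc = k_pc, n = n, mu = mu,
            delay_mean = delay_mean, delay_sd = delay_sd, kappa = kappa,
            sigma_eps = sigma_eps, init_rate = init_rate, mu0 = mu0,
            beta = beta, var_x0 = var_x0, tau_max = tau_max)
  num <- p[setdiff(names(p), "var_x0")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1 &&
                    is.finite(v) && v > 0, logical(1))))
    stop("ttfl_params: all parameters must be single positive numbers")
  if (!is.na(var_x0) && var_x0 <= 0) stop("ttfl_params: var_x0 must be > 0")
  if (delay_mean >= tau_max)
    stop("ttfl_params: delay_mean must be smaller than tau_max")
  structure(p, class = "ttfl_params")
}

#' @export
print.ttfl_params <- function(x, ...) {
  cat("<ttfl_params>\n")
  for (nm in names(x))
    cat(sprintf("  %-10s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Reaction network with distributed-delay hazards
#'
#' Container splitting the stoichiometry into the `w` reactions whose hazards
#' depend on the kernel-weighted past state (columns of `stoich_delayed`) and
#' the `z` reactions depending only on the current state
#' (`stoich_plain`); the full stoichiometry is their column concatenation.
#' Each species carries a delay density descriptor; species without delay
#' dependence use a point mass at lag 0.
#'
#' @param n_species number of species p.
#' @param stoich_delayed integer matrix p x w.
#' @param stoich_plain integer matrix p x z.
#' @param hazards_delayed function(u) -> length-w vector of non-negative
#'   hazards of the kernel-weighted past state vector `u` (length p).
#' @param hazards_plain function(x) -> length-z vector of non-negative
#'   hazards of the current state `x`.
#' @param kernels list of p `delay_kernel` objects (one per species).
#' @param jac_delayed optional function(u) -> w x p Jacobian of
#'   `hazards_delayed`; numerically differenced if omitted.
#' @param jac_plain optional function(x) -> z x p Jacobian of `hazards_plain`.
#' @return Object of class `delayed_network`.
#' @export
delayed_network <- function(n_species, stoich_delayed, stoich_plain,
                            hazards_delayed, hazards_plain, kernels,
                            jac_delayed = NULL, jac_plain = NULL) {
  stoich_delayed <- as.matrix(stoich_delayed)
  stoich_plain <- as.matrix(stoich_plain)
  stopifnot(nrow(stoich_delayed) == n_species,
            nrow(stoich_plain) == n_species,
            is.function(hazards_delayed), is.function(hazards_plain),
            length(kernels) == n_species)
  if (!all(vapply(kernels, inherits, logical(1), "delay_kernel")))
    stop("delayed_network: 'kernels' must be a list of delay_kernel objects")
  gs <- vapply(kernels, `[[`, numeric(1), "grid_step")
  ml <- vapply(kernels, `[[`, numeric(1), "max_lag")
  if (length(unique(gs)) != 1 || length(unique(ml)) != 1)
    stop("delayed_network: all kernels must share grid_step and max_lag")
  if (is.null(jac_delayed))
    jac_delayed <- function(u) num_jacobian(hazards_delayed, u)
  if (is.null(jac_plain))
    jac_plain <- function(x) num_jacobian(hazards_plain, x)
  structure(list(n_species = n_species, stoich_delayed = stoich_delayed,
                 stoich_plain = stoich_plain,
                 hazards_delayed = hazards_delayed,
                 hazards_plain = hazards_plain, kernels = kernels,
                 jac_delayed = jac_delayed, jac_plain = jac_plain),
            class = "delayed_network")
}

# forward-difference Jacobian; adequate for the smooth hazards used here
num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    xi <- x
    h <- eps * max(1, abs(x[i]))
    xi[i] <- xi[i] + h
    J[, i] <- (f(xi) - f0) / h
  }
  J
}

#' Delayed transcriptional negative-feedback (TTFL) network
#'
#' The reduced circadian feedback loop: a single species (mRNA X) produced by
#' a delayed Hill-repressed transcription reaction (stoichiometry +1, hazard
#' `nu(u) = r_max / (1 + (u/k_pc)^n)` of the Gamma-kernel-weighted past X)
#' and degraded by a first-order death reaction (stoichiometry -1, hazard
#' `mu * x`).
#'
#' @param params a [ttfl_params()] object.
#' @param grid_step lag lattice step for the delay kernel (hours).
#' @return A [delayed_network()] with one species and two reactions.
#' @export
ttfl_network <- function(params, grid_step = 0.1) {
  stopifnot(inherits(params, "ttfl_params"))
  h <- hill_function(params$r_max, params$k_pc, params$n)
  mu <- params$mu
  delayed_network(
    n_species = 1,
    stoich_delayed = matrix(1L, 1, 1),
    stoich_plain = matrix(-1L, 1, 1),
    hazards_delayed = function(u) hill_transcription(max(u, 0), h),
    hazards_plain = function(x) mu * max(x, 0),
    kernels = list(make_gamma_kernel(params$delay_mean, params$delay_sd,
                                     params$tau_max, grid_step)),
    jac_delayed = function(u) matrix(hill_gradient(max(u, 0), h), 1, 1),
    jac_plain = function(x) matrix(if (x >= 0) mu else 0, 1, 1))
}

#' Deterministic fixed point of the TTFL drift
#'
#' Solves `nu(x) = mu * x` by bisection; the intersection of a decreasing and
#' an increasing function, hence unique and positive.
#'
#' @param params a [ttfl_params()].
#' @return fixed-point abundance x* (molecules).
#' @export
ttfl_fixed_point <- function(params) {
  h <- hill_function(params$r_max, params$k_pc, params$n)
  f <- function(x) hill_transcription(x, h) - params$mu * x
  uniroot(f, c(1e-12, params$r_max / params$mu + 1), tol = 1e-12)$root
}
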