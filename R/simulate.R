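#' Trajectory of molecule counts on a fixed storage grid
#'
#' @param times time points (hours), equally spaced.
#' @param counts numeric matrix (length(times) x p) or vector (p = 1) of
#'   non-negative molecule counts.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(times, counts) {
  counts <- as.matrix(counts)
  stopifnot(length(times) == nrow(counts), all(counts >= 0))
  if (length(times) > 1) {
    d <- diff(times)
    if (max(abs(d - d[1])) > 1e-8 * max(1, abs(d[1])))
      stop("trajectory: times must be equally spaced")
  }
  structure(list(times = as.numeric(times), counts = counts),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d points, t in [%g, %g] h, %d species\n",
              length(x$times), min(x$times), max(x$times), ncol(x$counts)))
  invisible(x)
}

#' Observed light-intensity series
#'
#' Equally spaced observations; each time stamp marks the END of its
#' exposure bin (the camera integrates the preceding `exposure` hours).
#'
#' @param times bin end times (hours).
#' @param values intensities.
#' @param exposure exposure interval Delta_t (hours).
#' @param meta named list of provenance (seed, snr, sigma_eps, kappa, truth,
#'   params, ...).
#' @return Object of class `observed_series`.
#' @export
observed_series <- function(times, values, exposure, meta = list()) {
  stopifnot(length(times) == length(values), exposure > 0)
  if (length(times) > 1) {
    d <- diff(times)
    if (any(d <= 0)) stop("observed_series: times must be strictly increasing")
    if (max(abs(d - d[1])) > 1e-6 * d[1])
      stop("observed_series: times must be equally spaced")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 exposure = exposure, meta = meta),
            class = "observed_series")
}

#' @export
print.observed_series <- function(x, ...) {
  cat(sprintf("<observed_series> %d obs, exposure %g h, t in [%g, %g] h\n",
              length(x$times), x$exposure, min(x$times), max(x$times)))
  invisible(x)
}

# per-species kernel weights on the storage lattice (rebuilt from moments)
ssa_kernel_weights <- function(k, store_step) {
  if (k$sd == 0 && k$mean == 0) {
    w <- numeric(round(k$max_lag / store_step) + 1)
    w[1] <- 1
    w
  } else {
    make_gamma_kernel(k$mean, k$sd, k$max_lag, store_step)$weights
  }
}

#' Delayed stochastic simulation algorithm
#'
#' Jump-process simulation of a [delayed_network()]. Delayed hazards are
#' evaluated from the kernel-weighted past path and held constant over each
#' storage interval (`store_step`); within an interval, reactions fire with
#' Gillespie exponential clocks (plain hazards refreshed after every event)
#' and each selected reaction takes place immediately. The simulation is
#' exact in distribution apart from the piecewise-constant delayed hazards.
#'
#' @param net a [delayed_network()].
#' @param history a [trajectory()] covering `[-tau_max, 0]` on the
#'   `store_step` grid (integer counts; rounded if not).
#' @param horizon simulation length (hours), > 0.
#' @param seed integer RNG seed.
#' @param store_step storage grid step (hours); default 0.01.
#' @return A [trajectory()] over `[0, horizon]` (the state at time 0 is the
#'   final history point).
#' @export
delayed_ssa <- function(net, history, horizon, seed, store_step = 0.01) {
  stopifnot(inherits(net, "delayed_network"), inherits(history, "trajectory"))
  if (horizon <= 0) stop("delayed_ssa: horizon must be > 0")
  tau_max <- net$kernels[[1]]$max_lag
  M <- round(tau_max / store_step)
  hstep <- if (length(history$times) > 1) diff(history$times)[1] else NA
  if (length(history$times) != M + 1 ||
      (length(history$times) > 1 && abs(hstep - store_step) > 1e-9))
    stop("delayed_ssa: history must cover [-tau_max, 0] on the store grid")
  p <- net$n_species
  S <- cbind(net$stoich_delayed, net$stoich_plain)
  w_d <- ncol(net$stoich_delayed)
  n_steps <- round(horizon / store_step)
  # kernel weights per species, reversed so they align with x[(i-M):i]
  wrev <- lapply(net$kernels, function(k) rev(ssa_kernel_weights(k, store_step)))
  x_path <- matrix(0, M + 1 + n_steps, p)
  x_path[1:(M + 1), ] <- round(history$counts)
  set.seed(seed)
  x <- x_path[M + 1, ]
  for (i in (M + 1):(M + n_steps)) {
    u <- vapply(seq_len(p),
                function(j) sum(wrev[[j]] * x_path[(i - M):i, j]), numeric(1))
    hd <- net$hazards_delayed(u)
    if (any(hd < 0) ) stop("delayed_ssa: negative delayed hazard")
    t_in <- 0
    repeat {
      hp <- net$hazards_plain(x)
      if (any(hp < 0)) stop("delayed_ssa: negative hazard at state ",
                            paste(x, collapse = ","))
      rates <- c(hd, hp)
      tot <- sum(rates)
      if (tot <= 0) break
      t_in <- t_in + rexp(1, tot)
      if (t_in > store_step) break
      j <- sample.int(length(rates), 1, prob = rates)
      x <- x + S[, j]
    }
    x_path[i + 1, ] <- x
  }
  trajectory((0:n_steps) * store_step, x_path[(M + 1):(M + 1 + n_steps), ,
                                              drop = FALSE])
}

#' On-attractor deterministic history for the TTFL model
#'
#' Integrates the deterministic distributed-delay rate equation
#' `x' = nu(u) - mu x` by Euler stepping from a constant state 1.2 x* (a
#' perturbation of the unstable fixed point) for `burn_in` hours, and returns
#' the final `tau_max` hours as a history trajectory over `[-tau_max, 0]`.
#' This plays the role of an oscillatory pre-recording (the settled limit
#' cycle) used to start stochastic simulations on the attractor.
#'
#' @param params a [ttfl_params()].
#' @param store_step storage grid step (hours).
#' @param burn_in burn-in length (hours); default 240.
#' @return A [trajectory()] over `[-tau_max, 0]` with rounded counts.
#' @export
ttfl_history <- function(params, store_step = 0.01, burn_in = 240) {
  h <- hill_function(params$r_max, params$k_pc, params$n)
  M <- round(params$tau_max / store_step)
  wrev <- rev(make_gamma_kernel(params$delay_mean, params$delay_sd,
                                params$tau_max, store_step)$weights)
  xstar <- ttfl_fixed_point(params)
  n <- round(burn_in / store_step)
  x <- numeric(M + 1 + n)
  x[1:(M + 1)] <- 1.2 * xstar
  for (i in (M + 1):(M + n)) {
    u <- sum(wrev * x[(i - M):i])
    x[i + 1] <- x[i] + (hill_transcription(max(u, 0), h) -
                          params$mu * x[i]) * store_step
  }
  trajectory(seq(-params$tau_max, 0, by = store_step),
             pmax(round(x[(n + 1):(n + M + 1)]), 0))
}

#' Camera measurement process: bin, rescale, add noise
#'
#' Emulates luminescence imaging of a count trajectory: counts of the first
#' species are divided by their overall mean level, summed within each
#' exposure bin, and corrupted with i.i.d. Gaussian noise whose SD is set by
#' the signal-to-noise ratio. With `snr_def = "sd"` (default),
#' `sigma_eps = sd(noise-free binned signal) / snr`; with `"mean"` the mean
#' of the binned signal is used instead.
#'
#' @param traj a [trajectory()] starting at time 0.
#' @param exposure exposure interval (hours); must be a multiple of the
#'   storage step.
#' @param snr signal-to-noise ratio, > 0 (reference settings: 20 and 100).
#' @param seed integer RNG seed for the noise.
#' @param rescale divide counts by their mean level (default TRUE).
#' @param snr_def `"sd"` or `"mean"`.
#' @return An [observed_series()]; `meta` records `seed`, `snr`, `sigma_eps`,
#'   the implied observation scale `kappa` (intensity per molecule-hour) and
#'   the noise-free binned signal as `truth`.
#' @export
corrupt_measurements <- function(traj, exposure = 0.5, snr, seed,
                                 rescale = TRUE, snr_def = c("sd", "mean")) {
  stopifnot(inherits(traj, "trajectory"))
  if (snr <= 0) stop("corrupt_measurements: snr must be > 0")
  snr_def <- match.arg(snr_def)
  step <- diff(traj$times)[1]
  nb <- exposure / step
  if (abs(nb - round(nb)) > 1e-8)
    stop("corrupt_measurements: exposure must be a multiple of the store step")
  nb <- round(nb)
  x <- traj$counts[, 1]
  scale_level <- if (rescale) mean(x) else 1
  if (scale_level <= 0) stop("corrupt_measurements: zero mean signal")
  z <- x / scale_level
  n_bins <- (length(x) - 1) %/% nb
  # bin k sums grid points in ((k-1)*exposure, k*exposure]
  idx <- rep(seq_len(n_bins), each = nb)
  signal <- as.numeric(tapply(z[1 + seq_len(n_bins * nb)], idx, sum))
  sigma <- if (is.infinite(snr)) 0 else
    switch(snr_def, sd = sd(signal), mean = mean(signal)) / snr
  set.seed(seed)
  y <- signal + rnorm(n_bins, 0, sigma)
  observed_series(exposure * seq_len(n_bins), y, exposure,
                  meta = list(seed = seed, snr = snr, sigma_eps = sigma,
                              kappa = 1 / (scale_level * step),
                              truth = signal, snr_def = snr_def))
}

#' Remove a linear photon-yield decay trend
#'
#' Divides intensities by `f(t) = 1 - total_decay * t / span`, undoing a
#' linear decrease of the proportionality factor (e.g. luciferin substrate
#' consumption of about 30% over five days).
#'
#' @param raw an [observed_series()].
#' @param total_decay total fractional decrease over `span` (default 0.30).
#' @param span time over which the decay accrues (hours; default 120).
#' @return A detrended [observed_series()].
#' @export
detrend_series <- function(raw, total_decay = 0.30, span = 120) {
  stopifnot(inherits(raw, "observed_series"), span > 0,
            total_decay >= 0, total_decay < 1)
  f <- 1 - total_decay * raw$times / span
  if (any(f <= 0)) stop("detrend_series: decay factor reaches zero in range")
  observed_series(raw$times, raw$values / f, raw$exposure,
                  meta = c(raw$meta, list(detrended = total_decay)))
}

#' Generate replicated synthetic TTFL datasets
#'
#' Full synthetic-data pipeline: delayed SSA simulation of the TTFL network
#' from an on-attractor history, then the camera measurement process, once
#' per replicate. Per-replicate seeds are drawn from the master seed, so the
#' output is reproducible as a whole.
#'
#' @param params a [ttfl_params()].
#' @param n_rep number of replicates.
#' @param snr signal-to-noise ratio.
#' @param seed master integer seed.
#' @param horizon simulated length (hours); default 120 (five days).
#' @param exposure exposure interval (hours); default 0.5.
#' @param store_step storage grid (hours); default 0.01.
#' @param history optional [trajectory()] over `[-tau_max, 0]`; default
#'   [ttfl_history()].
#' @return List of `n_rep` [observed_series()]; each `meta` additionally
#'   carries `params` and `replicate`.
#' @export
generate_dataset <- function(params, n_rep, snr, seed, horizon = 120,
                             exposure = 0.5, store_step = 0.01,
                             history = NULL) {
  stopifnot(inherits(params, "ttfl_params"), n_rep >= 0)
  if (n_rep == 0) return(list())
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 2 * n_rep)
  if (is.null(history)) history <- ttfl_history(params, store_step)
  net <- ttfl_network(params, grid_step = store_step)
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    traj <- delayed_ssa(net, history, horizon, seeds[2 * r - 1], store_step)
    os <- corrupt_measurements(traj, exposure, snr, seeds[2 * r])
    os$meta$params <- params
    os$meta$replicate <- r
    os$meta$master_seed <- seed
    out[[r]] <- os
  }
  out
}
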