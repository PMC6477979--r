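#' Empirical coverage of predictive and partial-smoothing intervals
#'
#' Runs the delayed window filter at known (true) parameters on each series
#' and computes the fraction of noise-free binned signals (stored by the
#' simulator in `meta$truth`) falling inside central Gaussian intervals of
#' mass `level`, separately for the one-step predictive and the
#' partial-smoothing moments, pooled over series. Only post-initialization
#' bins (ending after `tau_max`) are counted. With `target = "signal"`
#' (default) the predictive SD of the noise-free integrated signal is used;
#' `"observation"` adds the measurement noise variance.
#'
#' @param series_list list of [observed_series()] with `meta$truth` attached.
#' @param params_true a [ttfl_params()] (the generating values).
#' @param level nominal interval mass; default 0.95.
#' @param dt filter lattice step; default 0.1.
#' @param target `"signal"` or `"observation"`.
#' @param use_meta_scale replicate-specific true `kappa` and `sigma_eps` are
#'   set by the measurement pipeline (counts are rescaled by their own mean
#'   level); when TRUE (default) they are taken from each series' metadata,
#'   overriding the values in `params_true`.
#' @return Object of class `coverage_report`: list with `level`,
#'   `predictive`, `smoothing` and `pooled` empirical coverages,
#'   `n_predictive`, `n_smoothing`, `dt`.
#' @export
coverage <- function(series_list, params_true, level = 0.95, dt = 0.1,
                     target = c("signal", "observation"),
                     use_meta_scale = TRUE) {
  if (inherits(series_list, "observed_series"))
    series_list <- list(series_list)
  target <- match.arg(target)
  stopifnot(length(series_list) >= 1, level > 0, level <= 1)
  z <- qnorm(1 - (1 - level) / 2)
  hit_p <- tot_p <- hit_s <- tot_s <- 0L
  for (series in series_list) {
    truth <- series$meta$truth
    if (is.null(truth)) stop("coverage: series lacks meta$truth")
    params <- params_true
    if (use_meta_scale) {
      upd <- series$meta[intersect(c("kappa", "sigma_eps"),
                                   names(series$meta))]
      if (length(upd))
        params <- do.call(ttfl_params, modifyList(unclass(params_true), upd))
    }
    fl <- filter_loglik(series, params, dt)
    post <- fl$predictive$phase == "filter"
    sd_p <- if (target == "signal") fl$predictive$sd_signal
      else fl$predictive$sd_obs
    in_p <- abs(truth[post] - fl$predictive$mean[post]) <= z * sd_p[post]
    in_s <- abs(truth[post] - fl$smoothing$mean[post]) <=
      z * fl$smoothing$sd[post]
    hit_p <- hit_p + sum(in_p)
    tot_p <- tot_p + sum(post)
    hit_s <- hit_s + sum(in_s)
    tot_s <- tot_s + sum(post)
  }
  structure(list(level = level, predictive = hit_p / tot_p,
                 smoothing = hit_s / tot_s,
                 pooled = (hit_p + hit_s) / (tot_p + tot_s),
                 n_predictive = tot_p, n_smoothing = tot_s, dt = dt),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "<coverage_report> nominal %g%%: predictive %.1f%% (n=%d), smoothing %.1f%% (n=%d), pooled %.1f%%\n",
    100 * x$level, 100 * x$predictive, x$n_predictive, 100 * x$smoothing,
    x$n_smoothing, 100 * x$pooled))
  invisible(x)
}

# Euler-Maruyama simulation of the delayed chemical Langevin equation on the
# dt lattice, started from the de-integrated head of the observed series
# (the observations over (0, tau_max] play the role of the state history,
# mirroring the filter's own initialization), returning one synthetic
# observation series for the post-initialization bins.
simulate_cle_obs <- function(params, series, dt) {
  h <- hill_function(params$r_max, params$k_pc, params$n)
  M <- round(params$tau_max / dt)
  ex <- series$exposure
  n_head <- round(params$tau_max / ex)
  n_obs <- length(series$values) - n_head
  wrev <- rev(make_gamma_kernel(params$delay_mean, params$delay_sd,
                                params$tau_max, dt)$weights)
  L <- round(ex / dt)
  # staircase de-integration of the head: X(t) ~ y_bin / (kappa * exposure)
  bin_of <- pmin(pmax(ceiling((0:M) * dt / ex), 1), n_head)
  hist <- pmax(series$values[bin_of] / (params$kappa * ex), 0)
  n_steps <- n_obs * L
  x <- c(hist, numeric(n_steps))
  for (i in (M + 1):(M + n_steps)) {
    u <- max(sum(wrev * x[(i - M):i]), 0)
    nu <- hill_transcription(u, h)
    haz <- nu + params$mu * max(x[i], 0)
    x[i + 1] <- max(x[i] + (nu - params$mu * x[i]) * dt +
                      sqrt(haz * dt) * rnorm(1), 0)
  }
  path <- x[(M + 1):(M + 1 + n_steps)]
  sig <- vapply(seq_len(n_obs), function(k) {
    blk <- path[((k - 1) * L + 1):(k * L + 1)]
    params$kappa * dt * (sum(blk) - (blk[1] + blk[length(blk)]) / 2)
  }, numeric(1))
  sig + rnorm(n_obs, 0, params$sigma_eps)
}

#' Posterior predictive simulation envelopes
#'
#' For each of `n_draws` thinned posterior parameter draws, simulates a new
#' observation series from the fitted model (delayed chemical Langevin
#' dynamics integrated on the filter lattice, camera integration, Gaussian
#' noise) and returns pointwise quantile envelopes. Each simulation is
#' started from the de-integrated first `tau_max` hours of the observed
#' series (the same role the data head plays in the filter's
#' initialization), so envelopes are reported for the post-initialization
#' observations only.
#'
#' @param series the fitted [observed_series()] (sets length, exposure and
#'   the initial history).
#' @param chains a `chain_result` or list of them.
#' @param n_draws number of posterior draws to simulate; default 50.
#' @param seed integer RNG seed.
#' @param burn_in fraction discarded before thinning; default 0.5.
#' @param fixed a [ttfl_params()] for parameters not in the chains.
#' @param level envelope mass; default 0.95.
#' @param dt simulation lattice (hours); default 0.1.
#' @return List with `times` (post-initialization bin ends), `draws`
#'   (n_draws x length(times) matrix), `lower`, `median`, `upper` pointwise
#'   envelopes.
#' @export
posterior_predictive <- function(series, chains, n_draws = 50, seed = 1,
                                 burn_in = 0.5, fixed = ttfl_params(),
                                 level = 0.95, dt = 0.1) {
  stopifnot(inherits(series, "observed_series"), n_draws >= 1)
  if (inherits(chains, "chain_result")) chains <- list(chains)
  pool <- do.call(rbind, lapply(chains, function(ch) {
    n <- nrow(ch$samples)
    ch$samples[(floor(burn_in * n) + 1):n, , drop = FALSE]
  }))
  set.seed(seed)
  rows <- pool[round(seq(1, nrow(pool), length.out = n_draws)), ,
               drop = FALSE]
  fixed_list <- unclass(fixed)
  draws <- NULL
  for (i in seq_len(n_draws)) {
    p <- do.call(ttfl_params, modifyList(fixed_list, as.list(rows[i, ])))
    d <- simulate_cle_obs(p, series, dt)
    if (is.null(draws)) draws <- matrix(NA_real_, n_draws, length(d))
    draws[i, ] <- d
  }
  n_head <- length(series$values) - ncol(draws)
  a <- (1 - level) / 2
  list(times = series$times[-seq_len(n_head)], draws = draws,
       lower = apply(draws, 2, quantile, a),
       median = apply(draws, 2, quantile, 0.5),
       upper = apply(draws, 2, quantile, 1 - a))
}

#' Standardized one-step innovation residuals
#'
#' `(y - predictive mean) / predictive SD` per observation, using the
#' observation-scale predictive SD (including measurement noise), excluding
#' the initialization window (the first `tau_max` hours).
#'
#' @param series an [observed_series()].
#' @param predictive the `predictive` data frame returned by
#'   [filter_loglik()] for the same series.
#' @return Data frame with `time` and `residual`.
#' @export
standardized_residuals <- function(series, predictive) {
  stopifnot(inherits(series, "observed_series"))
  if (nrow(predictive) != length(series$values))
    stop("standardized_residuals: predictive moments and series lengths differ")
  keep <- predictive$phase == "filter"
  data.frame(time = series$times[keep],
             residual = (series$values[keep] - predictive$mean[keep]) /
               predictive$sd_obs[keep])
}

#' Residual periodicity check
#'
#' Raw periodogram of the residual series with the top peaks reported, a
#' white-noise significance screen (periodogram ordinates are approximately
#' exponential under whiteness; a peak is flagged when it exceeds the
#' Bonferroni-adjusted 5% exponential quantile), and indicators for peaks
#' near the circadian (24 h) and half-circadian (12 h) periods. The
#' reporting is descriptive, not a formal goodness-of-fit test.
#'
#' @param residuals numeric residual series (or the data frame from
#'   [standardized_residuals()]); needs at least two full days.
#' @param exposure sampling interval of the residuals (hours).
#' @param n_peaks number of top peaks to report; default 3.
#' @param alpha screen level; default 0.05.
#' @return List with `peaks` (data frame: `period`, `power`,
#'   `normalized_power`, `flagged`), `flag_24h`, `flag_12h`.
#' @export
periodicity_check <- function(residuals, exposure, n_peaks = 3,
                              alpha = 0.05) {
  if (is.data.frame(residuals)) residuals <- residuals$residual
  if (length(residuals) * exposure < 48)
    stop("periodicity_check: need at least two full days of residuals")
  sp <- spec.pgram(ts(residuals - mean(residuals), deltat = exposure),
                   taper = 0, detrend = FALSE, plot = FALSE)
  period <- 1 / sp$freq
  ord <- order(sp$spec, decreasing = TRUE)[seq_len(n_peaks)]
  thresh <- mean(sp$spec) * (-log(alpha / length(sp$freq)))
  peaks <- data.frame(period = period[ord], power = sp$spec[ord],
                      normalized_power = sp$spec[ord] / mean(sp$spec),
                      flagged = sp$spec[ord] > thresh)
  near <- function(target, tol) any(peaks$flagged &
                                      abs(peaks$period - target) < tol)
  list(peaks = peaks, flag_24h = near(24, 3), flag_12h = near(12, 1.5))
}
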