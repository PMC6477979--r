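#' Default priors for the delayed feedback model
#'
#' Priors are specified on the log scale for positive parameters (normal on
#' log, i.e. lognormal) and as bounded uniforms for the delay moments:
#' generic N(0, 10^2) on the log of `r_max`, `k_pc` and `init_rate`; the
#' Hill coefficient `log(n) ~ N(log 1.5, 5^2)`; the degradation rates
#' `log(mu0)`, `log(mu) ~ N(log 0.58, 0.5^2)` (an informative reporter
#' half-life prior); `log(beta)`, `log(var_x0)` and `log(kappa)`
#' ~ N(0, 20^2); `log(sigma_eps)` normal with unit SD about a user-supplied
#' center (for synthetic data, the true simulation value; for real data it
#' must come from an independent noise measurement); delay mean ~ U(0, 23) h
#' and delay SD ~ U(0, 20) h.
#'
#' @param sigma_eps_center center (natural scale) of the measurement-noise
#'   prior.
#' @return Object of class `prior_spec`: a named list of per-parameter
#'   descriptors, `list(type = "lognormal", meanlog, sdlog)` or
#'   `list(type = "uniform", lo, hi)`, covering every [ttfl_params()] field
#'   except `tau_max` (a structural constant).
#' @export
default_priors <- function(sigma_eps_center = 1) {
  stopifnot(sigma_eps_center > 0)
  ln <- function(m, s) list(type = "lognormal", meanlog = m, sdlog = s)
  un <- function(lo, hi) list(type = "uniform", lo = lo, hi = hi)
  structure(list(
    r_max = ln(0, 10), k_pc = ln(0, 10), n = ln(log(1.5), 5),
    mu = ln(log(0.58), 0.5), delay_mean = un(0, 23), delay_sd = un(0, 20),
    kappa = ln(0, 20), sigma_eps = ln(log(sigma_eps_center), 1),
    init_rate = ln(0, 10), mu0 = ln(log(0.58), 0.5), beta = ln(0, 20),
    var_x0 = ln(0, 20)), class = "prior_spec")
}

#' Log prior density of one parameter (natural scale argument)
#'
#' @param priors a `prior_spec`.
#' @param name parameter name.
#' @param value value on the natural scale (vectorized).
#' @return log density (\eqn{-\infty} outside the support); for lognormal
#'   components this is the density of the natural-scale value.
#' @export
prior_logdensity <- function(priors, name, value) {
  d <- priors[[name]]
  if (is.null(d)) stop("prior_logdensity: unknown parameter ", name)
  if (d$type == "lognormal") {
    ifelse(value > 0,
           dnorm(log(value), d$meanlog, d$sdlog, log = TRUE) - log(value),
           -Inf)
  } else {
    ifelse(value > d$lo & value < d$hi, -log(d$hi - d$lo), -Inf)
  }
}

# sampling-scale machinery: theta = log(psi) for lognormal components,
# theta = logit(psi / hi) for uniform components (lo = 0 throughout)
theta_to_natural <- function(priors, names, theta) {
  psi <- numeric(length(theta))
  for (i in seq_along(names)) {
    d <- priors[[names[i]]]
    psi[i] <- if (d$type == "lognormal") exp(theta[i])
      else d$lo + (d$hi - d$lo) * plogis(theta[i])
  }
  names(psi) <- names
  psi
}

# log prior density on the sampling scale (includes the Jacobian)
theta_logprior <- function(priors, names, theta) {
  lp <- 0
  for (i in seq_along(names)) {
    d <- priors[[names[i]]]
    lp <- lp + if (d$type == "lognormal") {
      dnorm(theta[i], d$meanlog, d$sdlog, log = TRUE)
    } else {
      pr <- plogis(theta[i])
      log(pr) + log1p(-pr)    # uniform density x logit Jacobian
    }
  }
  lp
}

theta_prior_draw <- function(priors, names) {
  vapply(names, function(nm) {
    d <- priors[[nm]]
    if (d$type == "lognormal") rnorm(1, d$meanlog, d$sdlog)
    else qlogis(runif(1))
  }, numeric(1))
}

#' Delayed-acceptance adaptive Metropolis sampler (generic)
#'
#' Two-stage Metropolis-Hastings with adaptive Gaussian random-walk
#' proposals. Stage 1 screens a proposal with the cheap log-posterior
#' `logpost_coarse`; survivors face stage 2 with ratio
#' `[fine(x') coarse(x)] / [fine(x) coarse(x')]`, so the fine posterior is
#' the invariant distribution. Proposal covariance follows a Haario-style
#' running estimate scaled by `2.38^2 / d`, with a global scale adapted in
#' batches of 50 iterations (Roberts-Rosenthal style, diminishing
#' increments) towards a 0.234 overall (post-stage-2) acceptance rate --
#' targeting the overall rate automatically shrinks the steps when the
#' coarse surrogate disagrees with the fine posterior, which would
#' otherwise suppress stage-2 acceptance; adaptation is frozen after
#' `adapt_frac` of the run (diminishing adaptation, so ergodicity is
#' preserved). When coarse and fine posteriors coincide the
#' stage-2 ratio is identically 1 and the sampler is plain adaptive MH.
#'
#' @param logpost_coarse,logpost_fine functions of the sampling-scale
#'   parameter vector returning log posterior densities (up to constants).
#' @param init numeric initial parameter vector (sampling scale).
#' @param n_iter iterations.
#' @param seed integer RNG seed.
#' @param adapt_frac fraction of iterations after which adaptation freezes.
#' @param scale0 initial global proposal scale.
#' @return List with `samples` (n_iter x d, sampling scale), `lp_coarse`,
#'   `lp_fine` traces, and `accept_stage1` / `accept_overall` rates.
#' @export
da_sampler <- function(logpost_coarse, logpost_fine, init, n_iter, seed,
                       adapt_frac = 0.5, scale0 = 0.1) {
  set.seed(seed)
  d <- length(init)
  theta <- init
  lp1 <- logpost_coarse(theta)
  lp2 <- logpost_fine(theta)
  if (!is.finite(lp1) || !is.finite(lp2))
    stop("da_sampler: non-finite log posterior at the initial value")
  samples <- matrix(NA_real_, n_iter, d)
  tr1 <- tr2 <- numeric(n_iter)
  run_mean <- theta
  run_cov <- diag(d)
  log_scale <- log(scale0)
  n_acc1 <- n_acc <- 0L
  batch_acc <- 0L
  chol_prop <- diag(d)
  refresh <- function() {
    Sig <- (2.38^2 / d) * (run_cov + 1e-8 * diag(d)) * exp(2 * log_scale)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (!is.null(ch)) chol_prop <<- ch
  }
  refresh()
  freeze_at <- ceiling(adapt_frac * n_iter)
  for (it in seq_len(n_iter)) {
    prop <- theta + as.numeric(crossprod(chol_prop, rnorm(d)))
    lp1p <- logpost_coarse(prop)
    acc1 <- is.finite(lp1p) && log(runif(1)) < (lp1p - lp1)
    if (acc1) {
      n_acc1 <- n_acc1 + 1L
      lp2p <- logpost_fine(prop)
      if (is.finite(lp2p) &&
          log(runif(1)) < (lp2p - lp2) + (lp1 - lp1p)) {
        theta <- prop
        lp1 <- lp1p
        lp2 <- lp2p
        n_acc <- n_acc + 1L
        batch_acc <- batch_acc + 1L
      }
    }
    samples[it, ] <- theta
    tr1[it] <- lp1
    tr2[it] <- lp2
    if (it <= freeze_at) {
      gam <- min(1, 5 * it^-0.7)
      delta <- theta - run_mean
      run_mean <- run_mean + gam * delta
      run_cov <- run_cov + gam * (tcrossprod(delta) - run_cov)
      if (it %% 50 == 0) {
        b <- it %/% 50
        log_scale <- log_scale +
          min(0.3, 2 * b^-0.6) * (batch_acc / 50 - 0.234)
        batch_acc <- 0L
        refresh()
      }
    }
  }
  list(samples = samples, lp_coarse = tr1, lp_fine = tr2,
       accept_stage1 = n_acc1 / n_iter, accept_overall = n_acc / n_iter)
}

# names of the parameters sampled by default (var_x0 stays tied to beta)
default_sample_params <- function() {
  c("r_max", "k_pc", "n", "mu", "delay_mean", "delay_sd", "kappa",
    "sigma_eps", "init_rate", "mu0", "beta")
}

#' Delayed-acceptance MCMC for the delayed feedback model
#'
#' Samples the model parameters given an observed series, using the window
#' filter marginal likelihood at a coarse lattice step (`dt_coarse`) for
#' stage-1 screening and at a fine step (`dt_fine`) for final acceptance,
#' so the invariant distribution is the fine-likelihood posterior.
#' Positive parameters are proposed on the log scale and uniform-prior
#' parameters on the logit scale (with Jacobian correction); optionally the
#' sampler works in coordinates where the observation scale `kappa` is moved
#' into the state equation (sampling `log(kappa r_max)`, `log(kappa k_pc)`
#' instead of `log r_max`, `log k_pc`; an exact volume-preserving linear
#' recoordination that decorrelates `kappa` from the kinetic rates). Initial
#' values are drawn from the priors, re-drawn (up to `max_init_tries`) until
#' both likelihoods are finite.
#'
#' @param series an [observed_series()].
#' @param priors a `prior_spec` from [default_priors()].
#' @param n_iter iterations.
#' @param seed integer seed.
#' @param dt_coarse,dt_fine lattice steps (hours), `dt_coarse >= dt_fine`,
#'   both dividing the exposure; defaults 0.5 and 0.1.
#' @param sample_params names of parameters to sample; the rest are fixed at
#'   `fixed` values.
#' @param fixed a [ttfl_params()] supplying non-sampled parameter values
#'   (defaults to `ttfl_params()`).
#' @param reparam_kappa use the kappa-to-state recoordination (default TRUE).
#' @param use_data if FALSE the likelihood is forced constant, so the
#'   sampler targets the prior (a validation mode).
#' @param adapt_frac,max_init_tries tuning; see [da_sampler()].
#' @param init_best_of number of prior draws screened per chain; the chain
#'   starts at the draw with the highest coarse log-posterior (with very
#'   diffuse priors a single draw almost surely lands in a region of
#'   negligible posterior mass, so each chain is seeded at the best of a
#'   batch of prior draws; set to 1 for a single unscreened draw).
#' @param init_pilot_iters total budget of an optional cheap pilot phase:
#'   plain adaptive MH on the coarse posterior, split over
#'   `init_pilot_restarts` short runs from independent screened prior
#'   draws; the chain starts at the highest-posterior state seen across
#'   all pilots. With a multimodal posterior independent restarts give each
#'   chain several shots at the dominant basin. 0 (default) disables the
#'   pilot phase.
#' @param init_pilot_restarts number of pilot restarts (default 8).
#' @param init optional initial sampling-scale vector (overrides prior draw).
#' @return Object of class `chain_result`: `samples` (n_iter x d, natural
#'   scale), `samples_raw` (sampling scale), `lp_fine`, `lp_coarse`,
#'   acceptance rates, `param_names`, `seed`, `dt_coarse`, `dt_fine`.
#' @export
delayed_acceptance_mcmc <- function(series, priors, n_iter, seed,
                                    dt_coarse = 0.5, dt_fine = 0.1,
                                    sample_params = default_sample_params(),
                                    fixed = ttfl_params(),
                                    reparam_kappa = TRUE, use_data = TRUE,
                                    adapt_frac = 0.5, max_init_tries = 200,
                                    init_best_of = 100,
                                    init_pilot_iters = 0,
                                    init_pilot_restarts = 8, init = NULL) {
  stopifnot(inherits(series, "observed_series"),
            inherits(priors, "prior_spec"), dt_coarse >= dt_fine)
  nm <- sample_params
  d <- length(nm)
  fixed_list <- unclass(fixed)
  make_params <- function(psi) {
    pl <- modifyList(fixed_list, as.list(psi))
    tryCatch(do.call(ttfl_params, pl), error = function(e) NULL)
  }
  loglik_at <- function(psi, dt) {
    if (!use_data) return(0)
    p <- make_params(psi)
    if (is.null(p)) return(-Inf)
    ll <- tryCatch(filter_loglik(series, p, dt, engine = "cpp")$loglik,
                   error = function(e) -Inf)
    if (!is.finite(ll)) -Inf else ll
  }
  # optional linear recoordination eta = T theta (|det T| = 1)
  use_rep <- reparam_kappa && all(c("r_max", "k_pc", "kappa") %in% nm) &&
    priors$kappa$type == "lognormal"
  i_r <- match("r_max", nm); i_k <- match("k_pc", nm); i_c <- match("kappa", nm)
  to_theta <- function(eta) {
    if (!use_rep) return(eta)
    th <- eta
    th[i_r] <- eta[i_r] - eta[i_c]
    th[i_k] <- eta[i_k] - eta[i_c]
    th
  }
  from_theta <- function(th) {
    if (!use_rep) return(th)
    eta <- th
    eta[i_r] <- th[i_r] + th[i_c]
    eta[i_k] <- th[i_k] + th[i_c]
    eta
  }
  logpost <- function(eta, dt) {
    th <- to_theta(eta)
    lp <- theta_logprior(priors, nm, th)
    if (!is.finite(lp)) return(-Inf)
    lp + loglik_at(theta_to_natural(priors, nm, th), dt)
  }
  lp_coarse <- function(eta) logpost(eta, dt_coarse)
  lp_fine <- if (dt_coarse == dt_fine) lp_coarse
    else function(eta) logpost(eta, dt_fine)
  if (!is.null(init) && length(init) != d)
    stop("delayed_acceptance_mcmc: init must have one entry per sampled ",
         "parameter (", d, ")")
  set.seed(seed)
  draw_start <- function(n_keep) {
    best <- NULL
    best_lp <- -Inf
    kept <- 0L
    for (try in seq_len(max_init_tries + n_keep)) {
      cand <- from_theta(theta_prior_draw(priors, nm))
      lp <- lp_coarse(cand)
      if (is.finite(lp) && is.finite(lp_fine(cand))) {
        kept <- kept + 1L
        if (lp > best_lp) {
          best_lp <- lp
          best <- cand
        }
        if (kept >= n_keep) break
      }
    }
    if (is.null(best))
      stop("delayed_acceptance_mcmc: no finite-likelihood start found in ",
           max_init_tries, " prior draws")
    best
  }
  if (is.null(init)) {
    if (init_pilot_iters > 0) {
      n_restart <- max(1L, as.integer(init_pilot_restarts))
      len <- ceiling(init_pilot_iters / n_restart)
      keep_per <- max(1L, ceiling(init_best_of / n_restart))
      best_lp <- -Inf
      for (rs in seq_len(n_restart)) {
        start <- draw_start(keep_per)
        pilot <- da_sampler(lp_coarse, lp_coarse, start, len,
                            seed = seed + 1000L + rs, adapt_frac = 1)
        i_best <- which.max(pilot$lp_coarse)
        if (pilot$lp_coarse[i_best] > best_lp) {
          best_lp <- pilot$lp_coarse[i_best]
          init <- pilot$samples[i_best, ]
        }
      }
      if (!is.finite(lp_fine(init))) init <- draw_start(init_best_of)
    } else {
      init <- draw_start(init_best_of)
    }
  }
  run <- da_sampler(lp_coarse, lp_fine, init, n_iter,
                    seed = seed + 1L, adapt_frac = adapt_frac)
  nat <- t(apply(run$samples, 1, function(eta)
    theta_to_natural(priors, nm, to_theta(eta))))
  colnames(nat) <- nm
  colnames(run$samples) <- nm
  structure(list(samples = nat, samples_raw = run$samples,
                 lp_fine = run$lp_fine, lp_coarse = run$lp_coarse,
                 accept_stage1 = run$accept_stage1,
                 accept_overall = run$accept_overall,
                 param_names = nm, seed = seed,
                 dt_coarse = dt_coarse, dt_fine = dt_fine),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf(
    "<chain_result> %d iterations, %d parameters; acceptance %0.3f (stage 1 %0.3f)\n",
    nrow(x$samples), ncol(x$samples), x$accept_overall, x$accept_stage1))
  invisible(x)
}

#' Highest posterior density interval
#'
#' Narrowest interval containing a `level` fraction of the draws.
#'
#' @param samples numeric draws of one parameter (>= 100).
#' @param level interval mass, in (0, 1); default 0.95.
#' @return Named numeric `c(lo, hi)`.
#' @export
hpdi <- function(samples, level = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 100) stop("hpdi: need at least 100 draws")
  stopifnot(level > 0, level < 1)
  x <- sort(samples)
  n <- length(x)
  k <- max(1, ceiling(level * n))
  if (k >= n) return(c(lo = x[1], hi = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(lo = x[i], hi = x[i + k])
}

# multi-chain Rhat over a list of equal-length draws vectors
multichain_rhat <- function(xs) {
  n <- min(lengths(xs))
  h <- vapply(xs, function(x) x[seq_len(n)], numeric(n))
  W <- mean(apply(h, 2, var))
  B <- n * var(colMeans(h))
  if (W <= 0) return(if (B > 0) Inf else 1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# split-Rhat of one chain: potential scale reduction of its two halves
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  h <- cbind(x[1:n], x[(length(x) - n + 1):length(x)])
  W <- mean(apply(h, 2, var))
  B <- n * var(colMeans(h))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Pooled posterior summaries with convergence screening
#'
#' Applies burn-in and excludes non-convergent chains before pooling, using
#' three documented rules: (i) a chain whose worst per-parameter split-Rhat
#' (potential scale reduction between the two halves of the retained draws)
#' exceeds `rhat_threshold` is excluded; (ii) a chain that never moved
#' (zero variance in some parameter) is excluded; (iii) among the remaining
#' chains, if the multi-chain Rhat still exceeds the threshold -- the
#' signature of chains settled in different posterior modes -- chains with
#' the lowest mean log-posterior are dropped one at a time until the
#' survivors agree (the dominant-mode group is kept). Reports per-parameter
#' posterior mean, SD and HPDI on the natural scale.
#'
#' @param chains list of `chain_result` objects (>= 1).
#' @param burn_in fraction of each chain discarded (default 0.5).
#' @param level HPDI mass (default 0.95).
#' @param rhat_threshold exclusion threshold (default 1.1).
#' @param screen apply the convergence screen (default TRUE); with FALSE all
#'   chains are pooled regardless (use for quick unscreened looks only).
#' @return Data frame with columns `parameter`, `mean`, `sd`, `hpdi_lo`,
#'   `hpdi_hi`; attributes `excluded` (indices) and `rhat` (chain x
#'   parameter matrix).
#' @export
posterior_summaries <- function(chains, burn_in = 0.5, level = 0.95,
                                rhat_threshold = 1.1, screen = TRUE) {
  if (inherits(chains, "chain_result")) chains <- list(chains)
  stopifnot(length(chains) >= 1, burn_in >= 0, burn_in < 1)
  keep_tail <- function(x) {
    n <- NROW(x)
    idx <- (floor(burn_in * n) + 1):n
    if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
  }
  kept <- lapply(chains, function(ch) keep_tail(ch$samples))
  rh <- do.call(rbind, lapply(kept, function(s)
    apply(log(pmax(s, 1e-300)), 2, split_rhat)))
  colnames(rh) <- colnames(kept[[1]])
  stuck <- vapply(kept, function(s) any(apply(s, 2, var) == 0), logical(1))
  bad <- if (screen) which(apply(rh, 1, max) > rhat_threshold | stuck)
    else integer(0)
  ok <- setdiff(seq_along(kept), bad)
  if (!length(ok))
    stop("posterior_summaries: all chains flagged as non-convergent")
  # mode-agreement screen across the surviving chains
  lp <- lapply(chains, function(ch)
    if (!is.null(ch$lp_fine)) mean(keep_tail(ch$lp_fine)) else NA_real_)
  while (screen && length(ok) > 1) {
    logs <- lapply(kept[ok], function(s) log(pmax(s, 1e-300)))
    multi <- vapply(seq_len(ncol(rh)), function(j)
      multichain_rhat(lapply(logs, function(s) s[, j])), numeric(1))
    if (max(multi) <= rhat_threshold || anyNA(unlist(lp[ok]))) break
    ok <- ok[-which.min(unlist(lp[ok]))]
  }
  bad <- setdiff(seq_along(kept), ok)
  if (length(bad))
    message("posterior_summaries: excluding non-convergent chain(s) ",
            paste(bad, collapse = ", "))
  pool <- do.call(rbind, kept[ok])
  out <- data.frame(parameter = colnames(pool),
                    mean = colMeans(pool),
                    sd = apply(pool, 2, sd), row.names = NULL)
  hp <- t(apply(pool, 2, hpdi, level = level))
  out$hpdi_lo <- hp[, 1]
  out$hpdi_hi <- hp[, 2]
  attr(out, "excluded") <- bad
  attr(out, "rhat") <- rh
  out
}
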