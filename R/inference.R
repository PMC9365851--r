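#' Observed spatiotemporal line-profile dataset
#'
#' Noisy HURP intensity profiles around a directional switch: `y_plus`
#' holds the trailing-side (polymerising) matrix and `y_minus` the
#' leading-side (depolymerising) matrix, both with one row per
#' observation time and one column per observation position. The default
#' observation grid of the generators mirrors lattice light-sheet
#' sampling: a point every 104 nm in space and every 4.1 s in time, over
#' profiles extending 3 um from the kinetochore.
#'
#' @param x_obs Observation positions (um).
#' @param t_obs Observation times (s), shared between the two sides
#'   (times are measured from each side's directional switch).
#' @param y_plus,y_minus Intensity matrices, `length(t_obs)` rows by
#'   `length(x_obs)` columns.
#' @param sigma Fixed Gaussian measurement error (intensity units), > 0.
#' @return An object of class `observed_profiles`.
#' @export
observed_profiles <- function(x_obs, t_obs, y_plus, y_minus, sigma) {
  for (nm in c("y_plus", "y_minus")) {
    y <- get(nm)
    if (!is.matrix(y) || nrow(y) != length(t_obs) ||
        ncol(y) != length(x_obs)) {
      stop("'", nm, "' must be a ", length(t_obs), " x ", length(x_obs),
           " matrix (times x positions)", call. = FALSE)
    }
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  structure(list(x_obs = x_obs, t_obs = t_obs, y_plus = y_plus,
                 y_minus = y_minus, sigma = sigma),
            class = "observed_profiles")
}

#' @export
print.observed_profiles <- function(x, ...) {
  cat(sprintf(paste0("observed profiles: %d times x %d positions per side, ",
                     "dx = %g um, dt = %g s, sigma = %g\n"),
              length(x$t_obs), length(x$x_obs),
              if (length(x$x_obs) > 1) x$x_obs[2] - x$x_obs[1] else NA,
              if (length(x$t_obs) > 1) x$t_obs[2] - x$t_obs[1] else NA,
              x$sigma))
  invisible(x)
}

#' Estimate the measurement error from the data
#'
#' The observation noise is treated as known and fixed during inference.
#' When no external value is available it is estimated as the standard
#' deviation of first differences of the intensity along the spatial
#' coordinate divided by sqrt(2) (differencing removes the smooth signal
#' and doubles the noise variance).
#'
#' @param y Intensity matrix (times x positions) or an
#'   `observed_profiles` object (both sides pooled).
#' @return Estimated sigma (intensity units).
#' @export
estimate_sigma <- function(y) {
  if (inherits(y, "observed_profiles")) {
    d <- c(apply(y$y_plus, 1, diff), apply(y$y_minus, 1, diff))
  } else {
    d <- c(apply(y, 1, diff))
  }
  stats::sd(d) / sqrt(2)
}

#' Gaussian log-likelihood of observed profiles
#'
#' The likelihood is a product of independent Gaussians over sides
#' (trailing +, leading -), positions and times, with the model solution
#' as mean and the fixed measurement error `data$sigma` as standard
#' deviation. Model runs are evaluated on the observation grid by linear
#' interpolation in space; observation times must match solver output
#' times.
#'
#' @param params A [model_parameters()] object (not used for the noise;
#'   `data$sigma` is authoritative).
#' @param data An [observed_profiles()] dataset.
#' @param model_runs List with `leading` and `trailing` `hurp_profile`
#'   elements, as returned by [alternating_run()].
#' @return Log likelihood (scalar).
#' @export
log_likelihood <- function(params, data, model_runs) {
  H_plus <- evaluate_profile(model_runs$trailing, data$x_obs, data$t_obs)
  H_minus <- evaluate_profile(model_runs$leading, data$x_obs, data$t_obs)
  if (!all(dim(H_plus) == dim(data$y_plus)) ||
      !all(dim(H_minus) == dim(data$y_minus))) {
    stop("model evaluation does not conform to the observation grid",
         call. = FALSE)
  }
  sum(stats::dnorm(data$y_plus, H_plus, data$sigma, log = TRUE)) +
    sum(stats::dnorm(data$y_minus, H_minus, data$sigma, log = TRUE))
}

# multivariate normal log density at x with mean 0, covariance Sigma
ldmvnorm0 <- function(x, chol_sigma) {
  z <- backsolve(chol_sigma, x, transpose = TRUE)
  -0.5 * (sum(z^2) + length(x) * log(2 * pi)) -
    sum(log(diag(chol_sigma)))
}

#' Log-space random-walk proposal
#'
#' Proposes theta'_i = sign(theta_i) exp(log(delta_i + |theta_i|) + xi_i)
#' with xi ~ N(0, Sigma), jointly across the parameters: a random walk on
#' the (shifted) log scale, with the small tolerance `delta` preventing
#' the walk from freezing near 0. The map is asymmetric for delta > 0
#' (and the back-transform to the natural scale has a Jacobian), so the
#' exact Metropolis-Hastings log correction
#' log q(theta | theta') - log q(theta' | theta) is returned alongside.
#'
#' @param theta Named numeric vector of current parameter values.
#' @param Sigma Proposal covariance on the transformed scale (matrix, or
#'   scalar for an isotropic proposal). Must be positive-definite (the
#'   all-zero matrix is accepted as the degenerate identity proposal).
#' @param delta Per-parameter tolerance vector (recycled), >= 0.
#' @param xi Optional forced innovation vector (for testing); drawn from
#'   N(0, Sigma) when `NULL`.
#' @return List with `theta` (proposed values) and `log_hastings`.
#' @examples
#' propose_params(c(l = 1, D = 0.02), Sigma = diag(0.01, 2))
#' @export
propose_params <- function(theta, Sigma, delta = 1e-8, xi = NULL) {
  d <- length(theta)
  if (length(Sigma) == 1L) Sigma <- diag(as.numeric(Sigma), d)
  if (!all(dim(Sigma) == c(d, d))) {
    stop("'Sigma' must conform to the parameter vector", call. = FALSE)
  }
  delta <- rep_len(delta, d)
  if (any(delta < 0)) stop("'delta' must be >= 0", call. = FALSE)

  degenerate <- all(Sigma == 0)
  R <- NULL
  if (!degenerate) {
    R <- tryCatch(chol(Sigma), error = function(e) {
      stop("proposal covariance must be positive-definite", call. = FALSE)
    })
  }
  if (is.null(xi)) {
    xi <- if (degenerate) rep(0, d) else
      as.numeric(crossprod(R, stats::rnorm(d)))
  }
  theta_prop <- sign(theta) * exp(log(delta + abs(theta)) + xi)
  names(theta_prop) <- names(theta)

  if (degenerate) {
    return(list(theta = theta_prop, log_hastings = 0))
  }
  xi_rev <- log(abs(theta)) - log(delta + abs(theta_prop))
  lh <- ldmvnorm0(xi_rev, R) - ldmvnorm0(xi, R) +
    sum(log(abs(theta_prop)) - log(abs(theta)))
  list(theta = theta_prop, log_hastings = lh)
}

#' Generic random-walk Metropolis sampler with the log-space proposal
#'
#' Workhorse behind [run_mcmc()], usable directly on any log target
#' density over positive parameters (e.g. for sampler validation on
#' closed-form targets).
#'
#' @param log_post Function mapping a named parameter vector to a log
#'   density (may return `-Inf`).
#' @param init Named numeric initial vector with finite `log_post`.
#' @param Sigma,delta Proposal covariance and tolerance, see
#'   [propose_params()].
#' @param n_iter Number of iterations.
#' @param hastings Apply the exact Metropolis-Hastings correction for the
#'   asymmetric log-space map (default `TRUE`); `FALSE` reproduces a
#'   plain Metropolis accept rule on the proposal.
#' @param adapt_until Iteration up to which the proposal adapts: an
#'   exponentially weighted running covariance of the transformed draws
#'   (ridge-regularised, so every direction stays proposable) combined
#'   with Robbins-Monro tuning of a global scale toward
#'   `target_accept`. 0 disables adaptation; the kernel is frozen after
#'   `adapt_until`, so draws beyond it come from a fixed, valid
#'   Metropolis-Hastings kernel. Intended to coincide with the
#'   discarded burn-in.
#' @param target_accept Acceptance target of the scale adaptation.
#' @return List with `draws` (n_iter x d matrix), `log_post` trace,
#'   `acceptance_rate` (over post-adaptation iterations when adapting)
#'   and the final proposal covariance `Sigma`.
#' @export
metropolis_sampler <- function(log_post, init, Sigma, delta = 1e-8,
                               n_iter, hastings = TRUE,
                               adapt_until = 0, target_accept = 0.234) {
  d <- length(init)
  if (length(Sigma) == 1L) Sigma <- diag(as.numeric(Sigma), d)
  delta <- rep_len(delta, d)
  draws <- matrix(NA_real_, n_iter, d,
                  dimnames = list(NULL, names(init)))
  lp_trace <- numeric(n_iter)
  cur <- init
  lp_cur <- log_post(cur)
  if (!is.finite(lp_cur)) {
    stop("'init' must have finite log posterior", call. = FALSE)
  }
  Sig_cur <- Sigma
  lscale <- 0
  # exponentially weighted moments of the transformed draws; seeded from
  # the supplied covariance so early proposals stay sensible
  ew <- 0.01
  ridge <- diag(0.05^2, d)
  scale_d <- 2.38^2 / d
  C_run <- Sigma / scale_d
  m_run <- log(delta + abs(cur))
  n_acc <- 0L
  n_acc_post <- 0L
  for (i in seq_len(n_iter)) {
    prop <- propose_params(cur, Sig_cur, delta)
    lp_prop <- log_post(prop$theta)
    log_alpha <- lp_prop - lp_cur + if (hastings) prop$log_hastings else 0
    accepted <- is.finite(lp_prop) && log(stats::runif(1)) < log_alpha
    if (accepted) {
      cur <- prop$theta
      lp_cur <- lp_prop
      n_acc <- n_acc + 1L
      if (i > adapt_until) n_acc_post <- n_acc_post + 1L
    }
    draws[i, ] <- cur
    lp_trace[i] <- lp_cur
    if (i <= adapt_until) {
      alpha <- if (is.finite(lp_prop)) min(1, exp(min(0, log_alpha)))
               else 0
      gain <- min(0.5, 10 / i^0.8)
      lscale <- max(-15, min(5, lscale + gain * (alpha - target_accept)))
      eta <- pmax(pmin(log(delta + abs(cur)), 30), -30)
      m_run <- (1 - ew) * m_run + ew * eta
      dev <- eta - m_run
      C_run <- (1 - ew) * C_run + ew * tcrossprod(dev)
      Sig_cur <- exp(lscale) * scale_d * (C_run + ridge)
    }
  }
  n_post <- n_iter - adapt_until
  list(draws = draws, log_post = lp_trace,
       acceptance_rate = if (adapt_until > 0 && n_post > 0)
         n_acc_post / n_post else n_acc / n_iter,
       Sigma = Sig_cur)
}

#' MCMC configuration
#'
#' @param n_iter Iterations per chain.
#' @param n_chains Number of independent chains.
#' @param pilot_iter Length of the pilot run used to tune the proposal
#'   covariance (0 skips tuning and uses `proposal_cov` directly).
#' @param proposal_cov Initial proposal covariance on the transformed
#'   scale (scalar or matrix); also the pilot's proposal.
#' @param delta Log-space proposal tolerance, see [propose_params()].
#' @param burn_in_fraction Fraction of each chain discarded as burn-in.
#' @param seed RNG seed; every random element of the fit flows from it.
#' @param hastings Apply the exact Metropolis-Hastings correction
#'   (see [metropolis_sampler()]).
#' @param init_pool Number of finite-posterior prior draws scored per
#'   chain initialisation; the highest-posterior candidate starts the
#'   chain. 1 reproduces a plain prior-draw start; larger pools shorten
#'   the burn-in needed on short runs.
#' @param adapt_burnin Continue adapting each chain's proposal during
#'   its discarded burn-in phase (recommended; see
#'   [metropolis_sampler()]). `FALSE` freezes the kernel right after the
#'   pilot, replicating a strict single-pilot protocol.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 10000, n_chains = 4, pilot_iter = 1000,
                        proposal_cov = 0.01, delta = 1e-8,
                        burn_in_fraction = 0.5, seed = 1,
                        hastings = TRUE, adapt_burnin = TRUE,
                        init_pool = 25) {
  if (pilot_iter < 0) stop("'pilot_iter' must be >= 0", call. = FALSE)
  if (n_iter <= pilot_iter) {
    stop("'n_iter' must exceed 'pilot_iter'", call. = FALSE)
  }
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    stop("'burn_in_fraction' must be in [0, 1)", call. = FALSE)
  }
  structure(list(n_iter = n_iter, n_chains = n_chains,
                 pilot_iter = pilot_iter, proposal_cov = proposal_cov,
                 delta = delta, burn_in_fraction = burn_in_fraction,
                 seed = seed, hastings = hastings,
                 adapt_burnin = adapt_burnin,
                 init_pool = max(1L, as.integer(init_pool))),
            class = "mcmc_config")
}

#' Fit the HURP model to observed profiles by random-walk Metropolis
#'
#' Samples the posterior of the dynamic model parameters given a
#' spatiotemporal profile dataset. The protocol: a short pilot run tunes
#' the proposal covariance from the empirical covariance of the pilot
#' draws on the transformed (shifted-log) scale, scaled by the standard
#' optimal random-walk factor 2.38^2/d (plus a tiny diagonal jitter);
#' then `n_chains` independent chains of `n_iter` iterations are run,
#' each initialised from a prior draw, and the first `burn_in_fraction`
#' of each chain is marked as burn-in. A forward-solver failure at a
#' proposed parameter vector is treated as log posterior `-Inf` (the
#' proposal is rejected with a warning); the fit never aborts for that
#' reason. The whole procedure is reproducible from `config$seed`.
#'
#' @param data An [observed_profiles()] dataset (its `sigma` is the fixed
#'   measurement error; use [estimate_sigma()] when unknown).
#' @param priors Named list of prior entries for the *inferred*
#'   parameters (defaults to [default_priors()] minus anything in
#'   `fixed`).
#' @param config An [mcmc_config()].
#' @param fixed Named list of dynamic parameters held fixed at given
#'   values (e.g. `list(s = 3)`); they are excluded from theta.
#' @param grid Internal solver grid, a [spatial_grid()]; defaults to 300
#'   cells over L = 3 um (finer than the 104 nm observation spacing).
#' @param equilibrium_method Passed to [alternating_run()].
#' @return A `posterior_samples` object: `draws` (chains x iterations x
#'   parameters array), `log_post`, per-chain `acceptance_rate`,
#'   `burn_in` (last discarded iteration), `parameters`, plus the
#'   configuration used.
#' @seealso [summarize_posterior()]
#' @export
run_mcmc <- function(data, priors = NULL, config = mcmc_config(),
                     fixed = list(), grid = NULL,
                     equilibrium_method = "direct") {
  if (!inherits(data, "observed_profiles")) {
    stop("'data' must be an observed_profiles dataset", call. = FALSE)
  }
  if (is.null(grid)) grid <- spatial_grid(3, 300)
  if (is.null(priors)) {
    priors <- default_priors()
    priors[names(fixed)] <- NULL
  }
  inferred <- intersect(theta_names(), names(priors))
  if (!length(inferred)) stop("no parameters to infer", call. = FALSE)
  priors <- priors[inferred]
  if (length(bad <- setdiff(names(fixed), theta_names()))) {
    stop("unknown fixed parameters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  t_obs <- data$t_obs
  dts <- diff(t_obs)
  if (length(dts) < 1L || max(abs(dts - dts[1])) > 1e-9) {
    stop("'t_obs' must be a uniform time grid", call. = FALSE)
  }
  dt_out <- dts[1]
  duration <- max(t_obs)

  make_params <- function(theta) {
    args <- as.list(theta)
    args[names(fixed)] <- fixed
    args$sigma <- data$sigma
    args$L <- grid$L
    do.call(model_parameters, args)
  }
  log_post <- function(theta) {
    if (any(theta <= 0)) return(-Inf)
    lp <- log_prior(theta, priors)
    if (!is.finite(lp)) return(-Inf)
    params <- tryCatch(make_params(theta), error = function(e) NULL)
    if (is.null(params)) return(-Inf)
    runs <- tryCatch(
      alternating_run(params, grid, t_lead = duration, t_trail = duration,
                      dt_out = dt_out,
                      equilibrium_method = equilibrium_method),
      error = function(e) {
        warning("forward solver failed at a proposed parameter vector: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(runs)) return(-Inf)
    lp + log_likelihood(params, data, runs)
  }

  set.seed(config$seed)
  d <- length(inferred)
  delta <- rep_len(config$delta, d)

  # initialise from the best of a pool of prior draws: with short chains
  # a raw prior draw can sit many log-units from the posterior bulk and
  # exhaust the burn-in just descending
  draw_init <- function(pool = config$init_pool) {
    best <- NULL
    best_lp <- -Inf
    found <- 0L
    for (tries in seq_len(50L * pool)) {
      th <- draw_prior(priors)
      lp <- log_post(th)
      if (is.finite(lp)) {
        found <- found + 1L
        if (lp > best_lp) {
          best <- th
          best_lp <- lp
        }
        if (found >= pool) break
      }
    }
    if (is.null(best)) {
      stop("could not find a prior draw with finite posterior",
           call. = FALSE)
    }
    best
  }

  Sigma0 <- config$proposal_cov
  if (length(Sigma0) == 1L) Sigma0 <- diag(as.numeric(Sigma0), d)
  Sigma <- Sigma0
  if (config$pilot_iter > 0) {
    pilot <- metropolis_sampler(log_post, draw_init(), Sigma0, delta,
                                config$pilot_iter,
                                hastings = config$hastings)
    if (pilot$acceptance_rate == 0) {
      stop("pilot run accepted no proposals; shrink 'proposal_cov' or ",
           "revisit the priors", call. = FALSE)
    }
    # covariance from the pilot's second half: the early pilot is still
    # descending from its prior-draw start and would inflate the estimate
    half <- seq.int(floor(config$pilot_iter / 2) + 1L, config$pilot_iter)
    eta <- log(sweep(abs(pilot$draws[half, , drop = FALSE]), 2, delta,
                     "+"))
    # ridge keeps every direction proposable even when the pilot barely
    # explored one of them
    Sigma <- (2.38^2 / d) * (stats::cov(eta) + diag(0.05^2, d))
    if (any(!is.finite(Sigma))) Sigma <- Sigma0
  }

  draws <- array(NA_real_,
                 dim = c(config$n_chains, config$n_iter, d),
                 dimnames = list(NULL, NULL, inferred))
  lp_mat <- matrix(NA_real_, config$n_chains, config$n_iter)
  acc <- numeric(config$n_chains)
  burn <- floor(config$burn_in_fraction * config$n_iter)
  adapt_until <- if (isTRUE(config$adapt_burnin)) burn else 0
  for (ch in seq_len(config$n_chains)) {
    res <- metropolis_sampler(log_post, draw_init(), Sigma, delta,
                              config$n_iter, hastings = config$hastings,
                              adapt_until = adapt_until)
    draws[ch, , ] <- res$draws
    lp_mat[ch, ] <- res$log_post
    acc[ch] <- res$acceptance_rate
  }

  structure(list(draws = draws, log_post = lp_mat,
                 acceptance_rate = acc,
                 burn_in = burn,
                 parameters = inferred, fixed = fixed,
                 priors = priors, config = config,
                 proposal_cov = Sigma),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf(paste0("posterior samples: %d chains x %d iterations, %d ",
                     "parameters (%s)\n  burn-in: first %d iterations per ",
                     "chain; acceptance %.2f-%.2f\n"),
              dim(x$draws)[1], dim(x$draws)[2], dim(x$draws)[3],
              paste(x$parameters, collapse = ", "), x$burn_in,
              min(x$acceptance_rate), max(x$acceptance_rate)))
  invisible(x)
}

# Split-chain potential scale reduction factor for one parameter:
# each chain's retained draws are split in half, and the classic
# between/within variance ratio is computed over the 2m half-chains.
split_rhat <- function(chains) {
  halves <- list()
  for (i in seq_len(nrow(chains))) {
    v <- chains[i, ]
    n2 <- floor(length(v) / 2)
    halves[[length(halves) + 1L]] <- v[seq_len(n2)]
    halves[[length(halves) + 1L]] <- v[seq.int(n2 + 1L, 2L * n2)]
  }
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarise posterior samples
#'
#' Medians and central 95% credible intervals from pooled post-burn-in
#' draws, the mean acceptance rate, and a split-chain Rhat convergence
#' diagnostic per parameter (values near 1 indicate convergence;
#' degenerate constant chains yield `NA`).
#'
#' @param samples A `posterior_samples` object from [run_mcmc()].
#' @return A data.frame with one row per parameter: `parameter`,
#'   `median`, `q2.5`, `q97.5`, `acceptance_rate`, `rhat`.
#' @export
summarize_posterior <- function(samples) {
  dd <- dim(samples$draws)
  if (dd[1] < 2L) {
    stop("at least 2 chains are required to summarise", call. = FALSE)
  }
  keep <- seq.int(samples$burn_in + 1L, dd[2])
  if (length(keep) < 2L) {
    stop("no post-burn-in draws to summarise", call. = FALSE)
  }
  out <- data.frame(parameter = samples$parameters,
                    median = NA_real_, q2.5 = NA_real_, q97.5 = NA_real_,
                    acceptance_rate = mean(samples$acceptance_rate),
                    rhat = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(samples$parameters)) {
    pooled <- as.numeric(samples$draws[, keep, k])
    qs <- stats::quantile(pooled, c(0.025, 0.5, 0.975), names = FALSE,
                          type = 7)
    out$median[k] <- qs[2]
    out$q2.5[k] <- qs[1]
    out$q97.5[k] <- qs[3]
    out$rhat[k] <- split_rhat(samples$draws[, keep, k, drop = TRUE])
  }
  out
}
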