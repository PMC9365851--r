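# a small noisy dataset on a coarse shared grid for sampler tests
mcmc_fixture <- function(sigma = NULL, seed = 21, n_cells = 20,
                         duration = 24.6) {
  g <- spatial_grid(3, n_cells)
  truth <- model_parameters()
  ds <- generate_profile_dataset(truth, t_lead = duration,
                                 t_trail = duration, sigma = sigma,
                                 seed = seed, grid = g)
  list(grid = g, truth = truth, data = ds)
}

test_that("the sampler reproduces a closed-form 1-D posterior", {
  target <- function(th) stats::dlnorm(th[["x"]], 0.5, 0.8, log = TRUE)
  set.seed(9)
  out <- metropolis_sampler(target, c(x = 1), Sigma = diag((2.4 * 0.8)^2, 1),
                            delta = 1e-8, n_iter = 1e4)
  expect_gt(out$acceptance_rate, 0.2)
  draws <- out$draws[-(1:2500), 1]
  thin <- draws[seq(1, length(draws), by = 10)]
  ks <- suppressWarnings(stats::ks.test(thin, "plnorm", 0.5, 0.8))
  expect_gt(ks$p.value, 0.01)
})

test_that("the same seed reproduces the fit bitwise", {
  fx <- mcmc_fixture()
  cfg <- mcmc_config(n_iter = 40, n_chains = 2, pilot_iter = 10,
                     seed = 123)
  fit1 <- run_mcmc(fx$data, config = cfg, grid = fx$grid)
  fit2 <- run_mcmc(fx$data, config = cfg, grid = fx$grid)
  expect_identical(fit1$draws, fit2$draws)
  expect_identical(fit1$acceptance_rate, fit2$acceptance_rate)
})

test_that("with an uninformative likelihood the posterior reproduces the prior", {
  fx <- mcmc_fixture()
  flat <- fx$data
  flat$sigma <- 1e8   # likelihood is effectively constant over the prior
  pr <- default_priors()[c("l", "mu")]
  cfg <- mcmc_config(n_iter = 4000, n_chains = 4, pilot_iter = 200,
                     seed = 42)
  all_theta <- c("l", "D", "lam", "mu", "v_plus", "v_minus", "gamma1",
                 "gamma2", "s", "r")
  fit <- run_mcmc(flat, priors = pr, config = cfg,
                  fixed = as.list(unlist(fx$truth)[
                    setdiff(all_theta, c("l", "mu"))]),
                  grid = fx$grid)
  keep <- seq.int(fit$burn_in + 1L, dim(fit$draws)[2])
  probs <- c(0.25, 0.5, 0.75)
  # mu's prior is untouched by any support constraint ...
  pooled_mu <- log(as.numeric(fit$draws[, keep, "mu"]))
  expect_equal(quantile(pooled_mu, probs, names = FALSE),
               qnorm(probs, pr$mu$meanlog, pr$mu$sdlog),
               tolerance = 0.2)
  # ... while l's support is truncated at the domain length L = 3, so
  # the sampler should reproduce the *truncated* prior
  pooled_l <- log(as.numeric(fit$draws[, keep, "l"]))
  p_trunc <- plnorm(3, pr$l$meanlog, pr$l$sdlog)
  expect_equal(quantile(pooled_l, probs, names = FALSE),
               qnorm(probs * p_trunc, pr$l$meanlog, pr$l$sdlog),
               tolerance = 0.2)
  expect_lt(max(pooled_l), log(3) + 1e-9)
})

test_that("posterior summaries match brute-force order statistics", {
  # hand-built sample container
  draws <- array(NA_real_, dim = c(2, 10, 1),
                 dimnames = list(NULL, NULL, "l"))
  draws[1, , 1] <- 1:10
  draws[2, , 1] <- 1:10
  samp <- structure(list(draws = draws, acceptance_rate = c(0.5, 0.5),
                         burn_in = 5L, parameters = "l"),
                    class = "posterior_samples")
  sm <- summarize_posterior(samp)
  expect_equal(sm$median, median(rep(6:10, 2)))

  set.seed(8)
  big <- array(rnorm(2 * 5000, 10, 2), dim = c(2, 5000, 1),
               dimnames = list(NULL, NULL, "x"))
  big[big <= 0] <- 0.1
  samp2 <- structure(list(draws = big, acceptance_rate = c(0.4, 0.4),
                          burn_in = 0L, parameters = "x"),
                     class = "posterior_samples")
  sm2 <- summarize_posterior(samp2)
  # brute-force linear-interpolation order statistic (type-7 definition
  # recomputed by hand)
  pooled <- sort(as.numeric(big))
  bf <- function(p) {
    h <- (length(pooled) - 1) * p + 1
    lo <- floor(h)
    pooled[lo] + (h - lo) * (pooled[min(lo + 1, length(pooled))] - pooled[lo])
  }
  expect_equal(sm2$median, bf(0.5), tolerance = 1e-12)
  expect_equal(sm2$q2.5, bf(0.025), tolerance = 1e-12)
  expect_equal(sm2$q97.5, bf(0.975), tolerance = 1e-12)
})

test_that("degenerate constant chains are flagged in the diagnostics", {
  draws <- array(3, dim = c(2, 20, 1),
                 dimnames = list(NULL, NULL, "l"))
  samp <- structure(list(draws = draws, acceptance_rate = c(0, 0),
                         burn_in = 0L, parameters = "l"),
                    class = "posterior_samples")
  sm <- summarize_posterior(samp)
  expect_equal(sm$median, 3)
  expect_equal(sm$q2.5, 3)
  expect_equal(sm$q97.5, 3)
  expect_true(is.na(sm$rhat))
})

test_that("summaries require chains and post-burn-in draws", {
  draws <- array(1, dim = c(1, 10, 1),
                 dimnames = list(NULL, NULL, "l"))
  samp <- structure(list(draws = draws, acceptance_rate = 0.1,
                         burn_in = 5L, parameters = "l"),
                    class = "posterior_samples")
  expect_error(summarize_posterior(samp), "2 chains")
})

test_that("independently initialised chains converge to overlapping marginals", {
  # identifiable reduced fit: the three turnover/transport parameters
  # the data constrain most directly, others held at truth
  g <- spatial_grid(3, 30)
  truth <- model_parameters()
  ds <- generate_profile_dataset(truth, 61.5, 61.5, sigma = NULL,
                                 seed = 9, grid = g)
  all_theta <- c("l", "D", "lam", "mu", "v_plus", "v_minus", "gamma1",
                 "gamma2", "s", "r")
  fx <- as.list(unlist(truth)[setdiff(all_theta, c("l", "D", "mu"))])
  fit <- run_mcmc(ds, priors = default_priors()[c("l", "D", "mu")],
                  config = mcmc_config(n_iter = 8000, n_chains = 4,
                                       pilot_iter = 500, seed = 3),
                  fixed = fx, grid = g)
  sm <- summarize_posterior(fit)
  expect_true(all(sm$rhat < 1.1))
  # and the marginals sit on the generating values
  for (nm in c("l", "D", "mu")) {
    row <- sm[sm$parameter == nm, ]
    tv <- unlist(truth)[[nm]]
    expect_true(row$q2.5 <= tv && tv <= row$q97.5)
  }
})
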