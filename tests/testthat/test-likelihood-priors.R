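make_runs_and_data <- function(sigma = 1, seed = NULL, perturb = 0) {
  g <- spatial_grid(3, 12)
  p <- model_parameters()
  times <- c(0, 4.1, 8.2)
  runs <- alternating_run(p, g, t_lead = 8.2, t_trail = 8.2,
                          dt_out = 4.1)
  y_plus <- evaluate_profile(runs$trailing, g$x, times)
  y_minus <- evaluate_profile(runs$leading, g$x, times)
  if (perturb > 0) {
    set.seed(seed)
    y_plus <- y_plus + rnorm(length(y_plus), 0, perturb)
    y_minus <- y_minus + rnorm(length(y_minus), 0, perturb)
  }
  data <- observed_profiles(g$x, times, y_plus, y_minus, sigma)
  list(params = p, data = data, runs = runs)
}

test_that("perfect agreement gives N log(1/sqrt(2 pi)) at sigma = 1", {
  s <- make_runs_and_data(sigma = 1)
  n_pts <- 2 * length(s$data$t_obs) * length(s$data$x_obs)
  expect_equal(log_likelihood(s$params, s$data, s$runs),
               n_pts * log(1 / sqrt(2 * pi)), tolerance = 1e-12)
})

test_that("a single residual of exactly sigma costs the standard normal exponent", {
  s <- make_runs_and_data(sigma = 0.7)
  base <- log_likelihood(s$params, s$data, s$runs)
  s$data$y_plus[2, 3] <- s$data$y_plus[2, 3] + 0.7
  shifted <- log_likelihood(s$params, s$data, s$runs)
  # difference relative to an exact match: -0.5 (the exponent)
  expect_equal(shifted - base, -0.5, tolerance = 1e-12)
  # absolute value of one perfect term: -log(sigma sqrt(2 pi))
  expect_equal(base / (2 * 3 * 12), -log(0.7 * sqrt(2 * pi)),
               tolerance = 1e-12)
})

test_that("log likelihood equals a brute-force product of normal densities", {
  s <- make_runs_and_data(sigma = 0.4, seed = 11, perturb = 0.5)
  H_plus <- evaluate_profile(s$runs$trailing, s$data$x_obs, s$data$t_obs)
  H_minus <- evaluate_profile(s$runs$leading, s$data$x_obs, s$data$t_obs)
  # independent oracle: accumulate density terms one by one in a loop
  acc <- 0
  for (i in seq_along(s$data$t_obs)) {
    for (j in seq_along(s$data$x_obs)) {
      acc <- acc +
        log(exp(-(s$data$y_plus[i, j] - H_plus[i, j])^2 / (2 * 0.4^2)) /
              (0.4 * sqrt(2 * pi))) +
        log(exp(-(s$data$y_minus[i, j] - H_minus[i, j])^2 / (2 * 0.4^2)) /
              (0.4 * sqrt(2 * pi)))
    }
  }
  expect_equal(log_likelihood(s$params, s$data, s$runs), acc,
               tolerance = 1e-10)
})

test_that("likelihood is largest near the generating parameters on clean data", {
  g <- spatial_grid(3, 24)
  truth <- model_parameters()
  ds <- generate_profile_dataset(truth, t_lead = 20.5, t_trail = 20.5,
                                 sigma = 0, grid = g)
  ll_at <- function(mu) {
    p <- model_parameters(mu = mu)
    runs <- alternating_run(p, g, 20.5, 20.5, dt_out = 4.1)
    log_likelihood(p, ds, runs)
  }
  mus <- c(0.05, 0.08, 0.1, 0.125, 0.2)
  lls <- vapply(mus, ll_at, numeric(1))
  expect_equal(mus[which.max(lls)], 0.1)
})

test_that("observation grid mismatches raise shape errors", {
  s <- make_runs_and_data()
  bad <- s$data
  bad$t_obs <- c(0, 1.7, 8.2)
  expect_error(log_likelihood(s$params, bad, s$runs),
               "not among solver output times")
})

test_that("log prior matches closed-form log-normal densities and support rules", {
  pr <- default_priors()
  th <- unlist(model_parameters()[theta_names <- names(pr)])
  # brute-force log-normal density, term by term
  oracle <- sum(vapply(theta_names, function(nm) {
    x <- th[[nm]]
    m <- pr[[nm]]$meanlog
    s <- pr[[nm]]$sdlog
    -log(x * s * sqrt(2 * pi)) - (log(x) - m)^2 / (2 * s^2)
  }, numeric(1)))
  expect_equal(log_prior(th, pr), oracle, tolerance = 1e-12)
  # independence: joint = sum of marginals
  expect_equal(log_prior(th, pr),
               sum(vapply(theta_names, function(nm)
                 log_prior(th[nm], pr[nm]), numeric(1))),
               tolerance = 1e-12)
  # support is the positive reals; out of support returns -Inf, no error
  th_bad <- th
  th_bad["D"] <- -0.01
  expect_identical(log_prior(th_bad, pr), -Inf)
  th_bad["D"] <- 0
  expect_identical(log_prior(th_bad, pr), -Inf)
})

test_that("prior draws respect the specification and the r prior is tight", {
  set.seed(3)
  draws <- t(replicate(400, draw_prior(default_priors())))
  expect_true(all(draws > 0))
  expect_lt(sd(log(draws[, "r"])), 0.2)   # informative ratio prior
  expect_gt(sd(log(draws[, "D"])), 0.5)   # weakly informative elsewhere
})

test_that("measurement error estimation recovers the injected noise", {
  g <- spatial_grid(3, 40)
  ds <- generate_profile_dataset(model_parameters(), t_lead = 41,
                                 t_trail = 41, sigma = 0.4, seed = 5,
                                 grid = g)
  expect_equal(estimate_sigma(ds), 0.4, tolerance = 0.1)
})
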