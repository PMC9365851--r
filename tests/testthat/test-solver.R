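test_that("zero right-hand side leaves the initial state untouched", {
  g <- grid_small(40)
  p <- model_parameters(l = 0, D = 0, lam = 0, mu = 0, v_plus = 0,
                        v_minus = 0, gamma1 = 0, gamma2 = 0)
  init <- gaussian_bump(g$x, 1.5, 0.4)
  out <- simulate_hurp(p, g, init, duration = 30, dt_out = 10)
  for (j in seq_along(out$times)) {
    expect_equal(out$H[j, ], init, tolerance = 1e-12)
  }
})

test_that("reaction-only dynamics relax to lambda/mu uniformly", {
  g <- grid_small(30)
  # s large makes g(x) ~ 1 across the 3 um window
  p <- model_parameters(l = 0, D = 0, lam = 0.2, mu = 0.1, v_plus = 0,
                        v_minus = 0, gamma1 = 0, gamma2 = 0, s = 1e9,
                        r = 1)
  out <- simulate_hurp(p, g, rep(0, g$n_cells), duration = 300,
                       dt_out = 300)
  expect_equal(out$H[2, ], rep(2, g$n_cells), tolerance = 1e-7)
})

test_that("pure diffusion matches the analytic heat kernel", {
  s0 <- 0.3
  D <- 0.02
  t_end <- 10
  errs <- vapply(c(75, 150, 300), function(n) {
    g <- spatial_grid(6, n)
    p <- pure_diffusion_params(D = D)
    init <- gaussian_bump(g$x, 3, s0)
    out <- simulate_hurp(p, g, init, duration = t_end, dt_out = t_end)
    s2 <- s0^2 + 2 * D * t_end
    ana <- s0 / sqrt(s2) * gaussian_bump(g$x, 3, sqrt(s2))
    max(abs(out$H[2, ] - ana)) / max(ana)
  }, numeric(1))
  expect_lt(errs[3], 0.01)           # < 1% of peak at default resolution
  expect_true(all(diff(errs) < 0))   # error shrinks under refinement
})

test_that("mass is conserved with no-flux boundaries and no reaction", {
  g <- spatial_grid(6, 150)
  p <- pure_diffusion_params()
  init <- gaussian_bump(g$x, 3, 0.5)
  out <- simulate_hurp(p, g, init, duration = 100, dt_out = 25)
  mass <- rowSums(out$H) * g$dx
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-6)
})

test_that("an advected pulse travels at speed v on the periodic harness", {
  g <- spatial_grid(6, 600)
  v <- 0.05
  p <- model_parameters(l = 0, D = 0, lam = 0, mu = 0, v_plus = v,
                        v_minus = 0, gamma1 = 0, gamma2 = 0, r = 1,
                        L = 6)
  init <- gaussian_bump(g$x, 2, 0.3)
  out <- simulate_hurp(p, g, init, duration = 10, dt_out = 10,
                       side = "trailing", boundary = "periodic")
  peak <- g$x[which.max(out$H[2, ])]
  expect_lt(abs(peak - (2 + v * 10)), g$dx)
  # mass is also conserved on the ring
  expect_equal(sum(out$H[2, ]), sum(init), tolerance = 1e-9)
})

test_that("boundary interaction strength interpolates reflecting to absorbing", {
  g <- grid_small(80)
  init <- rep(1, g$n_cells)
  gammas <- c(0, 0.01, 0.1, 1, 10)
  h_bdry <- vapply(gammas, function(g1) {
    p <- model_parameters(l = 0, D = 0.05, lam = 0, mu = 0, v_plus = 0,
                          v_minus = 0, gamma1 = g1, gamma2 = 0, r = 1)
    out <- simulate_hurp(p, g, init, duration = 20, dt_out = 20)
    out$H[2, 1]
  }, numeric(1))
  # H at the kinetochore boundary decreases monotonically in gamma1
  expect_true(all(diff(h_bdry) < 0))
  # gamma1 = 0 keeps the uniform state (no flux anywhere)
  expect_equal(h_bdry[1], 1, tolerance = 1e-9)
  # strong adsorption drives the boundary toward 0
  expect_lt(h_bdry[5], 0.25)
})

test_that("exponential-propagator solution agrees with an adaptive ODE solver", {
  skip_if_not_installed("deSolve")
  g <- grid_small(50)
  p <- model_parameters()
  op <- hurpdyn:::build_operator(p, g, side = "trailing")
  init <- gaussian_bump(g$x, 1, 0.5) * 3
  ours <- simulate_hurp(p, g, init, duration = 30, dt_out = 15,
                        side = "trailing")
  rhs <- function(t, y, parms) list(as.numeric(op$A %*% y) + op$b)
  ref <- deSolve::ode(y = init, times = c(0, 15, 30), func = rhs,
                      parms = NULL, method = "lsoda", rtol = 1e-10,
                      atol = 1e-12)
  expect_equal(ours$H[2, ], unname(ref[2, -1]), tolerance = 1e-6)
  expect_equal(ours$H[3, ], unname(ref[3, -1]), tolerance = 1e-6)
})

test_that("solutions stay non-negative across random parameter draws", {
  g <- grid_small(40)
  set.seed(7)
  for (i in 1:12) {
    p <- model_parameters(l = runif(1, 0, 2.5), D = runif(1, 0, 0.1),
                          lam = runif(1, 0, 2), mu = runif(1, 0, 0.5),
                          v_plus = runif(1, 0, 0.1),
                          v_minus = runif(1, 0, 0.1),
                          gamma1 = runif(1, 0, 0.5),
                          gamma2 = runif(1, 0, 0.5),
                          s = runif(1, 0.5, 10),
                          r = runif(1, 0.5, 10))
    side <- sample(c("leading", "trailing"), 1)
    init <- gaussian_bump(g$x, runif(1, 0, 3), 0.3) * 5
    out <- simulate_hurp(p, g, init, duration = 25, dt_out = 5,
                         side = side)
    expect_true(all(out$H >= 0))
  }
})

test_that("simulate validates its inputs", {
  g <- grid_small(20)
  p <- model_parameters()
  expect_error(simulate_hurp(p, g, rep(0, 5), 10, 1), "per grid cell")
  expect_error(simulate_hurp(p, g, rep(-1, 20), 10, 1), "non-negative")
  expect_error(simulate_hurp(p, g, rep(0, 20), -1, 1), "duration")
  expect_error(simulate_hurp(p, g, rep(0, 20), 10, 20), "dt_out")
})
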