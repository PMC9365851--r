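# Shared fixtures: coarse grids keep the suite fast; analytic-oracle
# tests use finer grids where the tolerance demands it.

grid_small <- function(n = 60, L = 3) spatial_grid(L, n)

# diffusion-only parameter set on a wide domain (heat-kernel oracle)
pure_diffusion_params <- function(D = 0.02, L = 6) {
  model_parameters(l = 0, D = D, lam = 0, mu = 0, v_plus = 0,
                   v_minus = 0, gamma1 = 0, gamma2 = 0, s = 3, r = 1,
                   L = L)
}

gaussian_bump <- function(x, centre, sd) exp(-(x - centre)^2 / (2 * sd^2))

# a tiny noiseless dataset + matching model runs on a shared grid
tiny_profile_setup <- function(n_cells = 20, duration = 12.3,
                               dt = 4.1, seed = 42) {
  g <- spatial_grid(3, n_cells)
  p <- model_parameters()
  ds <- generate_profile_dataset(p, t_lead = duration, t_trail = duration,
                                 sigma = 0.3, seed = seed, grid = g,
                                 dt_obs = dt)
  runs <- alternating_run(p, g, duration, duration, dt_out = dt)
  list(grid = g, params = p, data = ds, runs = runs)
}
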