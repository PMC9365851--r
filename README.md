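# hurpdyn

Spatiotemporal modelling of the microtubule-associated protein HURP on
kinetochore-fibres (K-fibres).

During metaphase, HURP decorates K-fibres but is excluded from a
kinetochore-proximal region of the polymerising (trailing) fibre — the
HURP-gap. `hurpdyn` implements a minimal continuum model of this
behaviour and the analyses built around it, for spindle biophysicists
who want to fit or probe the mechanism with their own line-profile,
FRAP or particle-tracking data:

- **Forward model** — the HURP intensity field H(x, t) along a fibre
  obeys

  ∂H/∂t + v ∂H/∂x = D ∂²H/∂x² + λ(x) g(x) − μH,

  with a binding rate λ(x) ramping linearly from λ/r on the GTP-cap
  (x = 0) to λ at the end of the mixed-nucleotide zone (x = l), a
  stationary RanGTP gradient g(x) = exp(−x/s), and partially adsorbing
  Robin boundaries γ₁, γ₂ at the kinetochore and the far end. Leading
  and trailing sides differ only by the advection direction and the
  presence of the cap/mixed zone. The solver is a method-of-lines
  discretisation advanced exactly in time by its matrix-exponential
  propagator (`simulate_hurp()`, `equilibrium_profile()`,
  `alternating_run()`, `measure_gap()`).
- **Bayesian inference** — random-walk Metropolis on log-transformed
  parameters with a pilot-tuned, burn-in-adapted proposal; Gaussian
  likelihood on the imaging grid (104 nm pixels, 4.1 s frames) with
  fixed measurement error (`run_mcmc()`, `summarize_posterior()`).
- **Synthetic data** — generators for noisy spatiotemporal profile
  datasets, 1-D Brownian particle traces and raw FRAP series
  (`generate_profile_dataset()`, `generate_particle_traces()`,
  `generate_frap_series()`).
- **Analyses** — HURP-gap sensitivity sweeps (`sensitivity_sweep()`),
  simulated FRAP (`simulate_frap()`), double normalisation and
  mono-exponential recovery fitting of raw FRAP series
  (`frap_double_normalise()`, `fit_monoexponential()`), and MSD
  diffusion estimation (`compute_msd()`, `estimate_diffusion()`).

See the vignette (`vignettes/hurp-kfibre-model.Rmd`) for the model's
assumptions, numerics and design choices.

## Worked example

Simulate a gap-forming regime, measure the gap, and check how it
scales with the cap/mixed-zone length:

```r
library(hurpdyn)

grid <- spatial_grid(L = 3, n_cells = 120)   # 3 um window, 25 nm cells
base <- gap_demo_parameters()                # gap-forming regime

eq <- equilibrium_profile(base, grid, side = "trailing")
measure_gap(eq, grid, frac = 0.5)
#> [1] 0.5918463

sensitivity_sweep(base, "l", c(0, 0.5, 1.0, 1.5, 2.0, 2.5), grid,
                  t_settle = 300)
#>   value    gap_um
#> 1   0.0 0.1491428
#> 2   0.5 0.3149521
#> 3   1.0 0.4709615
#> 4   1.5 0.5918463
#> 5   2.0 0.6704740
#> 6   2.5 0.6972756
```

The half-maximum gap on the trailing equilibrium is ~0.59 µm at the
default zone length l = 1.5 µm, shrinks to ~0.15 µm when the zone is
removed (l = 0; the residual gap comes from kinetochore-boundary
adsorption), and grows monotonically with l — the model's signature
that the gap tracks the mixed-nucleotide zone.

Fit the model to a synthetic dataset and summarise the posterior:

```r
grid40 <- spatial_grid(3, 40)
truth  <- model_parameters()
ds  <- generate_profile_dataset(truth, t_lead = 61.5, t_trail = 61.5,
                                seed = 101, grid = grid40)
fit <- run_mcmc(ds, config = mcmc_config(n_iter = 2000, n_chains = 4,
                                         pilot_iter = 500, seed = 1),
                grid = grid40)
subset(summarize_posterior(fit), parameter %in% c("l", "D", "mu"))
```

which prints, for each parameter, the posterior median, the central
95% credible interval, the acceptance rate and a split-chain Rhat —
with the intervals covering the generating values `l = 1.5`,
`D = 0.024`, `mu = 0.1` for this seed.

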