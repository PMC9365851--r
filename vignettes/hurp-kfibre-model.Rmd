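---
title: "A minimal spatiotemporal model of HURP on kinetochore-fibres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A minimal spatiotemporal model of HURP on kinetochore-fibres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hurpdyn)
```

## The model

HURP is a microtubule-associated protein that prefers the GDP-tubulin
lattice of kinetochore-fibres (K-fibres) and is excluded from a
kinetochore-proximal region — the HURP-gap — on the polymerising
(trailing) fibre. `hurpdyn` models the HURP intensity field $H(x,t)$
along one K-fibre, with $x$ the distance from the kinetochore toward
the pole, as a linear advection–diffusion–reaction equation

$$\frac{\partial H}{\partial t} + v\,\frac{\partial H}{\partial x}
  = D\,\frac{\partial^2 H}{\partial x^2} + \lambda(x)\,g(x) - \mu H,$$

where $D$ is the HURP diffusion coefficient, $\mu$ the unbinding rate,
$g(x) = e^{-x/s}$ a stationary chromosome-centred RanGTP activity
gradient with length scale $s$, and $\lambda(x)$ a binding rate that
ramps linearly from $\lambda/r$ at the kinetochore (the GTP-cap) to the
full lattice rate $\lambda$ at the end of the mixed-nucleotide zone of
length $l$:

$$\lambda(x) = \begin{cases}
  \dfrac{\lambda}{r} + \left(\lambda - \dfrac{\lambda}{r}\right)
  \dfrac{x}{l} & x \in (0, l) \\[4pt]
  \lambda & x \in (l, L).
\end{cases}$$

The advection speed $v$ is the rate of change of the distance between a
lattice site and the kinetochore. On the trailing side new lattice is
added at the kinetochore, so bound material recedes: $v = +\nu_+$. On
the leading (depolymerising) side material approaches the kinetochore:
$v = -\nu_-$. The cap/mixed zone exists only while the fibre
polymerises, so $l$ is treated as 0 on the leading side. Because $x$ is
kinetochore-anchored, poleward microtubule flux does not enter the
advection term.

Both ends carry partially adsorbing (Robin) boundaries with strengths
$\gamma_1$ (kinetochore) and $\gamma_2$ (far end), written in
outward-normal form:
$D\,\partial_x H(0,t) = \gamma_1 H(0,t)$ and
$D\,\partial_x H(L,t) = -\gamma_2 H(L,t)$. $\gamma_i = 0$ is a
reflecting (no-flux) boundary and $\gamma_i \to \infty$ an absorbing
one. Writing both conditions with the same literal sign would make the
far boundary an influx condition, contradicting the partial-adsorption
interpretation, so the outward-normal form is used.

### Parameters

| symbol | argument | meaning | unit | default |
|---|---|---|---|---|
| $l$ | `l` | GTP-cap + mixed-nucleotide zone length | µm | 1.5 |
| $D$ | `D` | HURP diffusion coefficient | µm²/s | 0.024 |
| $\lambda$ | `lam` | maximal binding rate | a.u./s | 1 |
| $\mu$ | `mu` | unbinding rate | 1/s | 0.1 |
| $\nu_+$ | `v_plus` | trailing advection speed | µm/s | 0.02 |
| $\nu_-$ | `v_minus` | leading advection speed | µm/s | 0.02 |
| $\gamma_1$ | `gamma1` | kinetochore boundary strength | µm/s | 0.01 |
| $\gamma_2$ | `gamma2` | far boundary strength | µm/s | 0.01 |
| $s$ | `s` | RanGTP gradient scale | µm | 3 |
| $r$ | `r` | lattice/cap binding ratio | — | 4 |
| $\sigma$ | `sigma` | observation noise (fixed) | a.u. | 0.5 |
| $L$ | `L` | modelled fibre length | µm | 3 |

The defaults are the package's synthetic-truth fixture: $D$ matches
single-particle tracking of HURP on the lattice (0.024 µm²/s), $l$ is a
micron-scale zone, $\mu$ gives the ~10 s turnover seen in FRAP, and $r$
reflects the roughly fourfold lower binding measured in vitro on
GTP-analogue lattices. $\lambda$ sets only the intensity scale
(equilibrium plateau $\lambda/\mu = 10$ a.u.); intensities are carried
through in arbitrary units. They are fixtures for testing, not fitted
values.

## Numerics

Space is discretised on a cell-centred grid (default 300 cells, i.e.
$\Delta x = L/300 = 10$ nm for the default window — much finer than the
104 nm observation pixels) with second-order central differences for
diffusion and first-order upwind differences for advection; the Robin
faces are eliminated through ghost values, and the advective flux at a
boundary face uses the Robin-implied face value. This yields a linear
system $\dot H = AH + b$ whose off-diagonals are non-negative, so the
exact solution operator $e^{A\Delta t}$ preserves non-negativity.

Because the model is linear, time integration uses the exact
matrix-exponential propagator (computed once per output step via the
augmented-matrix form, which also handles a singular $A$ in the
conservative special case). The scheme is therefore unconditionally
stable — there is no CFL restriction and no temporal truncation error;
accuracy is limited only by the spatial discretisation. An adaptive ODE
solver (`deSolve::lsoda`) serves as an independent cross-check in the
test suite, and analytic oracles (heat kernel, reaction fixed point,
mass conservation, advected pulse) bound the spatial error: pure
diffusion at default resolution is within 1% of the Gaussian kernel in
maximum norm.

Steady states solve $AH = -b$ directly (`method = "direct"`); the
time-marching alternative (`method = "evolve"`, relative change per
second below `tol`, horizon 2000 s) implements the
simulate-to-equilibrium description and is tested to agree. The direct
solve is exact and is the default because the steady state of the
discretised operator is unique whenever $\mu > 0$ or a boundary
adsorbs.

The leading/trailing alternation mirrors kinetochore directional
switches: the trailing equilibrium initialises a leading-side run,
whose final state initialises the trailing-side run. In the model the
near-kinetochore region is HURP-rich at the end of a leading episode
(full binding, no cap) and is then diluted by newly polymerised cap
lattice — the downward relaxation toward the trailing equilibrium is
exactly the gap forming.

## The gap estimator and the demonstration regime

`measure_gap()` reports the smallest distance at which a profile first
reaches a fraction (default one half) of its maximum, interpolating
linearly between cells. At the synthetic-truth fixture the trailing
equilibrium's minimum stays at 59% of its maximum — above the half-max
threshold — so the estimator reads 0 and a sensitivity sweep would be
degenerate. Gap-sensitivity analyses therefore use
`gap_demo_parameters()`: $s = 6$ µm (chromosome-centred RanGTP
gradients act over many microns, so over a 3 µm window the decay is
weak), $\gamma_1 = 0.1$ µm/s (active exclusion of HURP at the
kinetochore) and $\nu_+ = 0.04$ µm/s (a ~1.9 µm gap traversed over a
~45 s lifetime). In this regime the gap grows monotonically with the
cap/mixed-zone length and with the polymerisation speed, which is what
the sweep tests assert.

## Bayesian inference

The likelihood treats the two sides as conditionally independent
Gaussian observations of the model solution on the imaging grid (one
point per 104 nm pixel, one per 4.1 s frame), with known fixed noise
$\sigma$:
$\mathcal{L} = \prod_{k \in \{+,-\}} \prod_{i,j}
 N\!\left(y_k(x_i, t_j);\, H_k(x_i, t_j),\, \sigma\right)$.
The model is solved on a finer internal grid and interpolated linearly
in space onto the pixels, mirroring how line profiles are interpolated
between pixels. When $\sigma$ is unknown, `estimate_sigma()` uses the
standard deviation of first spatial differences divided by $\sqrt 2$.

Sampling is random-walk Metropolis with a log-space proposal
$\theta_i' = \operatorname{sign}(\theta_i)
 \exp(\log(\delta_i + |\theta_i|) + \xi_i)$, $\xi \sim N(0, \Sigma)$,
where the small tolerance $\delta$ (default $10^{-8}$) keeps the walk
alive near zero. For $\delta > 0$ the map is asymmetric, and the
back-transform carries a Jacobian, so the exact Metropolis–Hastings
correction is applied (a switch disables it for strict plain-Metropolis
replication; at the default $\delta$ the $\delta$-dependent part is
numerically negligible and only the standard log-scale Jacobian
remains).

Priors are independent log-normals with unit log-scale spread centred
on order-of-magnitude plausible values for all parameters except the
binding ratio $r$, which carries a tight prior centred at 4 (in vitro
knowledge of relative binding efficiencies). The support constraint
$l \le L$ truncates the prior of $l$ at the domain length. Chains are
initialised from prior draws.

The proposal covariance is tuned on a pilot run (default 1000
iterations; its second half is used, since the first half is still
descending from the prior draw), scaled by the optimal random-walk
factor $2.38^2/d$ and ridge-regularised so that no direction collapses.
During each chain's discarded burn-in (first half by default) the
kernel continues to adapt: an exponentially weighted running covariance
of the transformed draws plus Robbins–Monro tuning of a global scale
toward 23.4% acceptance. The kernel is frozen at the end of burn-in, so
all retained draws come from a fixed, valid Metropolis–Hastings kernel.
This burn-in adaptation matters on concentrated synthetic posteriors,
where a single pilot-tuned covariance leaves prior-initialised chains
stranded far from the posterior bulk. For the same reason each chain
starts from the highest-posterior of a pool of prior draws (default
25); `init_pool = 1` and `adapt_burnin = FALSE` reproduce the strict
pilot-then-fixed-kernel protocol. A forward-solver failure at a
proposed parameter vector counts as zero posterior density (the
proposal is rejected with a warning); the fit never aborts for that
reason.

Summaries report pooled post-burn-in medians, central 95% credible
intervals, acceptance rates and a split-chain $\hat R$ per parameter.
A caveat observed on the synthetic conditions (5% noise, two
16 × 29 profile matrices): the full 10-parameter posterior is located
accurately — medians and 95% intervals sit on the generating values —
but split-$\hat R$ can remain well above 1.1 even at 10,000 iterations,
because cross-chain mixing of a random walk in ten correlated
dimensions is slower than within-chain exploration. Reduced fits over
the identifiable subset (l, D, μ) reach $\hat R < 1.1$ comfortably;
for full-dimension fits the diagnostic should be read alongside the
interval behaviour rather than as a hard gate.

## Synthetic data

`generate_profile_dataset()` runs the alternation and samples it on the
imaging grid with i.i.d. Gaussian noise (default $\sigma$ = 5% of the
trailing-equilibrium maximum; undershoots below zero are kept, as
observation noise would produce). It emulates the observation grid,
the leading/trailing alternation around switches, and additive noise —
not photobleaching during acquisition, pixel point-spread, intensity
averaging across sister pairs, or tracking errors, so passing recovery
tests demonstrate the estimator's correctness on well-specified data,
not robustness to those real-data effects. One alternation cycle is
generated per dataset; averaging across replicates is left to the
caller. `generate_particle_traces()` produces 1-D Brownian paths
(increments $N(0, 2D\,\Delta t)$) and `generate_frap_series()` a raw
bleach/reference/background triplet with a mono-exponential recovery,
for exercising the measurement pipelines end to end.

## Downstream analyses

*Gap sensitivity*: each swept value runs the trailing side for a
settling time (default 300 s, long relative to the 1/μ = 10 s
relaxation) from the base equilibrium and measures the final gap.

*Simulated FRAP*: the trailing equilibrium is bleached beyond a cut
(default 1.5 µm from the kinetochore, region set to zero), the model
run forward, and the mean intensity in the bleached region — normalised
to its pre-bleach mean, the readout window being the whole bleached
region — is fitted with a mono-exponential to extract the recovery
timescale.

*FRAP measurement pipeline*: raw series are double-normalised,
$\mathrm{FRAP}(t) = \frac{\mathrm{Bleach}(t) - \mathrm{Back}(t)}
{\mathrm{Bleach}_{pre} - \mathrm{Back}_{pre}} \cdot
\frac{\mathrm{Ref}_{pre} - \mathrm{Back}_{pre}}
{\mathrm{Ref}(t) - \mathrm{Back}(t)}$,
which anchors pre-bleach frames at 1 and corrects acquisition
photobleaching through the whole-spindle reference. The recovery fit is
$f(t) = F_0 + A(1 - e^{-(t - t_{bleach})/\tau})$ on post-bleach points;
the mobile fraction is reported as the recovered fraction of the
bleached depth, $A / (1 - F_0)$ (the pre-bleach-normalised plateau is
also available from the fitted coefficients; small overshoots above 1
are tolerated to 1.05 and flagged).

*MSD*: time- and ensemble-averaged over overlapping windows;
$D$ = slope/2 of a free-intercept least-squares line through the first
five non-zero lags (the short-lag regime, before confinement or
localisation error would matter on real traces).

## Problem sizes

The test suite and the acceptance script run the solver at 40–300 cells
over 3–6 µm depending on the tolerance each check needs, and the
recovery study fits 4 chains × 2000 iterations (500-iteration pilot)
to datasets of two 16 × 29 profile matrices, generated and fitted on
the same 40-cell grid; the acceptance script runs one such fit at the
full protocol (4 × 10,000, 1000-iteration pilot). Generating and
fitting on the same
grid makes the recovery study a test of the inference machinery rather
than of grid-transfer bias, matching how synthetic validations are
normally constructed.

## Known limitations

The model is 1-D and deterministic: no spindle geometry, no
microtubule-level stochasticity, no poleward flux, one parameter set
per cell population. The binding ramp is linear by assumption; the
RanGTP gradient is stationary and exponential. The sampler is plain
random-walk Metropolis — adequate for this 10-parameter posterior but
slow compared to gradient-based methods, which are deliberately out of
scope. Intensities are in arbitrary units throughout, so only
quantities invariant to the intensity scale (lengths, rates, ratios)
are comparable across datasets.
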