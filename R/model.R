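#' RanGTP activity gradient
#'
#' The chromosome-centred RanGTP gradient is modelled as stationary and
#' exponentially decaying with distance from the kinetochore,
#' g(x) = exp(-x/s).
#'
#' @param x Position(s) along the K-fibre (um), >= 0.
#' @param s Gradient length scale (um), > 0.
#' @return Dimensionless factor(s) in (0, 1].
#' @examples
#' ran_gradient(c(0, 2, 4), s = 2)
#' @export
ran_gradient <- function(x, s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0) {
    stop("gradient scale 's' must be a single positive number",
         call. = FALSE)
  }
  if (any(x < 0)) stop("positions 'x' must be >= 0", call. = FALSE)
  exp(-x / s)
}

#' Spatial HURP binding-rate profile
#'
#' Binding ramps linearly from `lam / r` at the kinetochore (GTP-cap,
#' x = 0) to the full GDP-lattice rate `lam` at the end of the
#' mixed-nucleotide zone (x = l), and is constant `lam` beyond. With
#' l = 0 (leading side) the profile is the constant `lam`.
#'
#' @param x Position(s) along the K-fibre (um).
#' @param lam Maximal binding rate (intensity units / s), >= 0.
#' @param r Ratio of GDP-lattice to cap binding rates, > 0.
#' @param l Length of the GTP-cap + mixed-nucleotide zone (um), >= 0.
#' @return Binding rate(s) lambda(x).
#' @examples
#' binding_profile(c(0, 0.5, 1, 2), lam = 1, r = 4, l = 1)
#' @export
binding_profile <- function(x, lam, r, l) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("binding ratio 'r' must be a single positive number",
         call. = FALSE)
  }
  if (lam < 0) stop("'lam' must be >= 0", call. = FALSE)
  if (l < 0) stop("'l' must be >= 0", call. = FALSE)
  if (l == 0) return(rep(lam, length.out = length(x)))
  ifelse(x < l, lam / r + (lam - lam / r) * x / l, lam)
}

# Discretised spatial operator of the model on a cell-centred grid:
# dH/dt = A H + b, with second-order central diffusion, first-order upwind
# advection, partially adsorbing (Robin) boundary faces eliminated through
# ghost values, and the source b = lambda(x) g(x). A is Metzler
# (non-negative off-diagonals), so exp(At) preserves non-negativity.
build_operator <- function(params, grid, side = c("trailing", "leading"),
                           boundary = c("robin", "periodic")) {
  side <- match.arg(side)
  boundary <- match.arg(boundary)
  n <- grid$n_cells
  dx <- grid$dx
  D <- params$D
  mu <- params$mu
  # Side selects advection magnitude/direction and whether the excluded
  # zone applies: trailing flows away from the kinetochore (+x), leading
  # toward it (-x); the cap/mixed zone is effectively absent on the
  # leading side.
  if (side == "trailing") {
    v <- params$v_plus
    l_eff <- params$l
  } else {
    v <- -params$v_minus
    l_eff <- 0
  }

  A <- matrix(0, n, n)
  # interior faces k+1/2 for k = 1..n-1
  for (k in seq_len(n - 1L)) {
    # diffusion
    A[k, k] <- A[k, k] - D / dx^2
    A[k, k + 1L] <- A[k, k + 1L] + D / dx^2
    A[k + 1L, k] <- A[k + 1L, k] + D / dx^2
    A[k + 1L, k + 1L] <- A[k + 1L, k + 1L] - D / dx^2
    # upwind advection
    if (v >= 0) {
      A[k, k] <- A[k, k] - v / dx
      A[k + 1L, k] <- A[k + 1L, k] + v / dx
    } else {
      A[k, k + 1L] <- A[k, k + 1L] - v / dx
      A[k + 1L, k + 1L] <- A[k + 1L, k + 1L] + v / dx
    }
  }

  if (boundary == "periodic") {
    # wrap the face between cell n and cell 1 (test harness only)
    A[n, n] <- A[n, n] - D / dx^2
    A[n, 1L] <- A[n, 1L] + D / dx^2
    A[1L, n] <- A[1L, n] + D / dx^2
    A[1L, 1L] <- A[1L, 1L] - D / dx^2
    if (v >= 0) {
      A[n, n] <- A[n, n] - v / dx
      A[1L, n] <- A[1L, n] + v / dx
    } else {
      A[n, 1L] <- A[n, 1L] - v / dx
      A[1L, 1L] <- A[1L, 1L] + v / dx
    }
  } else {
    # Robin faces, outward-normal (partially adsorbing) form:
    #   x = 0:  D dH/dx = gamma1 H ;  x = L:  D dH/dx = -gamma2 H.
    # Ghost elimination with the first/last cell centre at dx/2 from the
    # face gives the face value H_face = alpha * H_cell with
    # alpha = (2D/dx) / (gamma + 2D/dx); the advective flux at a boundary
    # face uses this Robin-implied face value.
    g1 <- params$gamma1
    g2 <- params$gamma2
    if (D > 0) {
      a1 <- (2 * D / dx) / (g1 + 2 * D / dx)
      a2 <- (2 * D / dx) / (g2 + 2 * D / dx)
      # left face flux F0 = (v - gamma1) * a1 * H_1 (positive = toward +x)
      A[1L, 1L] <- A[1L, 1L] + (v - g1) * a1 / dx
      # right face flux Fn = (v + gamma2) * a2 * H_n
      A[n, n] <- A[n, n] - (v + g2) * a2 / dx
    } else {
      # pure advection: zero inflow, upwind outflow
      if (v < 0) A[1L, 1L] <- A[1L, 1L] + v / dx
      if (v > 0) A[n, n] <- A[n, n] - v / dx
    }
  }

  diag(A) <- diag(A) - mu
  b <- binding_profile(grid$x, params$lam, params$r, l_eff) *
    ran_gradient(grid$x, params$s)
  list(A = A, b = b, v = v, side = side)
}

# Exact one-step propagator of dH/dt = A H + b over step dt, computed with
# the augmented-matrix form so that a singular A (e.g. the conservative
# special case) needs no special handling:
#   expm([A b; 0 0] dt) = [E phi; 0 1],  H(t + dt) = E H(t) + phi.
step_propagator <- function(A, b, dt) {
  n <- nrow(A)
  M <- rbind(cbind(A, b), 0)
  EM <- as.matrix(Matrix::expm(Matrix::Matrix(M * dt)))
  list(E = EM[seq_len(n), seq_len(n), drop = FALSE],
       phi = EM[seq_len(n), n + 1L])
}

#' Simulate HURP dynamics on one side of a kinetochore
#'
#' Integrates dH/dt + v dH/dx = D d2H/dx2 + lambda(x) g(x) - mu H on a
#' cell-centred grid with partially adsorbing (Robin) boundaries. Space is
#' discretised by second-order central differences (diffusion) and
#' first-order upwind differences (advection); the resulting linear system
#' is advanced exactly in time through its matrix-exponential propagator,
#' so the scheme is unconditionally stable (no CFL restriction) and
#' preserves non-negativity.
#'
#' @param params A [model_parameters()] object.
#' @param grid A [spatial_grid()] object (the internal solver grid).
#' @param initial Initial intensity vector on `grid$x`, all >= 0.
#' @param duration Total simulated time (s), > 0.
#' @param dt_out Output sampling interval (s); samples are returned at
#'   t = 0, dt_out, 2 dt_out, ..., up to `duration`.
#' @param side `"trailing"` (polymerising, advection away from the
#'   kinetochore at `v_plus`, excluded zone of length `l`) or `"leading"`
#'   (depolymerising, advection toward the kinetochore at `v_minus`,
#'   no excluded zone).
#' @param boundary `"robin"` (default) or `"periodic"` (test harness).
#' @return A `hurp_profile`: list with `grid`, `times`, `H` (matrix, one
#'   row per time), and `side`.
#' @examples
#' g <- spatial_grid(3, 60)
#' p <- model_parameters()
#' out <- simulate_hurp(p, g, rep(0, g$n_cells), duration = 20, dt_out = 5)
#' dim(out$H)
#' @export
simulate_hurp <- function(params, grid, initial, duration, dt_out,
                          side = c("trailing", "leading"),
                          boundary = c("robin", "periodic")) {
  side <- match.arg(side)
  boundary <- match.arg(boundary)
  validate_model_parameters(params)
  if (length(initial) != grid$n_cells) {
    stop("'initial' must have one value per grid cell", call. = FALSE)
  }
  if (any(initial < 0)) stop("'initial' must be non-negative", call. = FALSE)
  if (duration <= 0) stop("'duration' must be > 0", call. = FALSE)
  if (dt_out <= 0 || dt_out > duration) {
    stop("'dt_out' must be in (0, duration]", call. = FALSE)
  }

  op <- build_operator(params, grid, side, boundary)
  times <- seq(0, duration, by = dt_out)
  prop <- step_propagator(op$A, op$b, dt_out)
  H <- matrix(NA_real_, length(times), grid$n_cells)
  H[1L, ] <- initial
  state <- as.numeric(initial)
  for (j in seq_along(times)[-1L]) {
    state <- as.numeric(prop$E %*% state) + prop$phi
    if (anyNA(state) || any(!is.finite(state))) {
      stop("solver divergence: non-finite state at t = ", times[j],
           call. = FALSE)
    }
    H[j, ] <- state
  }
  # the exact propagator is positivity-preserving; clip roundoff-level
  # undershoot only
  neg <- H < 0
  if (any(neg)) {
    if (min(H) < -1e-9) {
      stop("solver produced negative intensities beyond tolerance",
           call. = FALSE)
    }
    H[neg] <- 0
  }
  structure(list(grid = grid, times = times, H = H, side = side),
            class = "hurp_profile")
}

#' @export
print.hurp_profile <- function(x, ...) {
  cat(sprintf("HURP profile (%s side): %d times x %d cells, t in [%g, %g] s\n",
              x$side, length(x$times), x$grid$n_cells,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Steady-state HURP profile on one side
#'
#' The long-time profile of the model for fixed parameters. With
#' `method = "direct"` the steady linear system of the discretised model
#' is solved exactly; with `method = "evolve"` the system is marched from
#' a zero initial state until the maximum relative change per unit time
#' drops below `tol` (failing with a convergence error, carrying the last
#' residual, if `max_time` is exceeded). Both methods agree to solver
#' tolerance whenever the steady state is unique (mu > 0 or adsorbing
#' boundaries).
#'
#' @inheritParams simulate_hurp
#' @param tol Convergence tolerance: maximum relative change per second
#'   (`method = "evolve"`).
#' @param method `"direct"` (steady linear solve) or `"evolve"`
#'   (time-marching).
#' @param max_time Marching horizon (s) for `method = "evolve"`.
#' @return Intensity vector on `grid$x`.
#' @examples
#' g <- spatial_grid(3, 60)
#' eq <- equilibrium_profile(model_parameters(), g, side = "trailing")
#' @export
equilibrium_profile <- function(params, grid,
                                side = c("trailing", "leading"),
                                tol = 1e-6,
                                method = c("direct", "evolve"),
                                max_time = 2000) {
  side <- match.arg(side)
  method <- match.arg(method)
  validate_model_parameters(params)
  if (tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  op <- build_operator(params, grid, side)

  if (method == "direct") {
    eq <- tryCatch(solve(op$A, -op$b),
                   error = function(e) {
                     stop("steady-state system is singular; use method = ",
                          "\"evolve\" (", conditionMessage(e), ")",
                          call. = FALSE)
                   })
    eq[eq < 0 & eq > -1e-9] <- 0
    if (any(eq < 0)) {
      stop("steady-state solve produced negative intensities", call. = FALSE)
    }
    return(as.numeric(eq))
  }

  dt <- 10
  prop <- step_propagator(op$A, op$b, dt)
  state <- rep(0, grid$n_cells)
  t <- 0
  resid <- Inf
  while (t < max_time) {
    new <- as.numeric(prop$E %*% state) + prop$phi
    t <- t + dt
    scale <- max(abs(new), 1e-12)
    resid <- max(abs(new - state)) / scale / dt
    state <- new
    if (resid < tol) {
      state[state < 0 & state > -1e-9] <- 0
      return(state)
    }
  }
  cond <- simpleError(sprintf(
    "equilibrium not reached within %g s (last relative residual %.3g /s)",
    max_time, resid))
  class(cond) <- c("hurpdyn_convergence_error", class(cond))
  stop(cond)
}

#' Leading/trailing alternation around a directional switch
#'
#' Reproduces the model's initial-condition chain: the trailing side is
#' first brought to equilibrium; that profile initialises a leading-side
#' run of length `t_lead` (the kinetochore switching to depolymerisation);
#' the leading run's final state then initialises a trailing-side run of
#' length `t_trail` (switch back to polymerisation). Both runs are
#' returned.
#'
#' @inheritParams simulate_hurp
#' @param t_lead,t_trail Durations (s) of the leading and trailing runs.
#' @param equilibrium_method Passed to [equilibrium_profile()].
#' @return List with elements `leading` and `trailing`, both
#'   `hurp_profile` objects, plus `equilibrium` (the initial trailing
#'   steady state).
#' @examples
#' g <- spatial_grid(3, 60)
#' runs <- alternating_run(model_parameters(), g, 20, 20, dt_out = 4.1)
#' @export
alternating_run <- function(params, grid, t_lead, t_trail, dt_out,
                            equilibrium_method = "direct") {
  if (t_lead <= 0 || t_trail <= 0) {
    stop("'t_lead' and 't_trail' must be > 0", call. = FALSE)
  }
  eq <- equilibrium_profile(params, grid, side = "trailing",
                            method = equilibrium_method)
  lead <- simulate_hurp(params, grid, initial = eq, duration = t_lead,
                        dt_out = dt_out, side = "leading")
  trail <- simulate_hurp(params, grid,
                         initial = lead$H[nrow(lead$H), ],
                         duration = t_trail, dt_out = dt_out,
                         side = "trailing")
  list(leading = lead, trailing = trail, equilibrium = eq)
}

#' Measure the HURP-gap length of a profile
#'
#' The gap is the kinetochore-proximal region lacking HURP signal: the
#' smallest distance at which the profile first reaches `frac` times its
#' maximum, with linear interpolation between cell centres. A profile
#' already above threshold at the first cell has gap 0.
#'
#' @param intensity Intensity vector (one spatial profile), not all zero.
#' @param x Cell-centre positions (um), same length; alternatively pass a
#'   `spatial_grid` object.
#' @param frac Threshold fraction of the maximum, in (0, 1).
#' @return Gap length (um).
#' @examples
#' x <- seq(0.05, 3, by = 0.1)
#' measure_gap(pmin(x, 1.5), x)   # ramp reaching max 1.5 at x = 1.5
#' @export
measure_gap <- function(intensity, x, frac = 0.5) {
  if (inherits(x, "spatial_grid")) x <- x$x
  if (length(intensity) != length(x)) {
    stop("'intensity' and 'x' must have equal length", call. = FALSE)
  }
  if (frac <= 0 || frac >= 1) stop("'frac' must be in (0, 1)", call. = FALSE)
  if (all(intensity == 0)) {
    stop("gap is undefined for an all-zero profile", call. = FALSE)
  }
  thr <- frac * max(intensity)
  if (intensity[1L] >= thr) return(0)
  k <- which(intensity >= thr)[1L]
  # linear interpolation between cell centres k-1 and k
  x0 <- x[k - 1L]; y0 <- intensity[k - 1L]
  x1 <- x[k]; y1 <- intensity[k]
  x0 + (thr - y0) / (y1 - y0) * (x1 - x0)
}

#' Evaluate a simulated profile on an observation grid
#'
#' Linear interpolation in space onto `x_obs` (constant extrapolation at
#' the edges, mirroring pixel-centre sampling); times must match solver
#' output times exactly (the solver grid is at least as fine as the
#' observation grid in time).
#'
#' @param profile A `hurp_profile`.
#' @param x_obs Observation positions (um).
#' @param t_obs Observation times (s); must each match a solver output
#'   time to within 1e-6 s.
#' @return Matrix with `length(t_obs)` rows and `length(x_obs)` columns.
#' @export
evaluate_profile <- function(profile, x_obs, t_obs) {
  idx <- vapply(t_obs, function(t) {
    j <- which.min(abs(profile$times - t))
    if (abs(profile$times[j] - t) > 1e-6) {
      stop("observation time ", t, " s not among solver output times",
           call. = FALSE)
    }
    j
  }, integer(1))
  out <- matrix(NA_real_, length(t_obs), length(x_obs))
  for (i in seq_along(idx)) {
    out[i, ] <- stats::approx(profile$grid$x, profile$H[idx[i], ],
                              xout = x_obs, rule = 2)$y
  }
  out
}
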