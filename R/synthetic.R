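# All generators are pure functions of (arguments, seed): they seed the
# session RNG locally and restore the previous state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a synthetic spatiotemporal profile dataset
#'
#' Runs the forward model through its leading/trailing alternation
#' ([alternating_run()]), samples the solution on the lattice
#' light-sheet-like observation grid (one point every `dx_obs` in space
#' over `[0, x_max]`, pixel centres, and every `dt_obs` in time), and
#' adds i.i.d. Gaussian noise of standard deviation `sigma`. Negative
#' noisy values are kept: observation noise can undershoot zero.
#'
#' @param true_params Generating [model_parameters()].
#' @param t_lead,t_trail Durations (s) of the leading and trailing
#'   windows; the shared observation time grid requires
#'   `t_lead == t_trail`.
#' @param sigma Observation noise sd; default 5% of the trailing
#'   equilibrium maximum.
#' @param seed RNG seed (the dataset is a pure function of arguments and
#'   seed).
#' @param grid Internal solver grid; defaults to 300 cells over the
#'   modelled length `true_params$L`.
#' @param dx_obs,dt_obs Observation spacings (0.104 um pixels, 4.1 s
#'   frames by default).
#' @param x_max Extent of the observed line profile (um).
#' @return An [observed_profiles()] dataset; the generating parameters
#'   and noiseless fields are attached as attributes `true_params`,
#'   `H_plus` and `H_minus`.
#' @examples
#' g <- spatial_grid(3, 60)
#' ds <- generate_profile_dataset(model_parameters(), t_lead = 20,
#'                                t_trail = 20, seed = 1, grid = g)
#' @export
generate_profile_dataset <- function(true_params, t_lead = 60,
                                     t_trail = 60, sigma = NULL,
                                     seed = NULL, grid = NULL,
                                     dx_obs = 0.104, dt_obs = 4.1,
                                     x_max = 3) {
  if (abs(t_lead - t_trail) > 1e-9) {
    stop("the shared observation time grid requires t_lead == t_trail",
         call. = FALSE)
  }
  if (is.null(grid)) grid <- spatial_grid(true_params$L, 300)
  runs <- alternating_run(true_params, grid, t_lead, t_trail,
                          dt_out = dt_obs)
  x_obs <- seq(dx_obs / 2, x_max, by = dx_obs)
  t_obs <- runs$trailing$times
  H_plus <- evaluate_profile(runs$trailing, x_obs, t_obs)
  H_minus <- evaluate_profile(runs$leading, x_obs, t_obs)
  if (is.null(sigma)) sigma <- 0.05 * max(runs$equilibrium)
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)

  noisy <- with_seed(seed, {
    list(y_plus = H_plus + stats::rnorm(length(H_plus), 0, sigma),
         y_minus = H_minus + stats::rnorm(length(H_minus), 0, sigma))
  })
  ds <- observed_profiles(x_obs, t_obs,
                          matrix(noisy$y_plus, nrow(H_plus)),
                          matrix(noisy$y_minus, nrow(H_minus)),
                          sigma = max(sigma, .Machine$double.eps))
  attr(ds, "true_params") <- true_params
  attr(ds, "H_plus") <- H_plus
  attr(ds, "H_minus") <- H_minus
  ds
}

#' Generate 1-D Brownian particle traces
#'
#' Stand-in for single-particle tracking of lattice-bound HURP: each
#' trace takes independent Gaussian increments of variance 2 D dt per
#' step (1-D free diffusion).
#'
#' @param D Diffusion coefficient (um^2/s), >= 0.
#' @param n_traces Number of traces, >= 1.
#' @param dt Sampling interval (s), > 0.
#' @param n_steps Steps per trace (each trace has `n_steps + 1`
#'   positions).
#' @param seed RNG seed.
#' @param x0 Common starting position (um).
#' @return An object of class `particle_traces`: list of position
#'   vectors plus the sampling interval `dt`.
#' @examples
#' tr <- generate_particle_traces(0.024, n_traces = 5, dt = 0.1,
#'                                n_steps = 50, seed = 1)
#' @export
generate_particle_traces <- function(D, n_traces = 129, dt = 0.1,
                                     n_steps = 100, seed = NULL, x0 = 0) {
  if (D < 0) stop("'D' must be >= 0", call. = FALSE)
  if (n_traces < 1) stop("'n_traces' must be >= 1", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  if (n_steps < 1) stop("'n_steps' must be >= 1", call. = FALSE)
  traces <- with_seed(seed, {
    lapply(seq_len(n_traces), function(i) {
      x0 + c(0, cumsum(stats::rnorm(n_steps, 0, sqrt(2 * D * dt))))
    })
  })
  structure(list(traces = traces, dt = dt), class = "particle_traces")
}

#' Generate a raw FRAP intensity series
#'
#' Synthetic fixture for the double-normalisation and recovery-fit
#' pipeline: the bleach-ROI signal sits at a pre-bleach plateau for
#' `pre_frames` frames, drops to a floor at the bleach, and recovers
#' mono-exponentially to `mobile_fraction` of the bleached depth with
#' timescale `tau`; the whole-spindle reference and background channels
#' are constant. Optional Gaussian noise is added to all three channels.
#'
#' @param tau Recovery timescale (s), > 0.
#' @param mobile_fraction Fraction of the bleached depth that recovers,
#'   in `[0, 1]`.
#' @param pre_frames Number of pre-bleach frames, >= 1.
#' @param n_frames Total frames (pre + post).
#' @param dt Frame interval (s).
#' @param noise Gaussian noise sd added to each channel.
#' @param seed RNG seed.
#' @param levels Named list of channel levels: `bleach_pre`, `floor`
#'   (post-bleach bleach-ROI floor), `reference`, `background`.
#' @return An object of class `frap_raw`: `times`, `bleach`,
#'   `reference`, `background`, `pre_bleach_count`.
#' @examples
#' raw <- generate_frap_series(tau = 10, mobile_fraction = 0.917)
#' @export
generate_frap_series <- function(tau = 10, mobile_fraction = 0.917,
                                 pre_frames = 5, n_frames = 65, dt = 2,
                                 noise = 0, seed = NULL,
                                 levels = list(bleach_pre = 100,
                                               floor = 30,
                                               reference = 200,
                                               background = 10)) {
  if (tau <= 0) stop("'tau' must be > 0", call. = FALSE)
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    stop("'mobile_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (pre_frames < 1) stop("'pre_frames' must be >= 1", call. = FALSE)
  if (n_frames <= pre_frames + 3) {
    stop("'n_frames' must leave at least 4 post-bleach frames",
         call. = FALSE)
  }
  times <- seq(0, by = dt, length.out = n_frames)
  t_bleach <- times[pre_frames + 1L]
  depth <- levels$bleach_pre - levels$floor
  bleach <- ifelse(times < t_bleach, levels$bleach_pre,
                   levels$floor + mobile_fraction * depth *
                     (1 - exp(-(times - t_bleach) / tau)))
  reference <- rep(levels$reference, n_frames)
  background <- rep(levels$background, n_frames)
  if (noise > 0) {
    ch <- with_seed(seed, {
      list(b = stats::rnorm(n_frames, 0, noise),
           r = stats::rnorm(n_frames, 0, noise),
           k = stats::rnorm(n_frames, 0, noise))
    })
    bleach <- bleach + ch$b
    reference <- reference + ch$r
    background <- background + ch$k
  }
  structure(list(times = times, bleach = bleach, reference = reference,
                 background = background, pre_bleach_count = pre_frames),
            class = "frap_raw")
}
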