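#' Time- and ensemble-averaged mean squared displacement
#'
#' For each lag k dt up to `max_lag`, averages (x(t + lag) - x(t))^2 over
#' all traces and all valid (overlapping) start points.
#'
#' @param traces A `particle_traces` object
#'   (see [generate_particle_traces()]).
#' @param max_lag Largest lag (s); must not exceed the span of the
#'   shortest trace.
#' @return An object of class `msd_curve`: `lags` (s, starting at 0),
#'   `msd` (um^2), `n_pairs` per lag, and `D` (`NA` until
#'   [estimate_diffusion()]).
#' @examples
#' tr <- generate_particle_traces(0.024, 10, dt = 0.1, n_steps = 50,
#'                                seed = 1)
#' msd <- compute_msd(tr, max_lag = 1)
#' @export
compute_msd <- function(traces, max_lag) {
  if (!length(traces$traces)) stop("empty trace set", call. = FALSE)
  dt <- traces$dt
  min_span <- (min(lengths(traces$traces)) - 1L) * dt
  if (max_lag > min_span + 1e-9) {
    stop("'max_lag' exceeds the span of the shortest trace",
         call. = FALSE)
  }
  k_max <- floor(max_lag / dt + 1e-9)
  lags <- (0:k_max) * dt
  msd <- numeric(k_max + 1L)
  n_pairs <- integer(k_max + 1L)
  n_pairs[1L] <- sum(lengths(traces$traces))
  for (k in seq_len(k_max)) {
    sq <- unlist(lapply(traces$traces, function(x) {
      n <- length(x)
      (x[seq.int(k + 1L, n)] - x[seq_len(n - k)])^2
    }))
    msd[k + 1L] <- mean(sq)
    n_pairs[k + 1L] <- length(sq)
  }
  structure(list(lags = lags, msd = msd, n_pairs = n_pairs, D = NA_real_),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("MSD curve: %d lags up to %g s", length(x$lags),
              max(x$lags)))
  if (!is.na(x$D)) cat(sprintf("; fitted D = %.4g um^2/s", x$D))
  cat("\n")
  invisible(x)
}

#' Estimate a diffusion coefficient from an MSD curve
#'
#' Ordinary least squares line (free intercept) through the first
#' `fit_lags` non-zero lags of the MSD; for 1-D diffusion along the
#' lattice MSD = 2 D lag, so D = slope / 2. A degenerate (constant) MSD
#' returns 0 with a warning.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param fit_lags Number of short lags used in the fit, >= 2.
#' @return The `msd_curve` with `D` (um^2/s) filled in; the estimate is
#'   also attached as attribute `fit` (intercept, slope).
#' @examples
#' curve <- list(lags = 0:5, msd = 0.048 * (0:5), n_pairs = rep(10, 6))
#' class(curve) <- "msd_curve"
#' estimate_diffusion(curve)$D
#' @export
estimate_diffusion <- function(msd, fit_lags = 5) {
  if (fit_lags < 2) stop("'fit_lags' must be >= 2", call. = FALSE)
  nz <- which(msd$lags > 0)
  if (length(nz) < fit_lags) {
    stop("MSD curve has fewer than 'fit_lags' non-zero lags",
         call. = FALSE)
  }
  idx <- nz[seq_len(fit_lags)]
  x <- msd$lags[idx]
  y <- msd$msd[idx]
  if (diff(range(y)) < .Machine$double.eps) {
    warning("degenerate (constant) MSD; returning D = 0", call. = FALSE)
    msd$D <- 0
    return(msd)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  msd$D <- unname(fit$coefficients[2]) / 2
  attr(msd, "fit") <- c(intercept = unname(fit$coefficients[1]),
                        slope = unname(fit$coefficients[2]))
  msd
}
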