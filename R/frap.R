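#' Double-normalise a raw FRAP series
#'
#' FRAP(t) = [(Bleach(t) - Back(t)) / (Bleach_pre - Back_pre)] *
#' [(Ref_pre - Back_pre) / (Ref(t) - Back(t))], with pre-bleach means
#' taken over the pre-bleach frames. The reference (whole-spindle) factor
#' corrects for photobleaching induced by the imaging laser itself, so
#' pre-bleach values normalise to 1 exactly.
#'
#' @param raw A `frap_raw` series (see [generate_frap_series()] for the
#'   fields).
#' @return An (unfitted) `frap_curve`: `times`, `signal`,
#'   `pre_bleach_count`, with `tau`/`mobile_fraction` set to `NA` until
#'   [fit_monoexponential()] is applied.
#' @examples
#' curve <- frap_double_normalise(generate_frap_series())
#' @export
frap_double_normalise <- function(raw) {
  if (raw$pre_bleach_count < 1) {
    stop("at least one pre-bleach frame is required", call. = FALSE)
  }
  pre <- seq_len(raw$pre_bleach_count)
  bleach_pre <- mean(raw$bleach[pre])
  ref_pre <- mean(raw$reference[pre])
  back_pre <- mean(raw$background[pre])
  if (abs(bleach_pre - back_pre) < .Machine$double.eps) {
    stop("pre-bleach bleach-ROI mean equals background mean; ",
         "normalisation undefined", call. = FALSE)
  }
  denom <- raw$reference - raw$background
  bad <- which(abs(denom) < .Machine$double.eps)
  if (length(bad)) {
    stop("reference equals background at frame ", bad[1],
         "; normalisation undefined", call. = FALSE)
  }
  signal <- (raw$bleach - raw$background) / (bleach_pre - back_pre) *
    (ref_pre - back_pre) / denom
  structure(list(times = raw$times, signal = signal,
                 pre_bleach_count = raw$pre_bleach_count,
                 tau = NA_real_, mobile_fraction = NA_real_,
                 residual_norm = NA_real_),
            class = "frap_curve")
}

#' Fit a mono-exponential recovery to a normalised FRAP curve
#'
#' Least-squares fit of f(t) = F0 + A (1 - exp(-(t - t_bleach) / tau))
#' to the post-bleach points (t >= t_bleach). The mobile fraction is the
#' recovered fraction of the bleached depth relative to the pre-bleach
#' level: A / (1 - F0), where F0 is the fitted post-bleach floor. Values
#' slightly above 1 (fit overshoot) are tolerated up to 1.05 and flagged
#' with a warning above 1.
#'
#' @param curve A `frap_curve` (from [frap_double_normalise()] or
#'   [simulate_frap()]), or a list with `times` and `signal`.
#' @param t_bleach Bleach time (s); points at `t >= t_bleach` are fitted.
#'   Defaults to the first post-bleach frame time when `curve` carries
#'   `pre_bleach_count`.
#' @return The curve with `tau`, `mobile_fraction`, `F0`, `A` and
#'   `residual_norm` filled in.
#' @examples
#' curve <- frap_double_normalise(generate_frap_series(tau = 8))
#' fit <- fit_monoexponential(curve)
#' fit$tau
#' @export
fit_monoexponential <- function(curve, t_bleach = NULL) {
  if (is.null(t_bleach)) {
    if (is.null(curve$pre_bleach_count)) {
      stop("'t_bleach' is required when the curve has no pre-bleach ",
           "bookkeeping", call. = FALSE)
    }
    t_bleach <- curve$times[curve$pre_bleach_count + 1L]
  }
  post <- curve$times >= t_bleach - 1e-9
  tt <- curve$times[post] - t_bleach
  yy <- curve$signal[post]
  if (length(yy) < 4L) {
    stop("at least 4 post-bleach points are required", call. = FALSE)
  }

  out <- curve
  if (diff(range(yy)) < 1e-10) {
    # flat post-bleach signal: no recovery
    out$F0 <- mean(yy)
    out$A <- 0
    out$tau <- NA_real_
    out$mobile_fraction <- 0
    out$residual_norm <- sqrt(sum((yy - mean(yy))^2))
    return(out)
  }

  F0_start <- yy[1]
  plateau <- mean(utils::tail(yy, max(3L, length(yy) %/% 5L)))
  A_start <- max(plateau - F0_start, 1e-6)
  half <- F0_start + A_start / 2
  i_half <- which(yy >= half)[1]
  tau_start <- if (!is.na(i_half) && tt[i_half] > 0)
    tt[i_half] / log(2) else max(tt) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ F0 + A * (1 - exp(-tt / tau)),
                      start = list(F0 = F0_start, A = A_start,
                                   tau = tau_start),
                      lower = c(-Inf, 0, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("mono-exponential fit failed to converge: ",
           conditionMessage(e), call. = FALSE)
    })
  cf <- stats::coef(fit)
  out$F0 <- unname(cf["F0"])
  out$A <- unname(cf["A"])
  out$tau <- unname(cf["tau"])
  out$mobile_fraction <- out$A / (1 - out$F0)
  out$residual_norm <- sqrt(sum(stats::residuals(fit)^2))
  if (is.finite(out$mobile_fraction) && out$mobile_fraction > 1) {
    warning(sprintf("fitted mobile fraction %.3f exceeds 1%s",
                    out$mobile_fraction,
                    if (out$mobile_fraction > 1.05)
                      " (beyond overshoot tolerance)" else ""),
            call. = FALSE)
  }
  out
}

#' @export
print.frap_curve <- function(x, ...) {
  cat(sprintf("FRAP curve: %d frames", length(x$times)))
  if (!is.na(x$tau)) {
    cat(sprintf("; fit: tau = %.3g s, mobile fraction = %.3f",
                x$tau, x$mobile_fraction))
  }
  cat("\n")
  invisible(x)
}

#' Simulate a FRAP experiment on the model
#'
#' Takes the trailing-side equilibrium, sets the HURP field to zero
#' beyond `bleach_from` (the bleached region), simulates forward, and
#' reports the mean intensity in the bleached region normalised to its
#' pre-bleach equilibrium mean. A mono-exponential recovery is fitted to
#' extract the timescale; the half-time `tau * log(2)` is also reported.
#'
#' @inheritParams simulate_hurp
#' @param bleach_from Inner edge of the bleached region (um); the region
#'   `x > bleach_from` starts at zero intensity.
#' @param duration,dt_out Simulated time window and output step (s).
#' @return A fitted `frap_curve` with extra fields `halftime` and
#'   `bleach_from`.
#' @examples
#' g <- spatial_grid(3, 60)
#' fr <- simulate_frap(model_parameters(), g, duration = 40, dt_out = 1)
#' @export
simulate_frap <- function(params, grid, bleach_from = 1.5,
                          duration = 60, dt_out = 0.5) {
  if (bleach_from <= 0 || bleach_from >= grid$L) {
    stop("'bleach_from' must lie inside (0, L)", call. = FALSE)
  }
  eq <- equilibrium_profile(params, grid, side = "trailing")
  region <- grid$x > bleach_from
  if (!any(region)) stop("bleached region contains no grid cells",
                         call. = FALSE)
  pre <- mean(eq[region])
  if (pre <= 0) stop("equilibrium intensity vanishes in the bleached ",
                     "region", call. = FALSE)
  initial <- eq
  initial[region] <- 0
  run <- simulate_hurp(params, grid, initial, duration, dt_out,
                       side = "trailing")
  signal <- rowMeans(run$H[, region, drop = FALSE]) / pre
  curve <- structure(list(times = run$times, signal = signal,
                          pre_bleach_count = NULL,
                          tau = NA_real_, mobile_fraction = NA_real_,
                          residual_norm = NA_real_,
                          bleach_from = bleach_from),
                     class = "frap_curve")
  curve <- fit_monoexponential(curve, t_bleach = 0)
  curve$halftime <- curve$tau * log(2)
  curve
}
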