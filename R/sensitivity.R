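#' Gap-forming demonstration parameter set
#'
#' A parameter regime in which the trailing equilibrium carries a clear
#' half-maximum HURP-gap, suitable as the base of gap-sensitivity sweeps.
#' Relative to [model_parameters()] defaults it uses a weaker RanGTP
#' decay over the observed window (`s` = 6 um; chromosome-centred
#' gradients act over many microns), stronger kinetochore-boundary
#' adsorption (`gamma1` = 0.1 um/s, active HURP exclusion at the
#' kinetochore) and a polymerisation speed of 0.04 um/s (a micron-scale
#' gap traversed over a ~45 s lifetime). In the default fixture regime
#' the equilibrium dip stays above half-maximum and the gap estimator
#' reads 0 everywhere, which makes sweeps degenerate.
#'
#' @param ... Overrides passed to [model_parameters()].
#' @return A [model_parameters()] object.
#' @examples
#' gap_demo_parameters()$s
#' @export
gap_demo_parameters <- function(...) {
  args <- utils::modifyList(list(v_plus = 0.04, gamma1 = 0.1,
                                 gamma2 = 0.01, s = 6), list(...))
  do.call(model_parameters, args)
}

#' Sensitivity of the HURP-gap to a model parameter
#'
#' For each value of the swept parameter (`l`, the GTP-cap plus
#' mixed-nucleotide zone length, or `v_plus`, the trailing-side
#' polymerisation/advection speed), the trailing side is run to its
#' long-time state and the gap is measured on the final profile with
#' [measure_gap()]. All other parameters stay fixed at their values in
#' `base` (e.g. posterior medians). Each run starts from the trailing
#' equilibrium of the *base* parameter set and settles for `t_settle`
#' seconds under the modified parameters.
#'
#' @param base Baseline [model_parameters()].
#' @param param `"l"` or `"v_plus"`.
#' @param values Numeric vector of parameter values to sweep.
#' @param grid A [spatial_grid()].
#' @param t_settle Settling time (s) under each modified parameter set.
#' @param frac Gap threshold fraction, see [measure_gap()].
#' @return A data.frame with columns `value` and `gap_um`.
#' @examples
#' g <- spatial_grid(3, 60)
#' sensitivity_sweep(model_parameters(), "l", c(0, 1, 2), g,
#'                   t_settle = 100)
#' @export
sensitivity_sweep <- function(base, param = c("l", "v_plus"), values,
                              grid, t_settle = 300, frac = 0.5) {
  param <- match.arg(param)
  if (!length(values)) stop("'values' must be non-empty", call. = FALSE)
  if (t_settle <= 0) stop("'t_settle' must be > 0", call. = FALSE)
  base_eq <- equilibrium_profile(base, grid, side = "trailing")
  gaps <- vapply(values, function(v) {
    p <- unclass(base)
    p[[param]] <- v
    p <- do.call(model_parameters, p)
    run <- simulate_hurp(p, grid, initial = base_eq,
                         duration = t_settle, dt_out = t_settle,
                         side = "trailing")
    measure_gap(run$H[nrow(run$H), ], grid, frac = frac)
  }, numeric(1))
  data.frame(value = values, gap_um = gaps)
}
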