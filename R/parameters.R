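#' Model parameters for HURP dynamics on a kinetochore-fibre
#'
#' Bundles the parameter vector of the minimal advection-diffusion-reaction
#' model, theta = (l, D, lambda, mu, v_plus, v_minus, gamma1, gamma2, s, r),
#' together with the fixed observation noise `sigma` and the modelled
#' K-fibre length `L`.
#'
#' The defaults are the package's synthetic-truth fixture: orders of
#' magnitude anchored to published observations of HURP behaviour
#' (diffusion on the lattice near 0.024 um^2/s, a micron-scale excluded
#' zone, turnover on a ~10 s timescale, ~4-fold lower binding on the
#' GTP-cap than the GDP lattice). They are test fixtures, not fitted
#' values.
#'
#' @param l Length of the GTP-cap plus mixed-nucleotide zone (um). Binding
#'   ramps linearly from `lam/r` at the kinetochore (x = 0) to `lam` at
#'   x = l. On the leading (depolymerising) side l is treated as 0.
#' @param D HURP diffusion coefficient (um^2/s).
#' @param lam Maximal binding rate lambda on the GDP lattice
#'   (intensity units / s).
#' @param mu Unbinding rate (1/s).
#' @param v_plus Advection speed magnitude on the trailing (polymerising)
#'   K-fibre (um/s); applied as flow away from the kinetochore.
#' @param v_minus Advection speed magnitude on the leading (depolymerising)
#'   K-fibre (um/s); applied as flow toward the kinetochore.
#' @param gamma1 Kinetochore-boundary (x = 0) interaction strength (um/s);
#'   0 gives a reflecting (no-flux) boundary, large values an absorbing one.
#' @param gamma2 Far-boundary (x = L) interaction strength (um/s).
#' @param s RanGTP gradient length scale (um); the gradient is
#'   g(x) = exp(-x/s).
#' @param r Ratio of GDP-lattice to GTP-cap binding rates (dimensionless,
#'   > 0).
#' @param sigma Fixed Gaussian observation noise (intensity units).
#' @param L Modelled K-fibre length (um).
#'
#' @return An object of class `model_parameters` (a named list).
#' @examples
#' p <- model_parameters()
#' p$D
#' @export
model_parameters <- function(l = 1.5, D = 0.024, lam = 1, mu = 0.1,
                             v_plus = 0.02, v_minus = 0.02,
                             gamma1 = 0.01, gamma2 = 0.01,
                             s = 3, r = 4, sigma = 0.5, L = 3) {
  p <- list(l = l, D = D, lam = lam, mu = mu, v_plus = v_plus,
            v_minus = v_minus, gamma1 = gamma1, gamma2 = gamma2,
            s = s, r = r, sigma = sigma, L = L)
  validate_model_parameters(p)
  structure(p, class = "model_parameters")
}

#' @rdname model_parameters
#' @param p A list with the fields of `model_parameters`.
#' @export
validate_model_parameters <- function(p) {
  num1 <- function(z) is.numeric(z) && length(z) == 1L && is.finite(z)
  for (nm in c("l", "D", "lam", "mu", "v_plus", "v_minus",
               "gamma1", "gamma2", "s", "r", "sigma", "L")) {
    if (!num1(p[[nm]])) {
      stop("parameter '", nm, "' must be a single finite numeric value",
           call. = FALSE)
    }
  }
  nonneg <- c("l", "D", "lam", "mu", "v_plus", "v_minus",
              "gamma1", "gamma2", "s", "sigma", "L")
  bad <- nonneg[vapply(nonneg, function(nm) p[[nm]] < 0, logical(1))]
  if (length(bad)) {
    stop("parameters must be non-negative: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (p$r <= 0) stop("binding ratio 'r' must be > 0", call. = FALSE)
  if (p$l > p$L) stop("cap/mixed-zone length 'l' cannot exceed domain 'L'",
                      call. = FALSE)
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("HURP model parameters\n")
  cat(sprintf("  l = %g um, D = %g um^2/s, lambda = %g /s, mu = %g /s\n",
              x$l, x$D, x$lam, x$mu))
  cat(sprintf("  v+ = %g um/s (trailing), v- = %g um/s (leading)\n",
              x$v_plus, x$v_minus))
  cat(sprintf("  gamma1 = %g, gamma2 = %g um/s; s = %g um; r = %g\n",
              x$gamma1, x$gamma2, x$s, x$r))
  cat(sprintf("  sigma = %g (fixed), L = %g um\n", x$sigma, x$L))
  invisible(x)
}

# Names of the dynamic parameters theta, in canonical order.
theta_names <- function() {
  c("l", "D", "lam", "mu", "v_plus", "v_minus", "gamma1", "gamma2", "s", "r")
}

#' Cell-centred spatial grid along a K-fibre
#'
#' Positions are distances from the kinetochore (x = 0) toward the pole;
#' cell centres sit at dx/2, 3 dx/2, ..., L - dx/2.
#'
#' @param L Domain length (um).
#' @param n_cells Number of grid cells.
#' @return An object of class `spatial_grid` with fields `L`, `n_cells`,
#'   `dx` and `x` (cell-centre positions, um).
#' @examples
#' g <- spatial_grid(3, 30)
#' head(g$x)
#' @export
spatial_grid <- function(L = 3, n_cells = 300) {
  if (!is.numeric(L) || length(L) != 1L || L <= 0) {
    stop("domain length 'L' must be a single positive number", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 2L) {
    stop("'n_cells' must be an integer >= 2", call. = FALSE)
  }
  dx <- L / n_cells
  structure(list(L = L, n_cells = n_cells, dx = dx,
                 x = seq(dx / 2, by = dx, length.out = n_cells)),
            class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("spatial grid: L = %g um, %d cells, dx = %g um\n",
              x$L, x$n_cells, x$dx))
  invisible(x)
}
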