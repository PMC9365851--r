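# Tabular dialect shared by all modules: tab-separated UTF-8, '.' decimal
# separator, one header line with fixed column names. Positions are
# distances in um from the kinetochore (cell centres), increasing
# poleward.

profile_columns <- c("side", "time_s", "position_um", "intensity")

#' Write profiles to a tab-separated table
#'
#' Serialises a simulated `hurp_profile`, a `leading`/`trailing` pair
#' from [alternating_run()], or an [observed_profiles()] dataset to the
#' package's profile dialect: columns `side`, `time_s`, `position_um`,
#' `intensity` (tab-separated, header row, positions in um from the
#' kinetochore).
#'
#' @param x Object to serialise.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path) {
  rows <- function(side, times, xpos, H) {
    data.frame(side = side,
               time_s = rep(times, each = length(xpos)),
               position_um = rep(xpos, length(times)),
               intensity = as.vector(t(H)))
  }
  if (inherits(x, "hurp_profile")) {
    df <- rows(x$side, x$times, x$grid$x, x$H)
  } else if (inherits(x, "observed_profiles")) {
    df <- rbind(rows("trailing", x$t_obs, x$x_obs, x$y_plus),
                rows("leading", x$t_obs, x$x_obs, x$y_minus))
  } else if (is.list(x) && inherits(x$leading, "hurp_profile") &&
             inherits(x$trailing, "hurp_profile")) {
    df <- rbind(rows("leading", x$leading$times, x$leading$grid$x,
                     x$leading$H),
                rows("trailing", x$trailing$times, x$trailing$grid$x,
                     x$trailing$H))
  } else {
    stop("cannot serialise objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  utils::write.table(format(df, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile table
#'
#' Parses the tab-separated profile dialect (columns matched by name, in
#' any order). Files containing both a `trailing` and a `leading` side on
#' a common rectangular grid are returned as an [observed_profiles()]
#' dataset; single-side files as a `hurp_profile` on an inferred
#' cell-centred grid. The (time, position) grid of every side must be
#' complete; a missing cell is a format error naming the offending side
#' and time.
#'
#' @param path Input file path.
#' @param sigma Measurement error to attach to an observed dataset;
#'   estimated from the data with [estimate_sigma()] when `NULL`.
#' @return An `observed_profiles` dataset or a `hurp_profile`.
#' @export
read_profile_table <- function(path, sigma = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(profile_columns, names(df))
  if (length(missing_cols)) {
    stop("profile table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sides <- sort(unique(df$side))
  xpos <- sort(unique(df$position_um))
  times <- sort(unique(df$time_s))

  side_matrix <- function(side) {
    sub <- df[df$side == side, ]
    H <- matrix(NA_real_, length(times), length(xpos))
    i <- match(sub$time_s, times)
    j <- match(sub$position_um, xpos)
    H[cbind(i, j)] <- sub$intensity
    if (anyNA(H)) {
      hole <- which(is.na(H), arr.ind = TRUE)[1L, ]
      stop(sprintf(paste0("ragged grid: side '%s' is missing position ",
                          "%g um at time %g s"),
                   side, xpos[hole[2L]], times[hole[1L]]),
           call. = FALSE)
    }
    H
  }

  if (setequal(sides, c("leading", "trailing"))) {
    y_plus <- side_matrix("trailing")
    y_minus <- side_matrix("leading")
    if (is.null(sigma)) {
      sigma <- estimate_sigma(rbind(y_plus, y_minus))
      if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    }
    return(observed_profiles(xpos, times, y_plus, y_minus, sigma))
  }
  if (length(sides) != 1L ||
      !sides %in% c("leading", "trailing")) {
    stop("profile table must contain side 'leading', 'trailing' or both",
         call. = FALSE)
  }
  H <- side_matrix(sides)
  dx <- if (length(xpos) > 1) xpos[2] - xpos[1] else 2 * xpos[1]
  grid <- spatial_grid(L = max(xpos) + dx / 2, n_cells = length(xpos))
  structure(list(grid = grid, times = times, H = H, side = sides),
            class = "hurp_profile")
}

#' Write posterior draws as a long table
#'
#' Tab-separated columns `chain`, `iteration`, `parameter`, `value`.
#'
#' @param samples A `posterior_samples` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_posterior_table <- function(samples, path) {
  dd <- dim(samples$draws)
  df <- data.frame(
    chain = rep(seq_len(dd[1]), times = dd[2] * dd[3]),
    iteration = rep(rep(seq_len(dd[2]), each = dd[1]), times = dd[3]),
    parameter = rep(samples$parameters, each = dd[1] * dd[2]),
    value = as.vector(samples$draws))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a posterior summary as a key-value table
#'
#' @param summary Data.frame from [summarize_posterior()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summary, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(summary)), function(i) {
    vals <- summary[i, setdiff(names(summary), "parameter")]
    data.frame(key = paste(summary$parameter[i], names(vals), sep = "."),
               value = as.numeric(vals))
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

run_config_keys <- list(
  model = c("l", "D", "lam", "mu", "v_plus", "v_minus", "gamma1",
            "gamma2", "s", "r", "sigma", "L"),
  grid = c("L", "n_cells"),
  priors = NULL,   # nested per-parameter blocks, validated below
  mcmc = c("n_iter", "n_chains", "pilot_iter", "proposal_cov", "delta",
           "burn_in_fraction", "seed", "hastings"),
  synth = c("t_lead", "t_trail", "sigma", "dx_obs", "dt_obs", "x_max"),
  analyses = c("frac", "t_settle", "bleach_from", "fit_lags", "max_lag"),
  seed = NA, out_dir = NA, verbosity = NA, fixed = NULL)

#' Read and write flat run configurations (YAML)
#'
#' A run configuration is a named list with blocks `model`, `grid`,
#' `priors`, `mcmc`, `synth`, `analyses` plus global `seed`, `out_dir`,
#' `verbosity` and `fixed`, mirroring the package's constructor argument
#' names. Unknown keys are rejected (fail-fast), not ignored.
#'
#' @param path YAML file path.
#' @param config Named list to serialise.
#' @return `read_run_config()` returns the validated list;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(run_config_keys))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (block in names(cfg)) {
    allowed <- run_config_keys[[block]]
    if (is.null(allowed) || all(is.na(allowed))) next
    bad <- setdiff(names(cfg[[block]]), allowed)
    if (length(bad)) {
      stop("unknown key(s) in config block '", block, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write particle traces or FRAP series to tab-separated tables
#'
#' Traces use columns `trace_id`, `time_s`, `position_um`; FRAP series
#' use `time_s`, `bleach`, `reference`, `background` with a
#' `# pre_bleach_frames` header key line.
#'
#' @param x A `particle_traces` or `frap_raw` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(x, path) {
  if (inherits(x, "particle_traces")) {
    df <- do.call(rbind, lapply(seq_along(x$traces), function(i) {
      pos <- x$traces[[i]]
      data.frame(trace_id = i,
                 time_s = (seq_along(pos) - 1L) * x$dt,
                 position_um = pos)
    }))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (inherits(x, "frap_raw")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# pre_bleach_frames\t%d", x$pre_bleach_count),
               con)
    utils::write.table(data.frame(time_s = x$times, bleach = x$bleach,
                                  reference = x$reference,
                                  background = x$background),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stop("cannot serialise objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
  invisible(path)
}
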