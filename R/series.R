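#' Observed abundance time series
#'
#' A time-stamped series of abundance levels, e.g. digitised single-cell
#' mRNA measurements.  Times are in the file's native wall-clock unit
#' (minutes for yeast series, hours for mammalian ones); levels may be
#' baseline-subtracted and hence non-positive.
#'
#' @param times Strictly increasing numeric vector.
#' @param levels Numeric vector of the same length.
#' @param organism `"yeast"`, `"mammalian"` or `"other"`; sets the
#'   lifespan lower bound used by the fitter (10 minutes for yeast,
#'   2 hours for mammalian cells).
#' @param units_note Free-text note on units.
#' @return Class `observed_series`: list with `times`, `levels`,
#'   `organism`, `units_note` and `sampling_interval` (median spacing).
#' @export
observed_series <- function(times, levels,
                            organism = c("other", "yeast", "mammalian"),
                            units_note = "") {
  organism <- match.arg(organism)
  times <- as.numeric(times)
  levels <- as.numeric(levels)
  if (length(times) != length(levels)) {
    stop("`times` and `levels` must have equal length")
  }
  if (length(times) < 2L) stop("at least two observations are required")
  if (anyNA(times) || anyNA(levels)) stop("missing values are not allowed")
  dt <- diff(times)
  if (any(dt <= 0)) {
    stop("times must be strictly increasing (violated at row ",
         which(dt <= 0)[1L] + 1L, ")")
  }
  structure(list(times = times, levels = levels, organism = organism,
                 units_note = units_note,
                 sampling_interval = stats::median(dt)),
            class = "observed_series")
}

#' @export
print.observed_series <- function(x, ...) {
  cat("<observed_series>", length(x$times), "observations,",
      x$organism, "\n")
  cat("  t in [", x$times[1], ",", x$times[length(x$times)],
      "], interval", x$sampling_interval, "\n")
  invisible(x)
}

#' @export
length.observed_series <- function(x) length(x$times)

#' Read an observation series from CSV
#'
#' Expects a header with columns `time` and `level`; lines starting with
#' `#` are treated as comments (their count is reported).  Times must be
#' strictly increasing and (near-)uniformly spaced; deviations beyond a
#' relative tolerance of `1e-6` trigger a warning.
#'
#' @param path CSV file path.
#' @param organism Passed to [observed_series()].
#' @return An [observed_series()].
#' @export
read_series <- function(path, organism = "other") {
  raw <- readLines(path)
  n_comments <- sum(startsWith(trimws(raw), "#"))
  if (n_comments > 0) message(n_comments, " comment line(s) skipped")
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "level") %in% names(df))) {
    stop("CSV must have header columns `time` and `level`")
  }
  if (!is.numeric(df$time) || !is.numeric(df$level)) {
    stop("non-numeric values in `time` or `level`")
  }
  if (nrow(df) < 4L) stop("at least 4 observations are required")
  dup <- which(diff(df$time) == 0)
  if (length(dup)) stop("duplicate time at row ", dup[1L] + 1L)
  s <- observed_series(df$time, df$level, organism = organism)
  dt <- diff(s$times)
  if ((max(dt) - min(dt)) / stats::median(dt) > 1e-6) {
    warning("sampling times are not uniformly spaced")
  }
  s
}

#' Write / read a trajectory as tidy CSV
#'
#' Columns `time, TB, TA, DA, produced, degraded, acc_production,
#' acc_degradation`, plus the per-age columns `age_0..age_n` when
#' `per_age = TRUE`.  `read_trajectory()` restores the data columns (and
#' the age matrix when present); the generating profile and schedule are
#' not serialised.
#'
#' @param traj A trajectory.
#' @param path Output CSV path.
#' @param per_age Include wide per-age columns (default `TRUE`).
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `trajectory`.
#' @export
write_trajectory <- function(traj, path, per_age = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (nrow(traj) == 0L) stop("refusing to write an empty trajectory")
  df <- as.data.frame(traj)
  if (per_age) df <- cbind(df, as.data.frame(trajectory_ages(traj)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  core <- c("time", "TB", "TA", "DA", "produced", "degraded",
            "acc_production", "acc_degradation")
  if (!all(core %in% names(df))) {
    stop("not a trajectory CSV: missing columns ",
         paste(setdiff(core, names(df)), collapse = ", "))
  }
  age_cols <- grep("^age_", names(df), value = TRUE)
  ages <- if (length(age_cols)) as.matrix(df[age_cols]) else NULL
  structure(df[core], ages = ages, step_length = 1,
            class = c("trajectory", "data.frame"))
}

#' Serialise a fit result to JSON
#'
#' Writes every reported field of a [fit_exhaustive()] result (lifespan,
#' pulse level, survival rates, demand, initial age distribution,
#' accumulated amounts, net rates, R-squared, MdAPE and the fitted
#' values) as a JSON object.
#'
#' @param result A `fit_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(result, path) {
  stopifnot(inherits(result, "fit_result"))
  out <- unclass(result)
  out$trajectory <- NULL  # full model path available via re-simulation
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a run configuration
#'
#' YAML (or JSON) configuration for the simulation commands.  Top-level
#' keys are restricted to the documented set; unknown keys are rejected
#' with a clear message rather than silently ignored.
#'
#' @param path YAML file path.
#' @return Named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("n_ages", "max_age", "survival", "activity",
               "survival_family", "activity_family", "pulse_level", "mode",
               "demand", "horizon", "seed", "step_length", "out",
               "n_groups", "harvest_time", "sampling_interval", "noise",
               "noise_sd", "organism", "scenario", "window_size", "units")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Assemble simulation inputs from a configuration list
#'
#' @param cfg List as returned by [read_run_config()].
#' @return List with `profile`, `policy`, `demand`, `horizon`.
#' @export
config_to_simulation <- function(cfg) {
  max_age <- cfg$max_age %||%
    if (!is.null(cfg$survival)) length(cfg$survival) else
      if (!is.null(cfg$n_ages)) cfg$n_ages - 1L else 10L
  profile <- make_profile(cfg$survival %||% cfg$survival_family %||% "B",
                          cfg$activity %||% cfg$activity_family %||% "A",
                          max_age = max_age)
  policy <- pulse_policy(cfg$pulse_level %||% 100,
                         mode = cfg$mode %||% "demand_gated")
  dem <- cfg$demand %||% list(kind = "constant", level = 50)
  if (is.numeric(dem)) dem <- list(kind = "constant", level = dem)
  demand <- do.call(demand_schedule, dem)
  list(profile = profile, policy = policy, demand = demand,
       horizon = cfg$horizon %||% 100L)
}
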