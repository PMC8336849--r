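#' Detect cycles in a simulated trajectory
#'
#' The dynamics are deterministic with a finite reachable state space,
#' so a steady regime is either a fixed point or an exact periodic
#' orbit.  The period is found by the first exact recurrence of the full
#' age vector (quantised at `tol`), not by spectral estimation; for
#' time-varying periodic demand schedules (kind `"rotation"`) the
#' schedule phase is part of the recurrence state, so the reported
#' period is the global cycle of the driven system.  For rotation
#' schedules, sub-cycles within each dwell phase are also reported.
#'
#' @param traj A trajectory from [simulate_unit()].
#' @param tol Quantisation tolerance for exact state matching.
#' @return A `cycle_report`: list with `regime` (`"fixed_point"`,
#'   `"periodic"` or `"aperiodic_within_horizon"`), `transient` (steps
#'   before the steady regime), `period` (`NA` unless periodic),
#'   `amplitude` (max minus min total abundance over one steady period;
#'   0 for a fixed point), `global_period` and `sub_cycles` (a
#'   data.frame with one row per dwell phase of a rotation schedule),
#'   and `conclusive` (`FALSE` when the horizon was too short to
#'   observe a recurrence).
#' @examples
#' tr <- simulate_unit(make_profile("B", "A"), pulse_policy(100), 50, 60)
#' detect_cycles(tr)$period  # 5
#' @export
detect_cycles <- function(traj, tol = 1e-9) {
  stopifnot(inherits(traj, "trajectory"))
  ages <- trajectory_ages(traj)
  sched <- attr(traj, "schedule")
  n_rows <- nrow(ages)
  state_mat <- round(ages / tol) * tol
  keys <- apply(state_mat, 1L, paste, collapse = "|")
  periodic_driver <- !is.null(sched) && sched$kind == "rotation"
  if (periodic_driver) {
    sp <- sum(sched$dwell)
    phase <- (pmax(traj$time, 1) - 1) %% sp
    keys <- paste(phase, keys, sep = "@")
  } else if (!is.null(sched) && !sched$kind %in% c("constant", "rotation")) {
    # aperiodic forcing: only a terminal fixed point is classifiable
    return(fixed_point_or_inconclusive(traj, tol))
  }

  first <- match(keys, keys)
  rec <- which(first < seq_along(keys))
  if (length(rec) == 0L) {
    return(new_cycle_report("aperiodic_within_horizon", transient = NA,
                            period = NA, amplitude = NA,
                            conclusive = FALSE))
  }
  i <- rec[1L]
  s <- first[i]                  # row index of first repeated state
  period <- i - s
  transient <- traj$time[s]      # time index at which the orbit begins
  tb_cycle <- traj$TB[s:(i - 1L)]
  if (period == 1L) {
    return(new_cycle_report("fixed_point", transient = transient,
                            period = NA, amplitude = 0,
                            value = traj$TB[s]))
  }
  amplitude <- max(tb_cycle) - min(tb_cycle)
  sub <- NULL
  if (periodic_driver) {
    sub <- rotation_sub_cycles(traj, sched, start = s, period = period,
                               tol = tol)
  }
  new_cycle_report("periodic", transient = transient, period = period,
                   amplitude = amplitude, sub_cycles = sub,
                   global_period = period)
}

new_cycle_report <- function(regime, transient, period, amplitude,
                             sub_cycles = NULL, global_period = period,
                             value = NULL, conclusive = TRUE) {
  structure(list(regime = regime, transient = transient, period = period,
                 amplitude = amplitude, sub_cycles = sub_cycles,
                 global_period = global_period, value = value,
                 conclusive = conclusive),
            class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  cat("<cycle_report>", x$regime)
  if (!is.na(x$period %||% NA)) cat(", period", x$period)
  if (!is.null(x$amplitude) && !is.na(x$amplitude)) {
    cat(", amplitude", signif(x$amplitude, 6))
  }
  cat(", transient", x$transient, "\n")
  if (!is.null(x$sub_cycles)) {
    cat("  sub-cycles:\n")
    print(x$sub_cycles)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixed_point_or_inconclusive <- function(traj, tol) {
  ages <- trajectory_ages(traj)
  n <- nrow(ages)
  same <- rowSums(abs(sweep(ages, 2L, ages[n, ])) > tol) == 0
  run <- rev(cumprod(rev(same)))  # tail rows identical to the last row
  if (sum(run) >= 3L) {
    s <- which(run == 1)[1L]
    return(new_cycle_report("fixed_point", transient = traj$time[s],
                            period = NA, amplitude = 0,
                            value = traj$TB[n]))
  }
  new_cycle_report("aperiodic_within_horizon", transient = NA, period = NA,
                   amplitude = NA, conclusive = FALSE)
}

# Sub-cycle (within-dwell-phase) periods of a rotation-driven steady
# orbit: for each demand level, take the last complete dwell window in
# the steady segment and find the smallest exact period of TB inside
# it, allowing a short settle after the phase switch.
rotation_sub_cycles <- function(traj, sched, start, period, tol) {
  lv <- sched$levels
  dw <- sched$dwell
  sp <- sum(dw)
  out <- data.frame(level = lv, dwell = dw, period = NA_integer_,
                    settle = NA_integer_)
  seg_times <- traj$time[start:nrow(traj)]
  for (k in 1:2) {
    lo <- if (k == 1) 0 else dw[1]
    hi <- if (k == 1) dw[1] else sp
    phase <- (pmax(seg_times, 1) - 1) %% sp
    in_phase <- phase >= lo & phase < hi
    # last complete dwell window fully inside the recorded segment
    r <- rle(in_phase)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    full <- which(r$values & r$lengths == dw[k])
    if (length(full) == 0L) next
    w <- full[length(full)]
    tb <- traj$TB[(start - 1L) + (starts[w]:ends[w])]
    sc <- exact_sub_period(tb, tol)
    out$period[k] <- sc$period
    out$settle[k] <- sc$settle
  }
  out
}

# Smallest p such that v repeats with period p from some settle offset
# onwards, with at least two full periods observed.
exact_sub_period <- function(v, tol = 1e-9) {
  len <- length(v)
  for (p in seq_len(len %/% 2)) {
    for (off in 0:(len - 2L * p)) {
      w <- v[(off + 1L):len]
      nl <- length(w) - p
      if (all(abs(w[seq_len(nl)] - w[seq_len(nl) + p]) <= tol)) {
        return(list(period = p, settle = off))
      }
    }
  }
  list(period = NA_integer_, settle = NA_integer_)
}

#' Decimate a trajectory into an observation series
#'
#' Returns total abundance at times `offset, offset + interval, ...`,
#' emulating an experiment that samples the underlying dynamics at a
#' fixed interval.  Sampling a period-`p` orbit at interval `p` aliases
#' it to an apparently constant level.
#'
#' @param traj A trajectory.
#' @param interval Sampling interval in model steps (`>= 1`).
#' @param offset First sampled time index (`>= 0`).
#' @return An [observed_series()]; the decimation is recorded in its
#'   `units_note`.
#' @export
resample_trajectory <- function(traj, interval, offset = 0) {
  stopifnot(inherits(traj, "trajectory"))
  interval <- as.integer(interval)
  offset <- as.integer(offset)
  if (interval < 1L) stop("`interval` must be >= 1")
  if (offset < 0L) stop("`offset` must be >= 0")
  horizon <- max(traj$time)
  if (interval >= nrow(traj)) {
    stop("sampling interval exceeds the trajectory length")
  }
  times <- seq(offset, horizon, by = interval)
  if (length(times) < 2L) stop("fewer than two samples; extend the horizon")
  lv <- traj$TB[match(times, traj$time)]
  observed_series(times * attr(traj, "step_length"), lv,
                  units_note = sprintf("resampled interval=%d offset=%d",
                                       interval, offset))
}

#' Compare two equal-length trajectories
#'
#' Per-time differences of total abundance between two runs (for
#' example two demand levels), plus a sign summary showing at what
#' fraction of sampled times each run is the higher one — the basis of
#' the observation that a higher-demand condition can appear either
#' up- or down-regulated depending on sampling time.
#'
#' @param traj_a,traj_b Trajectories over the same horizon.
#' @return List with `differences` (data.frame `time`, `TB_a`, `TB_b`,
#'   `diff` = `TB_a - TB_b`), `frac_a_higher`, `frac_b_higher`,
#'   `frac_equal` and `sign_changes`.
#' @export
compare_demand_levels <- function(traj_a, traj_b) {
  stopifnot(inherits(traj_a, "trajectory"), inherits(traj_b, "trajectory"))
  if (nrow(traj_a) != nrow(traj_b)) stop("trajectories must share a horizon")
  d <- traj_a$TB - traj_b$TB
  list(
    differences = data.frame(time = traj_a$time, TB_a = traj_a$TB,
                             TB_b = traj_b$TB, diff = d),
    frac_a_higher = mean(d > 0),
    frac_b_higher = mean(d < 0),
    frac_equal = mean(d == 0),
    sign_changes = any(d > 0) && any(d < 0)
  )
}
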