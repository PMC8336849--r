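#' One-unit state: abundance by age
#'
#' @param abundance Non-negative numeric vector `B_0 .. B_n` (length
#'   `max_age + 1`); defaults to empty (all zeros).
#' @param profile The [age_profile()] the state belongs to (fixes the
#'   length).
#' @return Class `unit_state`: list with `abundance`, `tb`, `ta`.
#' @export
unit_state <- function(profile, abundance = NULL) {
  stopifnot(inherits(profile, "age_profile"))
  n1 <- profile$max_age + 1L
  if (is.null(abundance)) abundance <- rep(0, n1)
  abundance <- as.numeric(abundance)
  if (length(abundance) != n1) {
    stop("abundance vector must have one entry per age 0..", profile$max_age)
  }
  if (anyNA(abundance) || any(abundance < 0)) {
    stop("abundances must be non-negative")
  }
  structure(list(abundance = abundance,
                 tb = sum(abundance),
                 ta = sum(abundance * profile$activity)),
            class = "unit_state")
}

#' Advance a unit one time step
#'
#' All cohorts age by one step with survival applied (`B_{x,t} =
#' B_{x-1,t-1} d_{x-1}`); the cohort at the maximum age is removed in
#' full.  A production pulse then fires according to the policy: in
#' demand-gated mode iff the gating activity is strictly below `demand`
#' (ties do not trigger).  With the default `"pre_aging"` gate the
#' gating activity is the previous step's reported total activity; with
#' `"post_aging"` it is the total activity after aging, before the
#' pulse.  The pulse, when it fires, is included in the returned totals.
#'
#' @param state A [unit_state()].
#' @param profile An [age_profile()].
#' @param policy A [pulse_policy()].
#' @param demand Non-negative demand `DA_t` for this step.
#' @return List with the new `state`, `produced` (0 or the pulse level)
#'   and `degraded` (total abundance lost this step), satisfying
#'   `new_tb - old_tb == produced - degraded`.
#' @export
step_unit <- function(state, profile, policy, demand) {
  stopifnot(inherits(state, "unit_state"), inherits(profile, "age_profile"),
            inherits(policy, "pulse_policy"))
  if (length(demand) != 1L || is.na(demand) || demand < 0) {
    stop("`demand` must be a single non-negative number")
  }
  b <- state$abundance
  n1 <- length(b)
  d <- profile$survival
  aged <- c(0, b[-n1] * d)
  degraded <- sum(b[-n1] * (1 - d)) + b[n1]
  gate_ta <- if (policy$gate == "pre_aging") state$ta else
    sum(aged * profile$activity)
  fire <- switch(policy$mode,
    demand_gated = gate_ta < demand,
    unregulated_continuous = TRUE,
    silent = FALSE
  )
  produced <- 0
  if (fire) {
    aged[1] <- aged[1] + policy$pulse_level
    produced <- policy$pulse_level
  }
  list(state = unit_state(profile, aged), produced = produced,
       degraded = degraded)
}

#' Simulate a one-unit model
#'
#' Runs the age-structured recursion for `horizon` steps under a demand
#' schedule, recording totals, production and degradation at every step.
#'
#' @param profile An [age_profile()].
#' @param policy A [pulse_policy()].
#' @param demand A [demand_schedule()] (or a single number, taken as a
#'   constant schedule).
#' @param horizon Number of steps to simulate (`>= 1`).
#' @param initial Optional initial [unit_state()]; defaults to empty.
#' @param step_length Wall-clock length of one step (metadata only;
#'   default 1).
#' @return A `trajectory`: a data.frame with rows for times
#'   `0..horizon` and columns `time`, `TB`, `TA`, `DA`, `produced`,
#'   `degraded`, `acc_production`, `acc_degradation`.  The per-age
#'   abundance matrix (rows = times, columns `age_0..age_n`) is attached
#'   as attribute `"ages"`, along with `"profile"`, `"policy"`,
#'   `"schedule"` and `"step_length"`.
#' @examples
#' traj <- simulate_unit(make_profile("B", "A"), pulse_policy(100),
#'                       demand_schedule("constant", level = 50), 40)
#' head(traj)
#' @export
simulate_unit <- function(profile, policy, demand, horizon,
                          initial = NULL, step_length = 1) {
  stopifnot(inherits(profile, "age_profile"), inherits(policy, "pulse_policy"))
  if (is.numeric(demand) && length(demand) == 1L) {
    demand <- demand_schedule("constant", level = demand)
  }
  stopifnot(inherits(demand, "demand_schedule"))
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("`horizon` must be >= 1")
  if (is.null(initial)) initial <- unit_state(profile)
  stopifnot(inherits(initial, "unit_state"))

  n1 <- profile$max_age + 1L
  ages <- matrix(0, nrow = horizon + 1L, ncol = n1,
                 dimnames = list(NULL, paste0("age_", seq_len(n1) - 1L)))
  tb <- ta <- da <- produced <- degraded <- numeric(horizon + 1L)
  ages[1L, ] <- initial$abundance
  tb[1L] <- initial$tb
  ta[1L] <- initial$ta
  da[1L] <- demand_at(demand, 0)

  state <- initial
  for (t in seq_len(horizon)) {
    dem <- demand_at(demand, t)
    res <- step_unit(state, profile, policy, dem)
    state <- res$state
    i <- t + 1L
    ages[i, ] <- state$abundance
    tb[i] <- state$tb
    ta[i] <- state$ta
    da[i] <- dem
    produced[i] <- res$produced
    degraded[i] <- res$degraded
  }

  traj <- data.frame(time = 0:horizon, TB = tb, TA = ta, DA = da,
                     produced = produced, degraded = degraded,
                     acc_production = cumsum(produced),
                     acc_degradation = cumsum(degraded))
  structure(traj,
            ages = ages, profile = profile, policy = policy,
            schedule = demand, step_length = step_length,
            class = c("trajectory", "data.frame"))
}

#' Per-age abundance matrix of a trajectory
#'
#' @param traj A trajectory from [simulate_unit()].
#' @return Numeric matrix, one row per recorded time (starting at 0),
#'   one column per age.
#' @export
trajectory_ages <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  attr(traj, "ages")
}

#' Fixed point of continuous pulsing
#'
#' When a pulse of size `pulse_level` fires at every step (unregulated
#' production, or demand permanently above the reachable activity), the
#' total abundance converges to `B0 * sum_k prod_{j<k} d_j`: one full
#' ladder of surviving cohorts.
#'
#' @param profile An [age_profile()].
#' @param pulse_level Non-negative pulse size.
#' @return The steady-state total abundance.
#' @examples
#' steady_state_abundance(make_profile("B", "A"), 100)  # 364
#' @export
steady_state_abundance <- function(profile, pulse_level) {
  stopifnot(inherits(profile, "age_profile"))
  if (pulse_level < 0) stop("`pulse_level` must be non-negative")
  pulse_level * sum(cumprod(c(1, profile$survival)))
}
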