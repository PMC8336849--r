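#' Coefficient of determination
#'
#' `1 - SS_residual / SS_total`, with the total sum of squares taken
#' about the observed mean.
#'
#' @param observed,predicted Equal-length numeric vectors (`>= 2`
#'   points).
#' @return R-squared (at most 1; can be negative for fits worse than
#'   the mean).
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop("`observed` and `predicted` must share a length >= 2")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("zero total variation: R-squared is undefined for a constant series")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Median absolute percentage error
#'
#' Median over observations of `|observed - predicted| / |observed|`.
#' Observations with `|observed| < eps` (e.g. exactly-baseline points in
#' baseline-subtracted data) are dropped from the median, with the count
#' reported via `message()`.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param eps Magnitude below which an observation is excluded
#'   (default `1e-9`).
#' @return The MdAPE (a non-negative fraction).
#' @examples
#' mdape(c(10, 20), c(9, 24))  # 0.15
#' @export
mdape <- function(observed, predicted, eps = 1e-9) {
  if (length(observed) != length(predicted) || length(observed) < 1L) {
    stop("`observed` and `predicted` must have equal positive length")
  }
  keep <- abs(observed) >= eps
  if (!any(keep)) {
    stop("all observed values are below `eps`: MdAPE is undefined")
  }
  if (any(!keep)) {
    message(sum(!keep), " near-zero observation(s) excluded from MdAPE")
  }
  stats::median(abs(observed[keep] - predicted[keep]) / abs(observed[keep]))
}

#' Specification of the exhaustive-search fit
#'
#' Defines the candidate grids over which [fit_exhaustive()] searches.
#' Grids left `NULL` are derived from the data: the pulse grid spans
#' `0.1..1.5` times the maximum observed level in `n_pulse` steps
#' (refined to 0.1-unit resolution around the optimum when
#' `refine_pulse`), the demand grid spans `[max(0, min(obs)),
#' 1.5 max(obs)]` in `n_demand` steps, and the lifespan grid runs over
#' multiples of the sampling interval from the organism lower bound (10
#' minutes for yeast, 2 hours for mammalian cells, one sampling interval
#' otherwise) up to the series duration.
#'
#' The fit uses `n_ages` ages (default 5, dividing a lifespan into four
#' equal periods); activity coefficients are fixed at 1, survival rates
#' for the first `n_ages - 2` transitions are free on `survival_grid`
#' and the final transition is 0 (complete degradation at the maximum
#' age).  The initial age distribution is estimated on a coarse grid:
#' `"binary"` (each age either 0 or one pulse level; default) or
#' `"empty"` (all zero), or an explicit matrix of pulse multipliers.
#'
#' @param n_ages Number of ages (default 5).
#' @param survival_grid Candidate survival fractions (default
#'   `0, 0.1, ..., 1`).
#' @param pulse_grid,demand_grid,lifespan_grid Optional explicit grids.
#' @param lifespan_lower Optional explicit lifespan lower bound
#'   (overrides the organism default), in the series' time unit.
#' @param init_grid `"binary"`, `"empty"`, or a numeric matrix with
#'   `n_ages` columns of pulse-level multipliers.
#' @param scenario `"stable_demand"` (one constant demand, for stable or
#'   periodic series) or `"windowed_demand"` (demand re-estimated per
#'   window of `window_size` observations, for irregular series).
#' @param window_size Observations per demand window (`>= 4`).
#' @param n_pulse,n_demand Grid sizes for the data-driven grids.
#' @param refine_pulse Refine the pulse grid to 0.1-unit resolution
#'   around the coarse optimum (default `TRUE`).
#' @param budget Maximum number of grid evaluations allowed (error if
#'   exceeded).
#' @return Class `fit_spec`.
#' @export
fit_spec <- function(n_ages = 5L, survival_grid = 0:10 / 10,
                     pulse_grid = NULL, demand_grid = NULL,
                     lifespan_grid = NULL, lifespan_lower = NULL,
                     init_grid = c("binary", "empty"),
                     scenario = c("stable_demand", "windowed_demand"),
                     window_size = 4L, n_pulse = 20L, n_demand = 20L,
                     refine_pulse = TRUE, budget = 3e8) {
  scenario <- match.arg(scenario)
  if (!is.matrix(init_grid)) init_grid <- match.arg(init_grid)
  n_ages <- as.integer(n_ages)
  if (n_ages < 3L) stop("`n_ages` must be at least 3")
  if (any(survival_grid < 0 | survival_grid > 1)) {
    stop("survival grid values must lie in [0, 1]")
  }
  window_size <- as.integer(window_size)
  if (window_size < 4L) stop("`window_size` must be >= 4")
  structure(list(n_ages = n_ages, survival_grid = sort(survival_grid),
                 pulse_grid = pulse_grid, demand_grid = demand_grid,
                 lifespan_grid = lifespan_grid,
                 lifespan_lower = lifespan_lower, init_grid = init_grid,
                 scenario = scenario, window_size = window_size,
                 n_pulse = n_pulse, n_demand = n_demand,
                 refine_pulse = refine_pulse, budget = budget),
            class = "fit_spec")
}

organism_lifespan_lower <- function(organism, sampling_interval) {
  switch(organism,
         yeast = 10,        # minutes
         mammalian = 2,     # hours
         sampling_interval)
}

resolve_grids <- function(series, spec) {
  obs <- series$levels
  hi <- max(obs)
  if (hi <= 0) hi <- max(abs(obs), 1)
  pulse <- spec$pulse_grid %||%
    seq(0.1 * hi, 1.5 * hi, length.out = spec$n_pulse)
  demand <- spec$demand_grid %||%
    seq(max(0, min(obs)), 1.5 * hi, length.out = spec$n_demand)
  lower <- spec$lifespan_lower %||%
    organism_lifespan_lower(series$organism, series$sampling_interval)
  lifespans <- spec$lifespan_grid %||% {
    dt <- series$sampling_interval
    duration <- series$times[length(series$times)] - series$times[1L]
    cand <- seq(dt, max(duration, lower + dt), by = dt)
    cand <- cand[cand >= lower & cand <= max(duration, lower)]
    if (length(cand) == 0L) cand <- lower
    cand
  }
  free <- spec$n_ages - 2L
  sg <- sort(spec$survival_grid, decreasing = TRUE)
  surv_rows <- as.matrix(expand.grid(rev(rep(list(sg), free)),
                                     KEEP.OUT.ATTRS = FALSE))[,
                                     free:1L, drop = FALSE]
  surv <- cbind(surv_rows, 0)  # last transition: complete degradation
  colnames(surv) <- paste0("d_", 0:(spec$n_ages - 2L))
  init <- if (is.matrix(spec$init_grid)) {
    spec$init_grid
  } else if (identical(spec$init_grid, "binary")) {
    as.matrix(expand.grid(rep(list(c(0, 1)), spec$n_ages),
                          KEEP.OUT.ATTRS = FALSE))
  } else {
    matrix(0, 1L, spec$n_ages)
  }
  list(pulse = sort(unique(pulse)), demand = sort(unique(demand)),
       lifespans = sort(unique(lifespans)), surv = surv, init = init)
}

align_steps <- function(times, step_length) {
  rel <- (times - times[1L]) / step_length
  idx <- as.integer(round(rel))
  if (any(abs(rel - idx) > 1e-6 * pmax(1, abs(rel)))) {
    warning("observation times are not integer multiples of the model ",
            "step; using nearest-step alignment", call. = FALSE)
  }
  idx
}

#' Exhaustive grid-search fit of the demand-gated model
#'
#' Searches every combination of lifespan, survival rates, pulse level,
#' demand and initial age distribution on the grids of a [fit_spec()],
#' simulating the one-unit model (activity fixed at 1) for each and
#' selecting the candidate minimising the sum of squared errors against
#' the observed levels at the observation times.  One model step equals
#' `lifespan / (n_ages - 1)`; observations are matched to the nearest
#' model step.  Ties in SSE are broken deterministically: shorter
#' lifespan, then smaller pulse level, then larger survival rates, then
#' smaller demand, then sparser initial distribution.
#'
#' In the `"windowed_demand"` scenario the search is the two-stage
#' procedure of [estimate_demand_windowed()].
#'
#' @param series An [observed_series()] (`>= 4` observations).
#' @param spec A [fit_spec()].
#' @return Class `fit_result`: list with the selected `lifespan`,
#'   `step_length`, `pulse_level`, `survival`, `demand` (scalar, or
#'   per-step vector in the windowed scenario), `initial_ages`, `sse`,
#'   `r_squared`, `mdape`, `fitted` (data.frame `time`, `observed`,
#'   `predicted`, `step`), `accumulated_transcription`,
#'   `accumulated_degradation`, `net_transcription_rate`,
#'   `net_degradation_rate`, `duration`, `n_evaluated` and the fitted
#'   model `trajectory`.
#' @export
fit_exhaustive <- function(series, spec = fit_spec()) {
  stopifnot(inherits(series, "observed_series"), inherits(spec, "fit_spec"))
  if (length(series) < 4L) stop("at least 4 observations are required")
  if (spec$scenario == "windowed_demand") {
    return(estimate_demand_windowed(series, spec)$result)
  }
  g <- resolve_grids(series, spec)
  fit_over_lifespans(series, spec, g, demand_maker = NULL)
}

# Shared search driver.  demand_maker: NULL for the stable scenario
# (constant-demand candidates from g$demand), or function(n_steps,
# step_length) -> one-row demand matrix for fixed per-step demands.
fit_over_lifespans <- function(series, spec, g, demand_maker = NULL) {
  obs <- series$levels
  times <- series$times
  best <- NULL
  n_eval <- 0
  per_lifespan <- vapply(g$lifespans, function(L) {
    nrow(g$surv) * length(g$pulse) * nrow(g$init) *
      if (is.null(demand_maker)) length(g$demand) else 1
  }, numeric(1))
  if (sum(per_lifespan) > spec$budget) {
    stop("grid cardinality ", format(sum(per_lifespan), big.mark = ","),
         " exceeds the budget of ", format(spec$budget, big.mark = ","))
  }
  for (L in g$lifespans) {
    step_len <- L / (spec$n_ages - 1L)
    idx <- suppressWarnings(align_steps(times, step_len))
    n_steps <- max(idx, 1L)
    dm <- if (is.null(demand_maker)) {
      matrix(rep(g$demand, n_steps), nrow = length(g$demand))
    } else {
      demand_maker(n_steps, step_len)
    }
    res <- grid_search_cpp(obs, idx, g$surv, g$pulse, dm, g$init, n_steps)
    n_eval <- n_eval + res$n_evaluated
    if (is.null(best) || res$sse < best$sse) {
      best <- res
      best$lifespan <- L
      best$step_length <- step_len
      best$idx <- idx
      best$n_steps <- n_steps
      best$demand_row <- dm[res$i_demand, ]
    }
  }
  # warn (once, for the selected lifespan) if alignment was inexact
  invisible(align_steps(times, best$step_length))
  # optional pulse refinement at 0.1-unit resolution around the optimum
  coarse_h <- if (length(g$pulse) > 1L) min(diff(g$pulse)) else 0
  if (isTRUE(spec$refine_pulse) && coarse_h > 0.1) {
    p0 <- g$pulse[best$i_pulse]
    fine <- seq(max(0, round(p0 - coarse_h, 1)), round(p0 + coarse_h, 1),
                by = 0.1)
    g_fine <- g
    g_fine$pulse <- sort(unique(round(fine, 10)))
    spec2 <- spec
    spec2$refine_pulse <- FALSE
    fine_best <- fit_over_lifespans_raw(series, spec2, g_fine, demand_maker)
    n_eval <- n_eval + fine_best$n_evaluated_total
    if (fine_best$sse < best$sse) {
      best <- fine_best
      g <- g_fine
    }
  }
  build_fit_result(series, spec, g, best, n_eval)
}

# refinement pass without result assembly (avoids recursion into
# refinement again)
fit_over_lifespans_raw <- function(series, spec, g, demand_maker) {
  obs <- series$levels
  times <- series$times
  best <- NULL
  n_eval <- 0
  for (L in g$lifespans) {
    step_len <- L / (spec$n_ages - 1L)
    idx <- suppressWarnings(align_steps(times, step_len))
    n_steps <- max(idx, 1L)
    dm <- if (is.null(demand_maker)) {
      matrix(rep(g$demand, n_steps), nrow = length(g$demand))
    } else {
      demand_maker(n_steps, step_len)
    }
    res <- grid_search_cpp(obs, idx, g$surv, g$pulse, dm, g$init, n_steps)
    n_eval <- n_eval + res$n_evaluated
    if (is.null(best) || res$sse < best$sse) {
      best <- res
      best$lifespan <- L
      best$step_length <- step_len
      best$idx <- idx
      best$n_steps <- n_steps
      best$demand_row <- dm[res$i_demand, ]
    }
  }
  best$n_evaluated_total <- n_eval
  best
}

build_fit_result <- function(series, spec, g, best, n_eval) {
  pulse <- g$pulse[best$i_pulse]
  surv <- g$surv[best$i_surv, ]
  init_mult <- g$init[best$i_init, ]
  init_levels <- init_mult * pulse
  demand_row <- best$demand_row
  constant_demand <- length(unique(demand_row)) == 1L
  profile <- age_profile(unname(surv))
  policy <- pulse_policy(pulse)
  sched <- if (constant_demand) {
    demand_schedule("constant", level = demand_row[1L])
  } else {
    demand_schedule("explicit", values = demand_row)
  }
  traj <- simulate_unit(profile, policy, sched, best$n_steps,
                        initial = unit_state(profile, init_levels),
                        step_length = best$step_length)
  predicted <- traj$TB[best$idx + 1L]
  obs <- series$levels
  sse <- sum((obs - predicted)^2)
  duration <- series$times[length(series$times)] - series$times[1L]
  acc_t <- traj$acc_production[nrow(traj)]
  acc_d <- traj$acc_degradation[nrow(traj)]
  r2 <- tryCatch(r_squared(obs, predicted), error = function(e) NA_real_)
  md <- tryCatch(suppressMessages(mdape(obs, predicted)),
                 error = function(e) NA_real_)
  structure(list(
    lifespan = best$lifespan, step_length = best$step_length,
    n_ages = spec$n_ages, pulse_level = pulse,
    survival = unname(surv),
    demand = if (constant_demand) demand_row[1L] else demand_row,
    initial_ages = unname(init_levels),
    sse = sse, r_squared = r2, mdape = md,
    fitted = data.frame(time = series$times, observed = obs,
                        predicted = predicted, step = best$idx),
    accumulated_transcription = acc_t,
    accumulated_degradation = acc_d,
    net_transcription_rate = acc_t / duration,
    net_degradation_rate = acc_d / duration,
    duration = duration, organism = series$organism,
    scenario = spec$scenario, n_evaluated = n_eval,
    trajectory = traj
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n")
  cat("  lifespan", x$lifespan, "(step", signif(x$step_length, 4), ")\n")
  cat("  pulse level", x$pulse_level, "\n")
  cat("  survival", paste(signif(x$survival, 4), collapse = " "), "\n")
  cat("  demand", paste(signif(unique(x$demand), 4), collapse = " "), "\n")
  cat("  SSE", signif(x$sse, 6), " R2", signif(x$r_squared, 4),
      " MdAPE", signif(x$mdape, 4), "\n")
  cat("  accumulated transcription", signif(x$accumulated_transcription, 6),
      ", degradation", signif(x$accumulated_degradation, 6), "\n")
  invisible(x)
}

#' Two-stage windowed demand estimation
#'
#' For irregularly fluctuating series the demand cannot be assumed
#' constant.  Stage 1 fits every consecutive window of `window_size`
#' observations independently (all parameters free, initial age
#' distribution on the coarse binary grid) and retains only the demand
#' estimate of each window.  Stage 2 fixes the demand as the resulting
#' piecewise-constant schedule and re-fits all remaining parameters
#' against the full series.
#'
#' @param series An [observed_series()].
#' @param spec A [fit_spec()] (its `window_size` is used; a trailing
#'   partial window is merged into the last full one).
#' @return List with `windows` (data.frame `start_time`, `end_time`,
#'   `demand`) and `result` (the stage-2 `fit_result`, whose `demand`
#'   field is the per-step demand vector).
#' @export
estimate_demand_windowed <- function(series, spec = fit_spec()) {
  stopifnot(inherits(series, "observed_series"), inherits(spec, "fit_spec"))
  m <- length(series)
  w <- spec$window_size
  if (m < w) stop("series shorter than one window of ", w)
  starts <- seq(1L, m, by = w)
  if (m - starts[length(starts)] + 1L < w && length(starts) > 1L) {
    starts <- starts[-length(starts)]  # merge trailing partial window
  }
  ends <- c(starts[-1L] - 1L, m)

  g_full <- resolve_grids(series, spec)
  win_spec <- spec
  win_spec$scenario <- "stable_demand"
  win_spec$init_grid <- "binary"
  win_spec$refine_pulse <- FALSE
  windows <- data.frame(start_time = series$times[starts],
                        end_time = series$times[ends],
                        demand = NA_real_)
  for (i in seq_along(starts)) {
    sub <- observed_series(series$times[starts[i]:ends[i]],
                           series$levels[starts[i]:ends[i]],
                           organism = series$organism)
    gw <- resolve_grids(series, win_spec)  # grids from the full series
    res <- fit_over_lifespans_raw(sub, win_spec, gw, demand_maker = NULL)
    windows$demand[i] <- gw$demand[res$i_demand]
  }

  # left-continuous: the step observed exactly at a window's start time
  # is still governed by the previous window's demand
  demand_of_time <- stats::stepfun(windows$start_time[-1L], windows$demand,
                                   right = TRUE)
  maker <- function(n_steps, step_len) {
    tt <- series$times[1L] + seq_len(n_steps) * step_len
    matrix(demand_of_time(tt), nrow = 1L)
  }
  g2 <- g_full
  g2$demand <- NA_real_  # unused under a fixed demand schedule
  stage2 <- fit_over_lifespans(series, spec, g2, demand_maker = maker)
  stage2$scenario <- "windowed_demand"
  list(windows = windows, result = stage2)
}

#' Metabolic rates table from a fit
#'
#' Net transcription and degradation rates are the accumulated amounts
#' divided by the experiment duration; the lifespan is reported in
#' wall-clock units as `(n_ages - 1)` steps times the step length.
#'
#' @param result A `fit_result`.
#' @param duration Experiment duration (defaults to the fitted series'
#'   span).
#' @return A data.frame with columns `quantity` and `value`.
#' @export
metabolic_report <- function(result, duration = NULL) {
  stopifnot(inherits(result, "fit_result"))
  duration <- duration %||% result$duration
  data.frame(
    quantity = c("lifespan", "step_length", "pulse_level",
                 "accumulated_transcription", "accumulated_degradation",
                 "net_transcription_rate", "net_degradation_rate",
                 "r_squared", "mdape"),
    value = c(result$step_length * (result$n_ages - 1L),
              result$step_length, result$pulse_level,
              result$accumulated_transcription,
              result$accumulated_degradation,
              result$accumulated_transcription / duration,
              result$accumulated_degradation / duration,
              result$r_squared, result$mdape)
  )
}
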