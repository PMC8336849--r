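#' Generate a synthetic observation series with known ground truth
#'
#' Simulates the one-unit model, samples total abundance at a fixed
#' interval, converts step indices to wall-clock times, and optionally
#' adds seeded measurement noise.  The generating parameters are
#' attached as the `"ground_truth"` attribute, so the series can be used
#' directly in parameter-recovery experiments.
#'
#' With `noise = "none"` the series equals the resampled simulator
#' output exactly; with a fixed `seed` the output is reproducible
#' byte-for-byte.
#'
#' @param profile An [age_profile()].
#' @param policy A [pulse_policy()].
#' @param demand A [demand_schedule()] or constant level.
#' @param horizon Steps to simulate.
#' @param sampling_interval Sampling interval in model steps (default 1).
#' @param step_length Wall-clock length of one model step (default 1).
#' @param noise `"none"`, `"additive"` (Gaussian with standard deviation
#'   `noise_sd` times the mean absolute level) or `"multiplicative"`
#'   (levels scaled by `Normal(1, noise_sd)` draws).
#' @param noise_sd Noise scale as a fraction (default 0.05).
#' @param seed Optional integer seed for the noise draws.
#' @param organism Passed to [observed_series()].
#' @param initial Optional initial [unit_state()].
#' @return An [observed_series()] with attribute `"ground_truth"` (list
#'   of the generating profile, policy, demand, step length and the
#'   noise settings).
#' @examples
#' s <- generate_series(make_profile("B", "A"), pulse_policy(100), 50,
#'                      horizon = 40)
#' attr(s, "ground_truth")$policy$pulse_level
#' @export
generate_series <- function(profile, policy, demand, horizon,
                            sampling_interval = 1L, step_length = 1,
                            noise = c("none", "additive", "multiplicative"),
                            noise_sd = 0.05, seed = NULL,
                            organism = "other", initial = NULL) {
  noise <- match.arg(noise)
  traj <- simulate_unit(profile, policy, demand, horizon,
                        initial = initial, step_length = step_length)
  steps <- seq(0L, horizon, by = sampling_interval)
  lv <- traj$TB[steps + 1L]
  if (noise != "none") {
    if (!is.null(seed)) set.seed(seed)
    lv <- switch(noise,
      additive = lv + stats::rnorm(length(lv),
                                   sd = noise_sd * mean(abs(lv))),
      multiplicative = lv * stats::rnorm(length(lv), 1, noise_sd))
  }
  s <- observed_series(steps * step_length, lv, organism = organism,
                       units_note = sprintf("synthetic (%s noise)", noise))
  attr(s, "ground_truth") <- list(
    profile = profile, policy = policy, demand = demand,
    horizon = horizon, sampling_interval = sampling_interval,
    step_length = step_length, noise = noise,
    noise_sd = if (noise == "none") 0 else noise_sd, seed = seed)
  s
}

#' Write an observation series to CSV (with ground-truth sidecar)
#'
#' @param series An [observed_series()].
#' @param path Output CSV path; if the series carries a
#'   `"ground_truth"` attribute, a JSON sidecar `<path>.truth.json` is
#'   written alongside.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "observed_series"))
  utils::write.csv(data.frame(time = series$times, level = series$levels),
                   path, row.names = FALSE)
  gt <- attr(series, "ground_truth")
  if (!is.null(gt)) {
    flat <- list(
      survival = gt$profile$survival, activity = gt$profile$activity,
      pulse_level = gt$policy$pulse_level, mode = gt$policy$mode,
      demand = unclass(gt$demand), horizon = gt$horizon,
      sampling_interval = gt$sampling_interval,
      step_length = gt$step_length, noise = gt$noise,
      noise_sd = gt$noise_sd, seed = gt$seed)
    jsonlite::write_json(flat, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
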