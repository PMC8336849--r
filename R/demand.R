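#' Demand-for-activity schedule
#'
#' A `demand_schedule` maps the integer time index `t` to the demand for
#' biomolecule activity `DA_t`, the stimulus level against which total
#' activity is compared when gating production.  Supported kinds:
#'
#' * `"constant"`: `DA_t = level`.
#' * `"rotation"`: alternates `levels[1]` for `dwell[1]` steps with
#'   `levels[2]` for `dwell[2]` steps, starting at step 1 (so steps
#'   `1..dwell[1]` see `levels[1]`).
#' * `"logistic"`: `DA_t = L / (1 + exp(c - r * t))`; the default
#'   parameters `L = 400, c = 4, r = 0.2` give the aperiodic ramp used
#'   in the stimulus-variation scenarios.
#' * `"explicit"`: an arbitrary non-negative series `values[t]` for
#'   `t >= 1` (`DA_0` is taken as `values[1]`).
#'
#' @param kind Schedule kind, see above.
#' @param level Constant level (kind `"constant"`).
#' @param levels,dwell Two levels and their dwell times (kind
#'   `"rotation"`).
#' @param L,c,r Logistic parameters (kind `"logistic"`).
#' @param values Explicit series (kind `"explicit"`).
#' @return An object of class `demand_schedule`; evaluate it with
#'   [demand_at()].
#' @examples
#' demand_at(demand_schedule("logistic"), 20)   # 400 / (1 + exp(0)) = 200
#' demand_at(demand_schedule("rotation", levels = c(50, 150),
#'                           dwell = c(5, 5)), 7)
#' @export
demand_schedule <- function(kind = c("constant", "rotation", "logistic",
                                     "explicit"),
                            level = 50, levels = c(50, 150), dwell = c(5, 5),
                            L = 400, c = 4, r = 0.2, values = NULL) {
  kind <- match.arg(kind)
  sched <- switch(kind,
    constant = {
      if (level < 0) stop("demand level must be non-negative")
      list(kind = kind, level = level)
    },
    rotation = {
      if (length(levels) != 2L || length(dwell) != 2L) {
        stop("rotation needs two levels and two dwell times")
      }
      if (any(levels < 0)) stop("demand levels must be non-negative")
      if (any(dwell < 1)) stop("dwell times must be >= 1")
      list(kind = kind, levels = as.numeric(levels),
           dwell = as.integer(dwell))
    },
    logistic = {
      if (L < 0) stop("logistic ceiling must be non-negative")
      list(kind = kind, L = L, c = c, r = r)
    },
    explicit = {
      values <- as.numeric(values)
      if (length(values) < 1L || anyNA(values) || any(values < 0)) {
        stop("explicit demand values must be non-negative and non-missing")
      }
      list(kind = kind, values = values)
    }
  )
  structure(sched, class = "demand_schedule")
}

#' Evaluate a demand schedule at integer times
#'
#' @param schedule A [demand_schedule()].
#' @param t Integer time index (vectorised, `t >= 0`).
#' @return Numeric vector of demands `DA_t`.
#' @export
demand_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "demand_schedule"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("time index must be non-negative")
  switch(schedule$kind,
    constant = rep(schedule$level, length(t)),
    rotation = {
      period <- sum(schedule$dwell)
      # step 1 opens the first dwell phase; t = 0 reports the same phase
      phase <- (pmax(t, 1) - 1) %% period
      ifelse(phase < schedule$dwell[1], schedule$levels[1],
             schedule$levels[2])
    },
    logistic = schedule$L / (1 + exp(schedule$c - schedule$r * t)),
    explicit = {
      idx <- pmax(as.integer(t), 1L)
      if (any(idx > length(schedule$values))) {
        stop("explicit demand series shorter than requested horizon")
      }
      schedule$values[idx]
    }
  )
}

#' @export
print.demand_schedule <- function(x, ...) {
  cat("<demand_schedule>", x$kind, "\n")
  invisible(x)
}

#' @rdname demand_schedule
#' @param ... Passed to [demand_schedule()].
#' @export
make_demand <- function(kind, ...) demand_schedule(kind, ...)
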