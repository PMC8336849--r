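#' Per-age survival and activity profile of a biomolecule unit
#'
#' An `age_profile` describes how a biomolecule (an mRNA or a protein
#' species) ages: `survival[x]` is the fraction of age-`x-1` molecules
#' that survive to age `x` (the "degradation coefficient", a survival
#' percentage), and `activity[x]` is the activity contributed per unit
#' abundance at age `x-1`.  Ages run from 0 (nascent) to `max_age`, at
#' which point any remaining molecules are fully degraded on the next
#' step.
#'
#' @param survival Numeric vector of survival fractions `d_0 ... d_{n-1}`,
#'   each in `[0, 1]`; its length fixes the maximum age `n`.
#' @param activity Numeric vector of non-negative activity coefficients
#'   `a_0 ... a_n` (length `length(survival) + 1`).  Defaults to all 1,
#'   in which case total activity equals total abundance.
#' @param label Optional profile family tag (`"A"`, `"B"`, `"C"`, `"D"`).
#' @return An object of class `age_profile` with fields `survival`,
#'   `activity`, `max_age` and `label`.
#' @seealso [make_profile()] for the named profile families.
#' @examples
#' p <- age_profile(type_b_survival(10))
#' p$max_age
#' @export
age_profile <- function(survival, activity = NULL, label = NULL) {
  survival <- as.numeric(survival)
  if (length(survival) < 1L || anyNA(survival)) {
    stop("`survival` must be a non-empty numeric vector without NA")
  }
  if (any(survival < 0 | survival > 1)) {
    stop("survival fractions must lie in [0, 1]")
  }
  n <- length(survival)
  if (is.null(activity)) activity <- rep(1, n + 1L)
  activity <- as.numeric(activity)
  if (length(activity) != n + 1L) {
    stop("`activity` must have length(survival) + 1 entries (ages 0..n)")
  }
  if (anyNA(activity) || any(activity < 0)) {
    stop("activity coefficients must be non-negative")
  }
  structure(
    list(survival = survival, activity = activity, max_age = n,
         label = label),
    class = "age_profile"
  )
}

#' @export
print.age_profile <- function(x, ...) {
  cat("<age_profile> max age", x$max_age,
      if (!is.null(x$label)) paste0("(type ", x$label, ")"), "\n")
  cat("  survival:", paste(signif(x$survival, 4), collapse = " "), "\n")
  cat("  activity:", paste(signif(x$activity, 4), collapse = " "), "\n")
  invisible(x)
}

#' Production (pulse) policy of a unit
#'
#' Production is pulse-like: when it fires, a fixed nascent amount
#' `pulse_level` appears at age 0.  In `"demand_gated"` mode a pulse
#' fires at step `t` iff the previous step's total activity is strictly
#' below the current demand; in `"unregulated_continuous"` mode a pulse
#' fires at every step regardless of demand; `"silent"` never produces.
#'
#' @param pulse_level Non-negative nascent abundance per production event.
#' @param mode One of `"demand_gated"`, `"unregulated_continuous"`,
#'   `"silent"`.
#' @param gate Gating-time convention: `"pre_aging"` (default) compares
#'   the previous step's reported total activity against the current
#'   demand; `"post_aging"` compares activity after aging but before the
#'   pulse.  The default is the convention under which the reference
#'   type-B scenarios cycle every 5 steps at demand 50.
#' @return An object of class `pulse_policy`.
#' @export
pulse_policy <- function(pulse_level,
                         mode = c("demand_gated", "unregulated_continuous",
                                  "silent"),
                         gate = c("pre_aging", "post_aging")) {
  mode <- match.arg(mode)
  gate <- match.arg(gate)
  pulse_level <- as.numeric(pulse_level)
  if (length(pulse_level) != 1L || is.na(pulse_level) || pulse_level < 0) {
    stop("`pulse_level` must be a single non-negative number")
  }
  structure(list(pulse_level = pulse_level, mode = mode, gate = gate),
            class = "pulse_policy")
}

#' @export
print.pulse_policy <- function(x, ...) {
  cat("<pulse_policy>", x$mode, "pulse", x$pulse_level, "\n")
  invisible(x)
}

#' Default type-B (decreasing) survival ladder
#'
#' The shipped type-B survival coefficients are reconstructed from the
#' per-age steady-state ladder 100, 90, 72, 50, 31, 15, 6 (successive
#' ratios 0.9, 0.8, 50/72, 31/50, 15/31, 6/15, then 0).  The ratios are
#' deliberately non-smooth: they reproduce the printed ladder exactly
#' rather than assuming round underlying values.
#'
#' @param max_age Maximum age `n` (the vector has `n` entries); ages past
#'   the ladder get survival 0.
#' @return Numeric vector of survival fractions of length `max_age`.
#' @export
type_b_survival <- function(max_age = 10L) {
  ladder <- c(100, 90, 72, 50, 31, 15, 6)
  d <- ladder[-1] / ladder[-length(ladder)]
  out <- rep(0, max_age)
  k <- min(max_age, length(d))
  out[seq_len(k)] <- d[seq_len(k)]
  out
}

#' Construct a profile coefficient sequence from a named family
#'
#' The four families describe how a coefficient changes with age:
#' type A constant, type B decreasing, type C parabolic (unimodal,
#' peaked mid-life), type D increasing.  For `applies_to = "survival"`
#' the type-B default is the reconstructed ladder of
#' [type_b_survival()]; other families interpolate linearly (or
#' parabolically for C) between `lo` and `hi`.
#'
#' @param family `"A"`, `"B"`, `"C"` or `"D"`.
#' @param applies_to `"survival"` or `"activity"`.
#' @param max_age Maximum age `n`.
#' @param lo,hi Range of the generated coefficients.  Defaults: activity
#'   in `[0, 1]`, survival in `[0, 0.9]`.
#' @return For `"survival"`, a numeric vector of length `max_age`; for
#'   `"activity"`, length `max_age + 1`.
#' @examples
#' make_profile_coefs("C", "activity", 10)
#' @export
make_profile_coefs <- function(family = c("A", "B", "C", "D"),
                               applies_to = c("survival", "activity"),
                               max_age = 10L, lo = NULL, hi = NULL) {
  family <- match.arg(family)
  applies_to <- match.arg(applies_to)
  len <- if (applies_to == "survival") max_age else max_age + 1L
  if (is.null(hi)) hi <- if (applies_to == "survival") 0.9 else 1
  if (is.null(lo)) lo <- 0
  if (applies_to == "survival" && (hi > 1 || lo < 0)) {
    stop("survival coefficients must stay within [0, 1]")
  }
  x <- seq_len(len) - 1L
  out <- switch(family,
    A = rep(hi, len),
    B = if (applies_to == "survival") {
      type_b_survival(max_age)
    } else {
      hi - (hi - lo) * x / (len - 1L)
    },
    C = {
      mid <- (len - 1L) / 2
      lo + (hi - lo) * (1 - ((x - mid) / mid)^2)
    },
    D = lo + (hi - lo) * x / (len - 1L)
  )
  out
}

#' Build an age profile from named survival/activity families
#'
#' Convenience wrapper pairing [make_profile_coefs()] calls into an
#' [age_profile()].  `make_profile("B", "A")` is the configuration used
#' throughout the one-unit scenario simulations: decreasing survival,
#' activity 1 at every age.
#'
#' @param survival_family,activity_family Family tags (`"A"`-`"D"`), or
#'   explicit numeric vectors which are passed through unchanged.
#' @param max_age Maximum age `n` (default 10, i.e. 11 ages 0-10).
#' @param ... Passed to [make_profile_coefs()] (`lo`, `hi`).
#' @return An [age_profile()].
#' @export
make_profile <- function(survival_family = "B", activity_family = "A",
                         max_age = 10L, ...) {
  surv <- if (is.character(survival_family)) {
    make_profile_coefs(survival_family, "survival", max_age, ...)
  } else as.numeric(survival_family)
  act <- if (is.character(activity_family)) {
    make_profile_coefs(activity_family, "activity", length(surv), ...)
  } else as.numeric(activity_family)
  label <- if (is.character(survival_family) && is.character(activity_family)) {
    paste0(survival_family, "/", activity_family)
  }
  age_profile(surv, act, label = label)
}
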