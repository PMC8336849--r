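#' Demand transmitted upstream from an unmet downstream demand
#'
#' When a downstream unit's total activity falls short of its demand,
#' the deficit becomes a stimulus for the upstream unit: the upstream
#' demand is `gain * max(0, downstream_demand - downstream_activity)`,
#' clamped at zero when the downstream demand is already met.
#'
#' @param downstream_demand,downstream_activity Non-negative reals.
#' @param gain Non-negative scaling of the deficit (default 1, raw
#'   passthrough).
#' @return The derived upstream demand.
#' @examples
#' derive_upstream_demand(100, 40)    # 60
#' derive_upstream_demand(100, 120)   # 0
#' @export
derive_upstream_demand <- function(downstream_demand, downstream_activity,
                                   gain = 1) {
  if (any(c(downstream_demand, downstream_activity, gain) < 0)) {
    stop("inputs must be non-negative")
  }
  gain * pmax(0, downstream_demand - downstream_activity)
}

#' Chain of demand-coupled units
#'
#' Units are ordered upstream to downstream (for the RNA/protein model:
#' RNA first, protein second).  The external demand schedule applies to
#' the most downstream unit; every other unit's demand at step `t` is
#' the downstream neighbour's deficit (its demand minus its previous
#' total activity, clamped at 0) scaled by the link gain.  Units other
#' than the most upstream one require their upstream neighbour's
#' previous total activity to be positive before a pulse can fire
#' (production needs a template).
#'
#' @param units List of units, each a list with elements `profile`
#'   (an [age_profile()]) and `policy` (a [pulse_policy()]); optional
#'   `name` and `initial` (an abundance-by-age vector; default empty).
#' @param demand External [demand_schedule()] for the last unit.
#' @param gains Numeric vector of link gains, one per adjacent pair
#'   (length `length(units) - 1`); default all 1.
#' @return Class `chain_spec`.
#' @export
chain_spec <- function(units, demand, gains = NULL) {
  if (length(units) < 1L) stop("at least one unit is required")
  for (u in units) {
    stopifnot(inherits(u$profile, "age_profile"),
              inherits(u$policy, "pulse_policy"))
  }
  if (is.numeric(demand) && length(demand) == 1L) {
    demand <- demand_schedule("constant", level = demand)
  }
  stopifnot(inherits(demand, "demand_schedule"))
  if (is.null(gains)) gains <- rep(1, max(0L, length(units) - 1L))
  if (length(gains) != length(units) - 1L) {
    stop("`gains` must have one entry per link")
  }
  if (any(gains < 0)) stop("gains must be non-negative")
  structure(list(units = units, demand = demand, gains = gains),
            class = "chain_spec")
}

#' Simulate a chain of demand-coupled units
#'
#' At each step the demands are propagated from the most downstream
#' unit upstream (all from the previous step's total activities), then
#' every unit advances one step.  A chain of length 1 reduces exactly to
#' [simulate_unit()]; a chain of length 2 is the RNA/protein two-unit
#' model.
#'
#' @param spec A [chain_spec()].
#' @param horizon Number of steps (`>= 1`).
#' @return List of trajectories, one per unit (upstream first), each as
#'   returned by [simulate_unit()], with the unit's derived demand in
#'   its `DA` column.  Class `chain_trajectories`.
#' @export
simulate_chain <- function(spec, horizon) {
  stopifnot(inherits(spec, "chain_spec"))
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("`horizon` must be >= 1")
  K <- length(spec$units)
  profs <- lapply(spec$units, `[[`, "profile")
  pols <- lapply(spec$units, `[[`, "policy")
  states <- lapply(spec$units, function(u) {
    unit_state(u$profile, u$initial)
  })

  rec <- lapply(seq_len(K), function(k) {
    n1 <- profs[[k]]$max_age + 1L
    list(ages = matrix(0, horizon + 1L, n1,
                       dimnames = list(NULL, paste0("age_", 0:(n1 - 1L)))),
         tb = numeric(horizon + 1L), ta = numeric(horizon + 1L),
         da = numeric(horizon + 1L), produced = numeric(horizon + 1L),
         degraded = numeric(horizon + 1L))
  })
  da0 <- numeric(K)
  da0[K] <- demand_at(spec$demand, 0)
  if (K > 1L) {
    for (k in (K - 1L):1L) {
      da0[k] <- derive_upstream_demand(da0[k + 1L], states[[k + 1L]]$ta,
                                       spec$gains[k])
    }
  }
  for (k in seq_len(K)) {
    rec[[k]]$ages[1L, ] <- states[[k]]$abundance
    rec[[k]]$tb[1L] <- states[[k]]$tb
    rec[[k]]$ta[1L] <- states[[k]]$ta
    rec[[k]]$da[1L] <- da0[k]
  }

  for (t in seq_len(horizon)) {
    prev_ta <- vapply(states, `[[`, numeric(1), "ta")
    # demand propagation, downstream to upstream, all from prev activities
    da <- numeric(K)
    da[K] <- demand_at(spec$demand, t)
    if (K > 1L) {
      for (k in (K - 1L):1L) {
        da[k] <- derive_upstream_demand(da[k + 1L], prev_ta[k + 1L],
                                        spec$gains[k])
      }
    }
    for (k in seq_len(K)) {
      pol <- pols[[k]]
      # downstream units need an upstream template to produce
      if (k > 1L && pol$mode != "silent" && prev_ta[k - 1L] <= 0) {
        pol <- pulse_policy(pol$pulse_level, "silent")
      }
      res <- step_unit(states[[k]], profs[[k]], pol, da[k])
      states[[k]] <- res$state
      i <- t + 1L
      rec[[k]]$ages[i, ] <- res$state$abundance
      rec[[k]]$tb[i] <- res$state$tb
      rec[[k]]$ta[i] <- res$state$ta
      rec[[k]]$da[i] <- da[k]
      rec[[k]]$produced[i] <- res$produced
      rec[[k]]$degraded[i] <- res$degraded
    }
  }

  out <- lapply(seq_len(K), function(k) {
    r <- rec[[k]]
    traj <- data.frame(time = 0:horizon, TB = r$tb, TA = r$ta, DA = r$da,
                       produced = r$produced, degraded = r$degraded,
                       acc_production = cumsum(r$produced),
                       acc_degradation = cumsum(r$degraded))
    structure(traj, ages = r$ages, profile = profs[[k]],
              policy = pols[[k]],
              schedule = if (k == K) spec$demand else NULL,
              step_length = 1,
              class = c("trajectory", "data.frame"))
  })
  names(out) <- vapply(seq_len(K), function(k) {
    spec$units[[k]]$name %||% paste0("unit_", k)
  }, character(1))
  structure(out, spec = spec, class = "chain_trajectories")
}

#' Two-unit RNA/protein model
#'
#' The downstream (protein) unit is driven by the demand for protein
#' activity; its unmet deficit, scaled by `gain`, becomes the demand for
#' RNA activity that gates transcription.  Protein pulses additionally
#' require RNA to be present (positive total RNA activity on the
#' previous step); the pulse magnitude is the constant nascent amount
#' per step.
#'
#' @param dpa A [demand_schedule()] (or constant) for protein activity.
#' @param rna_profile,protein_profile [age_profile()]s; default
#'   type-B survival with type-A activity for both.
#' @param rna_pulse,protein_pulse Nascent amounts per production event
#'   (defaults 100 and 48).
#' @param gain Coupling gain turning the protein deficit into RNA
#'   demand (default 1).
#' @return A `chain_spec` of length 2 (units named `rna`, `protein`).
#' @export
coupled_model <- function(dpa, rna_profile = make_profile("B", "A"),
                          protein_profile = make_profile("B", "A"),
                          rna_pulse = 100, protein_pulse = 48, gain = 1) {
  chain_spec(
    units = list(
      list(profile = rna_profile, policy = pulse_policy(rna_pulse),
           name = "rna"),
      list(profile = protein_profile, policy = pulse_policy(protein_pulse),
           name = "protein")
    ),
    demand = dpa, gains = gain
  )
}

#' @rdname coupled_model
#' @param model A `chain_spec` from [coupled_model()].
#' @param horizon Number of steps.
#' @return For `simulate_coupled()`: list with trajectories `rna` and
#'   `protein`.
#' @export
simulate_coupled <- function(model, horizon) {
  stopifnot(inherits(model, "chain_spec"), length(model$units) == 2L)
  simulate_chain(model, horizon)
}

#' Joint cycle analysis of coupled trajectories
#'
#' Exact recurrence detection on the joint state (all units' age
#' vectors, plus the external schedule phase when it is periodic),
#' with per-unit regime classification: a unit is a `fixed_point` if
#' its own state is constant over the joint steady orbit, otherwise
#' `periodic` with the smallest divisor of the joint period at which
#' its state repeats.
#'
#' @param chains A `chain_trajectories` from [simulate_chain()].
#' @param tol Quantisation tolerance.
#' @return List with `joint` (a `cycle_report`) and `units` (data.frame
#'   of per-unit `regime`, `period`, `amplitude`).
#' @export
classify_regimes <- function(chains, tol = 1e-9) {
  stopifnot(inherits(chains, "chain_trajectories"))
  spec <- attr(chains, "spec")
  joint_ages <- do.call(cbind, lapply(chains, trajectory_ages))
  jtb <- rowSums(joint_ages)
  joint <- structure(
    data.frame(time = chains[[1L]]$time, TB = jtb, TA = jtb),
    ages = joint_ages, schedule = spec$demand, step_length = 1,
    class = c("trajectory", "data.frame"))
  rep_joint <- detect_cycles(joint, tol = tol)
  units <- data.frame(unit = names(chains), regime = NA_character_,
                      period = NA_integer_, amplitude = NA_real_)
  if (rep_joint$regime %in% c("periodic", "fixed_point")) {
    s <- rep_joint$transient + 1L
    P <- if (rep_joint$regime == "fixed_point") 1L else rep_joint$period
    for (k in seq_along(chains)) {
      A <- trajectory_ages(chains[[k]])
      orbit <- A[s:(s + P - 1L), , drop = FALSE]
      divs <- Filter(function(p) P %% p == 0L, seq_len(P))
      per <- P
      for (p in divs) {
        shifted <- orbit[((seq_len(P) - 1L + p) %% P) + 1L, , drop = FALSE]
        if (max(abs(orbit - shifted)) <= tol) { per <- p; break }
      }
      tb <- chains[[k]]$TB[s:(s + P - 1L)]
      amp <- max(tb) - min(tb)
      units$regime[k] <- if (per == 1L) "fixed_point" else "periodic"
      units$period[k] <- if (per == 1L) NA_integer_ else per
      units$amplitude[k] <- if (per == 1L) 0 else amp
    }
  }
  list(joint = rep_joint, units = units)
}

#' Production-rate and abundance ratios of a coupled pair
#'
#' Summarises the relationship between the downstream (translation) and
#' upstream (transcription) production rates: per-step rates, trailing
#' windowed mean rates, their ratio, and the abundance ratio
#' `TPro / TR` with explicit flagging of the unbounded case `TR = 0`.
#'
#' @param rna_traj,protein_traj Equal-length trajectories.
#' @param window Trailing window (steps) for mean rates (default 5).
#' @return List with `per_step` (data.frame of `time`,
#'   `transcription_rate`, `translation_rate`, `rate_ratio`,
#'   `abundance_ratio`), `windowed` (same on trailing means), and
#'   `summary` (`peak_transcription_rate`, `peak_translation_rate`,
#'   `rate_ratio_range`, `transcription_rate_range`,
#'   `abundance_ratio_unbounded`).
#' @export
rate_ratio_summary <- function(rna_traj, protein_traj, window = 5L) {
  stopifnot(inherits(rna_traj, "trajectory"),
            inherits(protein_traj, "trajectory"))
  if (nrow(rna_traj) != nrow(protein_traj)) {
    stop("trajectories must have equal length")
  }
  tr_rate <- rna_traj$produced[-1L]
  tl_rate <- protein_traj$produced[-1L]
  time <- rna_traj$time[-1L]
  abundance_ratio <- ifelse(rna_traj$TB[-1L] > 0,
                            protein_traj$TB[-1L] / rna_traj$TB[-1L],
                            ifelse(protein_traj$TB[-1L] > 0, Inf, NaN))
  per_step <- data.frame(
    time = time, transcription_rate = tr_rate, translation_rate = tl_rate,
    rate_ratio = ifelse(tr_rate > 0, tl_rate / tr_rate, NA_real_),
    abundance_ratio = abundance_ratio)

  roll <- function(x) {
    as.numeric(stats::filter(x, rep(1, window), sides = 1)) / window
  }
  wtr <- roll(tr_rate)
  wtl <- roll(tl_rate)
  windowed <- data.frame(
    time = time, transcription_rate = wtr, translation_rate = wtl,
    rate_ratio = ifelse(!is.na(wtr) & wtr > 0, wtl / wtr, NA_real_))

  fin <- windowed$rate_ratio[is.finite(windowed$rate_ratio)]
  wtr_pos <- wtr[!is.na(wtr) & wtr > 0]
  list(per_step = per_step, windowed = windowed, window = window,
       summary = list(
         peak_transcription_rate = max(wtr, na.rm = TRUE),
         peak_translation_rate = max(wtl, na.rm = TRUE),
         rate_ratio_range = if (length(fin)) range(fin) else c(NA, NA),
         transcription_rate_range =
           if (length(wtr_pos)) range(wtr_pos) else c(NA, NA),
         abundance_ratio_unbounded = any(is.infinite(abundance_ratio))
       ))
}
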