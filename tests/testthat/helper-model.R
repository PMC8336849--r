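# Shared generators and independent oracles for the test suite.

random_profile <- function(max_age = sample(2:10, 1)) {
  age_profile(stats::runif(max_age),
              activity = stats::runif(max_age + 1, 0, 2))
}

random_schedule <- function() {
  switch(sample(c("constant", "rotation", "logistic"), 1),
    constant = demand_schedule("constant", level = stats::runif(1, 0, 300)),
    rotation = demand_schedule("rotation",
                               levels = stats::runif(2, 0, 300),
                               dwell = sample(1:10, 2, replace = TRUE)),
    logistic = demand_schedule("logistic", L = stats::runif(1, 0, 400))
  )
}

# Independent matrix formulation of the aging recursion: survival as a
# subdiagonal projection matrix applied to the age vector, plus pulse
# injection at age 0.
leslie_matrix <- function(profile) {
  n1 <- profile$max_age + 1L
  L <- matrix(0, n1, n1)
  L[cbind(2:n1, 1:(n1 - 1L))] <- profile$survival
  L
}

matrix_simulate_tb <- function(profile, policy, schedule, horizon) {
  L <- leslie_matrix(profile)
  b <- rep(0, profile$max_age + 1L)
  tb <- numeric(horizon)
  ta_prev <- 0
  for (t in seq_len(horizon)) {
    b <- as.numeric(L %*% b)
    dem <- demand_at(schedule, t)
    fire <- switch(policy$mode,
                   demand_gated = ta_prev < dem,
                   unregulated_continuous = TRUE,
                   silent = FALSE)
    if (fire) b[1] <- b[1] + policy$pulse_level
    tb[t] <- sum(b)
    ta_prev <- sum(b * profile$activity)
  }
  tb
}

# Per-age steady ladder implied by the default type-B survival profile.
type_b_ladder <- c(100, 90, 72, 50, 31, 15, 6)

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
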