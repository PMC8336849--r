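test_that("exact recurrence detection recovers known periods", {
  p <- make_profile("B", "A")
  r50 <- detect_cycles(simulate_unit(p, pulse_policy(100), 50, 60))
  expect_equal(r50$regime, "periodic")
  expect_equal(r50$period, 5)

  r80 <- detect_cycles(simulate_unit(p, pulse_policy(100), 80, 120))
  expect_equal(r80$period, 7)

  fp <- detect_cycles(simulate_unit(p, pulse_policy(100), 400, 60))
  expect_equal(fp$regime, "fixed_point")
  expect_true(is.na(fp$period))
  expect_equal(fp$amplitude, 0)
  expect_equal(fp$value, 364)
})

test_that("a too-short horizon is reported inconclusive, not guessed", {
  p <- make_profile("B", "A")
  short <- simulate_unit(p, pulse_policy(100), 50, 4)
  rep_c <- detect_cycles(short)
  expect_false(rep_c$conclusive)
  expect_equal(rep_c$regime, "aperiodic_within_horizon")
})

test_that("logistic forcing is classified only via a terminal fixed point", {
  p <- make_profile("B", "A")
  traj <- simulate_unit(p, pulse_policy(100), demand_schedule("logistic"),
                        150)
  rep_c <- detect_cycles(traj)
  # demand saturates at 400 (unattainable), so the level stabilises
  expect_equal(rep_c$regime, "fixed_point")
  expect_equal(rep_c$value, 364)
})

test_that("resampling decimates exactly and records metadata", {
  p <- make_profile("B", "A")
  traj <- simulate_unit(p, pulse_policy(100), 50, 60)
  s <- resample_trajectory(traj, 1)
  expect_equal(s$levels, traj$TB)
  expect_error(resample_trajectory(traj, 100), "exceeds")
})

test_that("sampling a period-p orbit at interval p aliases to a constant", {
  p <- make_profile("B", "A")
  traj <- simulate_unit(p, pulse_policy(100), 50, 120)
  period <- detect_cycles(traj)$period
  for (offset in 3:(3 + period - 1)) {   # past the transient, any phase
    s <- resample_trajectory(traj, period, offset)
    expect_equal(length(unique(s$levels)), 1L)
  }
})

test_that("coprime sampling intervals preserve the period (aliased scan)", {
  p <- make_profile("B", "A")
  traj <- simulate_unit(p, pulse_policy(100), 50, 400)
  period <- detect_cycles(traj)$period   # 5
  scan_period <- function(v) {
    for (q in seq_len(length(v) %/% 2)) {
      n <- length(v) - q
      if (all(v[seq_len(n)] == v[seq_len(n) + q])) return(q)
    }
    NA_integer_
  }
  for (k in c(2, 3, 4, 6, 7)) {          # intervals coprime with 5
    s <- resample_trajectory(traj, k, offset = 10)
    q <- scan_period(s$levels)
    expected <- period / gcd_int(period, k)
    expect_equal(q, expected)
  }
})

test_that("rotating demand yields global cycles with phase sub-cycles", {
  p <- make_profile("B", "A")
  fast <- simulate_unit(p, pulse_policy(100),
                        demand_schedule("rotation", levels = c(50, 150),
                                        dwell = c(5, 5)), 300)
  expect_equal(detect_cycles(fast)$period, 30)

  slow <- simulate_unit(p, pulse_policy(100),
                        demand_schedule("rotation", levels = c(50, 150),
                                        dwell = c(25, 25)), 500)
  rep_c <- detect_cycles(slow)
  expect_equal(rep_c$global_period, 50)
  expect_equal(rep_c$sub_cycles$period[rep_c$sub_cycles$level == 50], 5)
  expect_equal(rep_c$sub_cycles$period[rep_c$sub_cycles$level == 150], 7)
})

test_that("trajectory comparison reports signed differences", {
  p <- make_profile("B", "A")
  a <- simulate_unit(p, pulse_policy(100), 80, 100)
  b <- simulate_unit(p, pulse_policy(100), 50, 100)

  same <- compare_demand_levels(a, a)
  expect_true(all(same$differences$diff == 0))
  expect_equal(same$frac_equal, 1)
  expect_false(same$sign_changes)

  cmp <- compare_demand_levels(a, b)
  expect_equal(cmp$differences$diff, a$TB - b$TB)  # subtraction oracle
  # the higher-demand run is sometimes above, sometimes below
  expect_true(cmp$sign_changes)
  expect_gt(cmp$frac_a_higher, 0)
  expect_gt(cmp$frac_b_higher, 0)
})
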