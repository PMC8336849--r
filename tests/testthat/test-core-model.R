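test_that("a single step ages cohorts, gates pulses on prior activity", {
  p <- make_profile("B", "A")
  pol <- pulse_policy(100)

  # empty state: zero activity is below any positive demand, pulse fires
  res <- step_unit(unit_state(p), p, pol, 50)
  expect_equal(res$produced, 100)
  expect_equal(res$state$tb, 100)
  expect_equal(res$state$ta, 100)

  # prior activity 100 >= demand 50: no pulse, cohort ages with d_0 = 0.9
  s1 <- unit_state(p, c(100, rep(0, p$max_age)))
  res2 <- step_unit(s1, p, pol, 50)
  expect_equal(res2$produced, 0)
  expect_equal(res2$state$tb, 90)
  expect_equal(res2$degraded, 10)

  # activity exactly equal to demand does not trigger (strict inequality)
  res3 <- step_unit(s1, p, pol, 100)
  expect_equal(res3$produced, 0)

  # lossless accumulation: all survival 1, unregulated pulses
  lossless <- age_profile(rep(1, 10))
  st <- unit_state(lossless)
  for (k in 1:5) {
    st <- step_unit(st, lossless, pulse_policy(100, "unregulated_continuous"),
                    0)$state
  }
  expect_equal(st$tb, 500)

  expect_error(step_unit(s1, p, pol, -1), "non-negative")
  expect_error(unit_state(p, c(-1, rep(0, p$max_age))), "non-negative")
})

test_that("unattainable demand fills the type-B steady-state ladder", {
  traj <- simulate_unit(make_profile("B", "A"), pulse_policy(100), 400, 60)
  expect_equal(tail(traj$TB, 1), 364)
  ages <- trajectory_ages(traj)[61, ]
  expect_equal(unname(ages[1:7]), type_b_ladder)
  expect_equal(unname(ages[8:11]), rep(0, 4))
})

test_that("constant demand 50 drives production every 5 steps", {
  traj <- simulate_unit(make_profile("B", "A"), pulse_policy(100), 50, 60)
  fired <- which(traj$produced > 0) - 1L  # time indices
  expect_equal(diff(fired), rep(5, length(fired) - 1L))
  expect_equal(sort(unique(traj$TB[20:60])), c(31, 50, 72, 96, 115))
})

test_that("mass is conserved and accumulators reconcile", {
  set.seed(42)
  for (rep_i in 1:25) {
    p <- random_profile()
    traj <- simulate_unit(p, pulse_policy(stats::runif(1, 0, 200)),
                          random_schedule(), 50)
    dtb <- diff(traj$TB)
    flux <- traj$produced[-1] - traj$degraded[-1]
    expect_equal(dtb, flux, tolerance = 1e-9)
    expect_equal(tail(traj$TB, 1) - traj$TB[1],
                 tail(traj$acc_production, 1) - tail(traj$acc_degradation, 1),
                 tolerance = 1e-9)
    expect_true(all(diff(traj$acc_production) >= 0))
    expect_true(all(diff(traj$acc_degradation) >= 0))
  }
})

test_that("steady_state_abundance is the continuous-pulsing fixed point", {
  expect_equal(steady_state_abundance(age_profile(rep(1, 10)), 100), 1100)
  expect_equal(steady_state_abundance(make_profile("B", "A"), 100), 364)
  expect_equal(steady_state_abundance(make_profile("B", "A"), 0), 0)
})

test_that("unregulated growth is monotone and converges to the fixed point", {
  set.seed(7)
  for (rep_i in 1:10) {
    p <- random_profile()
    pol <- pulse_policy(stats::runif(1, 1, 100), "unregulated_continuous")
    traj <- simulate_unit(p, pol, 0, 80)
    ss <- steady_state_abundance(p, pol$pulse_level)
    expect_true(all(diff(traj$TB) >= -1e-9))
    expect_true(all(traj$TB <= ss + 1e-9))
    expect_equal(tail(traj$TB, 1), ss, tolerance = 1e-6)
  }
})

test_that("with type-A activity total activity equals total abundance", {
  p <- make_profile("B", "A")
  traj <- simulate_unit(p, pulse_policy(100), 80, 100)
  expect_identical(traj$TA, traj$TB)
})

test_that("constant-demand runs settle into a fixed point or exact orbit", {
  set.seed(11)
  for (rep_i in 1:10) {
    p <- random_profile(6)
    traj <- simulate_unit(p, pulse_policy(100),
                          stats::runif(1, 10, 300), 400)
    rep_c <- detect_cycles(traj)
    expect_true(rep_c$regime %in% c("fixed_point", "periodic"))
    expect_true(rep_c$conclusive)
  }
})

test_that("post-aging gating is available and shortens the cycle", {
  p <- make_profile("B", "A")
  traj <- simulate_unit(p, pulse_policy(100, gate = "post_aging"), 50, 60)
  rep_c <- detect_cycles(traj)
  expect_equal(rep_c$period, 4)
})
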