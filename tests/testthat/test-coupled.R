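test_that("upstream demand is the clamped, scaled downstream deficit", {
  expect_equal(derive_upstream_demand(100, 100, 1), 0)
  expect_equal(derive_upstream_demand(100, 40, 1), 60)
  expect_equal(derive_upstream_demand(100, 120, 2), 0)
  expect_equal(derive_upstream_demand(100, 40, 0.5), 30)
  expect_error(derive_upstream_demand(-1, 0, 1), "non-negative")
})

test_that("a 1-unit chain reproduces the core simulator bit-for-bit", {
  p <- make_profile("B", "A")
  sched <- demand_schedule("rotation", levels = c(50, 150), dwell = c(5, 5))
  ch <- simulate_chain(
    chain_spec(list(list(profile = p, policy = pulse_policy(100))), sched),
    120)
  ref <- simulate_unit(p, pulse_policy(100), sched, 120)
  expect_identical(as.data.frame(ch[[1]]), as.data.frame(ref))
  expect_identical(trajectory_ages(ch[[1]]), trajectory_ages(ref))
})

test_that("a 2-unit chain is the RNA/protein two-unit model", {
  m <- coupled_model(100)
  direct <- simulate_coupled(m, 150)
  chain <- simulate_chain(m, 150)
  expect_identical(as.data.frame(direct$rna), as.data.frame(chain[[1]]))
  expect_identical(as.data.frame(direct$protein), as.data.frame(chain[[2]]))
})

test_that("both coupled trajectories conserve mass", {
  ch <- simulate_coupled(coupled_model(175), 200)
  for (traj in ch) {
    expect_equal(diff(traj$TB), traj$produced[-1] - traj$degraded[-1],
                 tolerance = 1e-9)
  }
})

test_that("zero coupling gain silences the RNA unit", {
  p <- make_profile("B", "A")
  m <- chain_spec(
    units = list(
      list(profile = p, policy = pulse_policy(100), name = "rna"),
      list(profile = p, policy = pulse_policy(48), name = "protein",
           initial = c(200, rep(0, p$max_age)))),
    demand = 500, gains = 0)
  ch <- simulate_chain(m, 60)
  expect_true(all(ch$rna$produced == 0))
  expect_true(all(ch$rna$TB == 0))
  # the protein unit's initial stock decays to extinction: no RNA
  # template ever exists, so no translation can replace it
  expect_true(all(ch$protein$produced == 0))
  expect_equal(tail(ch$protein$TB, 1), 0)
  expect_true(all(diff(ch$protein$TB) <= 1e-12))
})

test_that("a silent middle unit starves downstream and saturates upstream", {
  p <- age_profile(c(0.5, 0.5, 0))   # short-lived, 4 ages
  spec <- chain_spec(
    units = list(
      list(profile = p, policy = pulse_policy(10)),
      list(profile = p, policy = pulse_policy(0)),   # silent middle
      list(profile = p, policy = pulse_policy(10))),
    demand = 100, gains = c(1, 1))
  ch <- simulate_chain(spec, 10)

  # independent hand-stepped oracle for the top unit: with the middle
  # and bottom units stuck at zero activity, the unmet demand of 100 is
  # passed through both links unchanged, so the top unit pulses every
  # step once its own activity stays below 100 (which it always is:
  # steady state 10 * (1 + .5 + .25) = 17.5 < 100)
  b <- rep(0, 4); tb_oracle <- numeric(10)
  for (t in 1:10) {
    b <- c(0, b[1:3] * c(0.5, 0.5, 0))
    b[1] <- 10
    tb_oracle[t] <- sum(b)
  }
  expect_equal(ch[[1]]$TB[-1], tb_oracle)
  expect_true(all(ch[[1]]$produced[-1] == 10))
  expect_true(all(ch[[2]]$TB == 0))
  expect_true(all(ch[[3]]$produced == 0))   # no template from unit 2
  expect_true(all(ch[[3]]$DA[-1] == 100))   # deficit persists
})

test_that("rate ratios report constant-rate and unbounded cases", {
  # constant rates: protein 48/step vs RNA 100/step -> ratio 0.48
  ch <- simulate_coupled(coupled_model(600), 120)
  rs <- rate_ratio_summary(ch$rna, ch$protein)
  steady <- rs$per_step$time > 20
  expect_true(all(rs$per_step$rate_ratio[steady] == 0.48))
  expect_equal(rs$windowed$rate_ratio[steady],
               rep(0.48, sum(steady)))

  # TR = 0 while TPro > 0 is flagged unbounded
  p <- make_profile("B", "A")
  silent_rna <- chain_spec(
    units = list(
      list(profile = p, policy = pulse_policy(0), name = "rna"),
      list(profile = p, policy = pulse_policy(48), name = "protein",
           initial = c(100, rep(0, p$max_age)))),
    demand = 500, gains = 1)
  ch2 <- simulate_chain(silent_rna, 5)
  rs2 <- rate_ratio_summary(ch2$rna, ch2$protein)
  expect_true(rs2$summary$abundance_ratio_unbounded)
  expect_true(any(is.infinite(rs2$per_step$abundance_ratio)))
})

test_that("regime classification separates attainable and unattainable demand", {
  high <- classify_regimes(simulate_coupled(coupled_model(600), 200))
  expect_equal(high$units$regime, c("fixed_point", "fixed_point"))
  low <- classify_regimes(simulate_coupled(coupled_model(25), 300))
  expect_equal(low$units$regime, c("periodic", "periodic"))
})
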