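# Feed planner: rate targets, enzyme dosing, closed-loop tracking.

test_that("target rate is the difference quotient", {
  expect_equal(target_rate(2, 3, 0.5), 2)
  expect_equal(target_rate(2, 2, 0.5), 0)
  expect_lt(target_rate(3, 2, 0.5), 0)  # caller clamps: release irreversible
})

test_that("exponential profile follows the fed-batch feed law", {
  sched <- setpoint_schedule(data.frame(start_h = 0, mu_set = 0.2),
                             horizon = 6)
  r <- target_release_profile(3, sched, Y_XS = 0.5)
  expect_equal(r(0), 0.2 / 0.5 * 3)
  expect_equal(r(0), 1.2)
  expect_equal(r(2), 1.2 * exp(0.2 * 2), tolerance = 1e-12)
  # doubling the yield halves the rate everywhere
  r2 <- target_release_profile(3, sched, Y_XS = 1.0)
  expect_equal(r2(c(0, 1, 3)), r(c(0, 1, 3)) / 2, tolerance = 1e-12)
  # mu = 0 gives a zero rate
  sched0 <- setpoint_schedule(data.frame(start_h = 0, mu_set = 0), horizon = 6)
  expect_equal(target_release_profile(3, sched0)(c(0, 3)), c(0, 0))
  # phases chain continuously through the carried biomass
  sched2 <- setpoint_schedule(data.frame(start_h = c(0, 6),
                                         mu_set = c(0.2, 0.1)), horizon = 10)
  rr <- target_release_profile(3, sched2, Y_XS = 0.5)
  X6 <- 3 * exp(0.2 * 6)
  expect_equal(rr(6), 0.1 / 0.5 * X6, tolerance = 1e-12)
})

test_that("enzyme addition inverts the rate law and clamps at zero", {
  p <- ref_params()
  s <- release_state(S = 40, WS = 0.464, E = 0, V = 0.010)
  # independent hand evaluation
  SS <- 0.464 * 40; SR <- 0.536 * 40
  expect_equal(enzyme_addition(s, p, 1),
               (1 - 0) * (40 + 0.001) / (1.111 * (0.134 * SS + 0.00212 * SR)),
               tolerance = 1e-12)
  expect_equal(enzyme_addition(s, p, 1), 14.22, tolerance = 1e-3)
  # adding that much enzyme realizes the target rate exactly
  s2 <- release_state(S = 40, WS = 0.464, E = enzyme_addition(s, p, 1),
                      V = 0.010)
  expect_equal(p$nu * sum(release_rates(s2, p)), 1, tolerance = 1e-9)
  # current rate above target: no addition
  s_hot <- release_state(S = 40, WS = 0.464, E = 100, V = 0.010)
  expect_identical(enzyme_addition(s_hot, p, 0.1), 0)
  # no substrate: infeasible
  s0 <- release_state(S = 0, WS = 0.464, E = 0, V = 0.010)
  expect_error(enzyme_addition(s0, p, 1), "infeasible")
})

test_that("stock volume reproduces the target concentration exactly", {
  p <- ref_params()
  s <- release_state(S = 40, WS = 0.464, E = 0, V = 0.010)
  E_add <- enzyme_addition(s, p, 1)
  v <- stock_volume(s, E_add)
  expect_equal(v, 4.76e-5, tolerance = 1e-3)
  s2 <- apply_bolus(s, bolus_event(0, "enzyme", v, stock = 3000))
  expect_equal(s2$E, E_add, tolerance = 1e-10)
  expect_identical(stock_volume(s, 0), 0)
  expect_error(stock_volume(s, 3000), "unreachable")
})

test_that("constant-rate plans track the target within 2 % in regime", {
  p <- ref_params()
  d <- experiment_design(release_state(S = 40, WS = 0.464, E = 0, V = 0.010),
                         horizon = 8)
  sched <- setpoint_schedule(data.frame(start_h = 0, mu_set = 0), horizon = 6)
  plan <- plan_feed(d, p, sched, profile = function(t) rep(1, length(t)))
  rr <- realized_rates(plan)
  expect_true(all(rr$guard < 0.01))
  expect_lt(max(abs(rr$r_realized / rr$r_target - 1)), 0.02)
  # errors do not accumulate: each interval restarts from the exactly
  # integrated state, so the cumulative relative error never exceeds the
  # worst single-interval relative error
  cum_rel <- abs(sum(rr$r_realized) / sum(rr$r_target) - 1)
  worst_rel <- max(abs(rr$r_realized / rr$r_target - 1))
  expect_lte(cum_rel, worst_rel + 1e-12)
})

test_that("zero setpoint means no enzyme is ever added", {
  p <- ref_params()
  d <- experiment_design(release_state(S = 40, WS = 0.464, E = 0, V = 0.010),
                         horizon = 8)
  sched <- setpoint_schedule(data.frame(start_h = 0, mu_set = 0), horizon = 4)
  plan <- plan_feed(d, p, sched,
                    profile = target_release_profile(3, sched))
  expect_true(all(plan$plan$E_add_UL == 0))
  expect_true(all(plan$plan$enzyme_uL == 0))
})

test_that("exponential two-phase plans are well-formed and reproducible", {
  p <- ref_params()
  d <- experiment_design(release_state(S = 40, WS = 0.464, E = 0, V = 0.010),
                         horizon = 12)
  sched <- setpoint_schedule(data.frame(start_h = c(0, 6),
                                        mu_set = c(0.21, 0.11)),
                             horizon = 10, induction_h = 6)
  prof <- target_release_profile(3, sched, Y_XS = 0.5)
  plan <- plan_feed(d, p, sched, profile = prof)
  expect_true(all(plan$plan$E_add_UL >= 0))
  expect_true(all(plan$plan$dextrin_uL == 40))          # every 10 min
  expect_equal(nrow(plan$plan), 60)                     # 10 h on a 10-min grid
  plan2 <- plan_feed(d, p, sched, profile = prof)
  expect_identical(plan$plan, plan2$plan)               # bit-for-bit
})

test_that("the planner signals substrate exhaustion as infeasible", {
  p <- ref_params()
  d <- experiment_design(release_state(S = 0.5, WS = 1, E = 0, V = 0.010),
                         horizon = 8)
  sched <- setpoint_schedule(data.frame(start_h = 0, mu_set = 0), horizon = 6)
  expect_error(
    plan_feed(d, p, sched, profile = function(t) rep(5, length(t)),
              dextrin_volume = 0),
    "infeasible")
})

test_that("shooting refinement stays close to the closed form in regime", {
  p <- ref_params()
  d <- experiment_design(release_state(S = 40, WS = 0.464, E = 0, V = 0.010),
                         horizon = 3)
  sched <- setpoint_schedule(data.frame(start_h = 0, mu_set = 0), horizon = 1)
  plan_cf <- plan_feed(d, p, sched, profile = function(t) rep(1, length(t)))
  plan_sh <- plan_feed(d, p, sched, profile = function(t) rep(1, length(t)),
                       shooting = TRUE)
  rr <- realized_rates(plan_sh)
  expect_lt(max(abs(rr$r_realized / rr$r_target - 1)), 0.02)
  expect_equal(plan_sh$plan$E_add_UL, plan_cf$plan$E_add_UL, tolerance = 0.1)
})

test_that("cumulating a feed plan conserves the pipetted volumes", {
  p <- ref_params()
  d <- experiment_design(release_state(S = 40, WS = 0.464, E = 0, V = 0.010),
                         horizon = 4)
  sched <- setpoint_schedule(data.frame(start_h = 0, mu_set = 0), horizon = 2)
  plan <- plan_feed(d, p, sched, profile = function(t) rep(0.8, length(t)))
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- write_feed_plan(plan, path, cumulate = 0.5)
  expect_lt(nrow(tab), nrow(plan$plan))
  expect_equal(sum(tab$enzyme_uL), sum(plan$plan$enzyme_uL))
  expect_equal(sum(tab$dextrin_uL), sum(plan$plan$dextrin_uL))
})
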