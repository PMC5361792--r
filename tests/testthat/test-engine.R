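test_that("all-zero rates give a constant trajectory equal to the initial state", {
  spec <- scenario_spec(
    name = "frozen", model = "extended",
    params = model_params(r_N = 0, r_T = 0, r_R = 0, r_M = 0, kappa = 0),
    initial_state = population_state(N = 5, T = 3, T_R = 2, T_M = 1),
    horizon = 10
  )
  traj <- integrate_scenario(spec)
  expect_equal(nrow(traj), 21L)
  expect_true(all(abs(traj$N - 5) < 1e-10))
  expect_true(all(abs(traj$T - 3) < 1e-10))
  expect_true(all(abs(traj$T_R - 2) < 1e-10))
  expect_true(all(abs(traj$T_M - 1) < 1e-10))
})

test_that("a single logistic population matches the closed form to 1e-6 relative", {
  spec <- logistic_spec(T0 = 1e4, r = 0.25, K = 1e6, horizon = 200)
  traj <- integrate_scenario(spec)
  exact <- logistic_closed_form(traj$time, 1e4)
  expect_true(all(abs(traj$T - exact) / exact < 1e-6))
  # the other compartments stay empty
  expect_true(all(traj$T_R == 0 & traj$T_M == 0 & traj$N == 0))
})

test_that("first crossing time is interpolated between grid points", {
  ramp <- trajectory(seq(0, 100, by = 1),
                     data.frame(T_R = seq(0, 4e5, length.out = 101)))
  expect_equal(first_crossing_time(ramp, "T_R", 2e5), 50)
  expect_true(is.na(first_crossing_time(ramp, "T_R", 5e5)))
  expect_true(is.na(first_crossing_time(ramp, "T", 1)))  # flat at 0
  # already above the threshold at the first point
  high <- trajectory(0:10, data.frame(T_R = 100 + 0:10))
  expect_equal(first_crossing_time(high, "T_R", 50), 0)
  expect_error(first_crossing_time(ramp, "X", 1), "population")
  expect_error(first_crossing_time(ramp, "T_R", 0), "threshold")
})

test_that("extinction time locates the last downward crossing", {
  t <- seq(0, 100, by = 1)
  decaying <- trajectory(t, data.frame(T = pmax(100 - 99 / 80 * t, 0)))
  expect_equal(extinction_time(decaying, "T", 1), 80)
  const <- trajectory(t, data.frame(T = rep(50, length(t))))
  expect_true(is.na(extinction_time(const, "T", 1)))
  zero <- trajectory(t, data.frame(T = rep(0, length(t))))
  expect_equal(extinction_time(zero, "T", 1), 0)
  # a dip below eps that recovers does not count
  dip <- trajectory(t, data.frame(T = c(rep(10, 40), rep(0, 20), rep(10, 41))))
  expect_true(is.na(extinction_time(dip, "T", 1)))
})

test_that("dominant tumor population excludes normal cells and breaks ties T > T_M > T_R", {
  t <- 0:10
  traj <- trajectory(t, data.frame(N = rep(100, 11), T = rep(5, 11),
                                   T_R = rep(3, 11), T_M = rep(1, 11)))
  expect_identical(dominant_population(traj, 10), "T")
  tie <- trajectory(t, data.frame(T = rep(5, 11), T_M = rep(5, 11),
                                  T_R = rep(2, 11)))
  expect_identical(dominant_population(tie, 10), "T")
  none <- trajectory(t, data.frame(N = rep(100, 11)))
  expect_true(is.na(dominant_population(none, 10)))
  expect_error(dominant_population(traj, 11), "horizon")
})

test_that("a constant-zero trajectory yields the vacuous analytics report", {
  t <- seq(0, 50, by = 0.5)
  zero <- trajectory(t, data.frame(T = rep(0, length(t))))
  rep0 <- analyze_trajectory(zero, threshold = 2e5, eps = 1)
  expect_true(all(is.na(rep0$detection_time)))
  expect_true(all(rep0$extinction_time == 0))
  expect_true(is.na(rep0$dominant))
  expect_identical(rep0$final_state$T, 0)
})

test_that("solver noise is clamped to zero only at output", {
  traj_raw <- integrate_scenario(scenario_preset("a"), clamp = FALSE)
  mins <- vapply(c("N", "T", "T_R", "T_M"), function(p) min(traj_raw[[p]]),
                 numeric(1))
  expect_true(all(mins >= -1e-6))
  traj <- integrate_scenario(scenario_preset("a"))
  expect_true(all(traj$N >= 0 & traj$T >= 0 & traj$T_R >= 0 & traj$T_M >= 0))
})

test_that("the dense grid covers the horizon at the requested spacing", {
  traj <- integrate_scenario(logistic_spec(horizon = 25), grid_dt = 0.5)
  expect_equal(traj$time, seq(0, 25, by = 0.5))
  # horizon not a grid multiple: final point is still reported
  spec <- logistic_spec(horizon = 10.3)
  traj2 <- integrate_scenario(spec, grid_dt = 0.5)
  expect_equal(max(traj2$time), 10.3)
})
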