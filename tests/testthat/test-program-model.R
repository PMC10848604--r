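test_that("stage and program constructors enforce their invariants", {
  expect_error(stage_spec("R1", nominal_duration = 0), "positive")
  expect_error(stage_spec("R1", 1, pandemic_alos = 0.9), "cannot accelerate")
  expect_error(program_config(list(stage_spec("R1")), c(12, 10)), "one entry per stage")
  expect_error(program_config(list(stage_spec("R1")), -1), "nonnegative")
  expect_error(program_config(list(stage_spec("R1")), 12, intake_rate = -2),
               "nonnegative")
  expect_error(pandemic_scenario(-1), "nonnegative")

  cfg <- bundled_program()
  expect_equal(cfg$stages$pandemic_alos, c(1.22, 1.08, 1.23, 1.32, 1.23))
  expect_equal(cfg$initial_stocks, c(12, 10, 10, 18, 12))
  expect_equal(cfg$intake_rate, 12)
})

test_that("effective ALOS is pandemic-adjusted only while the breaker is active", {
  sr1 <- stage_spec("SR1", 1, 1.32)
  cb1 <- pandemic_scenario(duration_T = 1)

  expect_equal(effective_alos(sr1, cb1, 0.5), 1.32)
  expect_equal(effective_alos(sr1, cb1, 1.0), 1.0)   # impact deactivated at onset + T
  expect_equal(effective_alos(sr1, cb1, 3.0), 1.0)
  expect_equal(effective_alos(sr1, pandemic_scenario(0), 0.5), 1.0)  # BAU: never active
  # partial baseline impact interpolates linearly between nominal and pandemic ALOS
  expect_equal(effective_alos(sr1, pandemic_scenario(1, baseline_impact = 0.5), 0.5),
               1.16)
  # late onset: nominal before the breaker starts
  expect_equal(effective_alos(sr1, pandemic_scenario(1, onset = 2), 0.5), 1.0)
  expect_equal(effective_alos(sr1, pandemic_scenario(1, onset = 2), 2.5), 1.32)
})

test_that("transfer rate is first-order outflow stock / ALOS", {
  expect_equal(transfer_rate(10, 1.0), 10.0)
  expect_equal(transfer_rate(18, 1.32), 13.6364, tolerance = 1e-4)
  expect_equal(transfer_rate(0, 1.32), 0.0)
  expect_error(transfer_rate(10, 0), "invalid stage")
  expect_error(transfer_rate(-1, 1), "nonnegative")
})

test_that("one Euler step matches the hand-computed update", {
  cfg <- program_config(lapply(c("R1", "R2", "R3", "SR1", "SR2"), stage_spec),
                        initial_stocks = c(12, 10, 10, 18, 12), intake_rate = 12)
  s0 <- list(time = 0, stocks = cfg$initial_stocks, graduates_cumulative = 0)
  s1 <- step_state(s0, cfg, pandemic_scenario(0), dt = 0.25)
  expect_equal(s1$stocks, c(12.0, 10.5, 10.0, 16.0, 13.5))
  expect_equal(s1$graduates_cumulative, 3.0)
  expect_equal(s1$time, 0.25)

  # all stocks equal to intake with unit ALOS is a fixed point
  eq <- list(time = 0, stocks = rep(12, 5), graduates_cumulative = 0)
  s <- step_state(eq, neutral_config(), pandemic_scenario(0), dt = 0.1)
  expect_equal(s$stocks, rep(12, 5))
  expect_equal(s$graduates_cumulative, 1.2)

  # a T = 0 scenario steps identically to a config with no pandemic excess
  cb0 <- step_state(s0, bundled_program(), pandemic_scenario(0), dt = 0.25)
  expect_identical(cb0, s1)

  expect_error(step_state(s0, cfg, pandemic_scenario(0), dt = 0), "positive")
})

test_that("equilibrium programs graduate the intake every year under both flow laws", {
  cfg <- neutral_config(stock = 7)
  for (flow in c("conveyor", "first_order")) {
    traj <- simulate_program(cfg, horizon = 10, dt = 0.25, flow = flow)
    expect_equal(unname(annual_graduates(traj)), rep(7, 10), tolerance = 1e-9)
  }
})

test_that("T = 0 trajectory is bitwise identical to a no-pandemic program", {
  cfg <- bundled_program()
  flat <- program_config(lapply(cfg$stages$name, stage_spec),
                         cfg$initial_stocks, cfg$intake_rate)
  for (flow in c("conveyor", "first_order")) {
    a <- simulate_program(cfg, pandemic_scenario(0), horizon = 8, dt = 0.25, flow = flow)
    b <- simulate_program(flat, pandemic_scenario(3), horizon = 8, dt = 0.25, flow = flow)
    expect_identical(as.matrix(as.data.frame(a)), as.matrix(as.data.frame(b)))
  }
})

test_that("simulation validates its grid and rejects degenerate steps", {
  cfg <- bundled_program()
  expect_error(simulate_program(cfg, horizon = 0), "positive")
  expect_error(simulate_program(cfg, horizon = 10, dt = 0.3), "divide one year")
  expect_error(simulate_program(cfg, horizon = 10.1, dt = 0.25), "whole multiple")
  # identical inputs give identical output (deterministic engine)
  a <- simulate_program(cfg, pandemic_scenario(2), horizon = 10)
  b <- simulate_program(cfg, pandemic_scenario(2), horizon = 10)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("annual graduates are nonnegative and telescope to the cumulative total", {
  cfg <- bundled_program()
  for (flow in c("conveyor", "first_order")) {
    for (T in c(0, 1, 3, 5)) {
      traj <- simulate_program(cfg, pandemic_scenario(T), horizon = 12, flow = flow)
      ann <- annual_graduates(traj)
      expect_true(all(ann >= -1e-12))
      expect_equal(sum(ann), traj$graduates_cumulative[nrow(traj)], tolerance = 1e-9)
    }
  }
})

test_that("cumulative graduates never decrease and stocks stay nonnegative", {
  cfg <- bundled_program()
  for (flow in c("conveyor", "first_order")) {
    traj <- simulate_program(cfg, pandemic_scenario(2), horizon = 12, flow = flow)
    expect_true(all(diff(traj$graduates_cumulative) >= -1e-12))
    stocks <- as.matrix(as.data.frame(traj)[cfg$stages$name])
    expect_true(all(stocks >= -1e-12))
  }
})

test_that("Euler engine matches the closed-form exponential drain", {
  # single stage, no intake: stock(t) = s0 * exp(-t / alos)
  cfg <- program_config(list(stage_spec("S1", 1.3, 1.3)), initial_stocks = 20,
                        intake_rate = 0)
  exact <- function(t) 20 * exp(-t / 1.3)
  err_at <- function(dt) {
    traj <- simulate_program(cfg, horizon = 2, dt = dt, flow = "first_order")
    abs(traj$S1[nrow(traj)] - exact(2))
  }
  e1 <- err_at(0.01)
  expect_lt(e1 / exact(2), 0.01)
  # first-order convergence: halving dt roughly halves the error
  expect_equal(err_at(0.02) / e1, 2, tolerance = 0.2)
})

test_that("Euler chain agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  cfg <- bundled_program()
  alos <- cfg$stages$pandemic_alos  # constant-ALOS chain (breaker active throughout)
  rhs <- function(t, y, parms) {
    out <- y[1:5] / alos
    list(c(cfg$intake_rate - out[1], out[1:4] - out[2:5], out[5]))
  }
  sol <- deSolve::ode(y = c(cfg$initial_stocks, 0), times = seq(0, 4, 0.25),
                      func = rhs, parms = NULL, method = "lsoda")
  traj <- simulate_program(cfg, pandemic_scenario(duration_T = 10), horizon = 4,
                           dt = 0.01, flow = "first_order")
  rows <- match(seq(0, 4, 0.25), round(traj$time, 9))
  euler <- as.matrix(as.data.frame(traj)[rows, c(cfg$stages$name, "graduates_cumulative")])
  expect_equal(unname(euler), unname(sol[, -1]), tolerance = 1e-3)
})

test_that("annual counts are stable under step refinement", {
  cfg <- bundled_program()
  sc <- pandemic_scenario(2)
  coarse <- annual_graduates(simulate_program(cfg, sc, 10, dt = 0.25, flow = "first_order"))
  fine <- annual_graduates(simulate_program(cfg, sc, 10, dt = 0.0125, flow = "first_order"))
  expect_equal(unname(coarse), unname(fine), tolerance = 0.02)
  # the conveyor law is grid-independent by construction
  c1 <- annual_graduates(simulate_program(cfg, sc, 10, dt = 0.25))
  c2 <- annual_graduates(simulate_program(cfg, sc, 10, dt = 0.05))
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("trajectories rejoin the baseline after the breaker ends", {
  cfg <- bundled_program()
  for (flow in c("conveyor", "first_order")) {
    bau <- simulate_program(cfg, pandemic_scenario(0), horizon = 25, flow = flow)
    cb <- simulate_program(cfg, pandemic_scenario(2), horizon = 25, flow = flow)
    gap <- abs(annual_graduates(cb) - annual_graduates(bau))
    expect_lt(gap[25], 1e-3)
    # the tail gap shrinks towards zero
    expect_true(all(diff(gap[10:25]) <= 1e-9))
  }
})
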