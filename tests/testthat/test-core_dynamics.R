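test_that("gain is a rectified saturating function of net input", {
  expect_equal(wc_gain(-5), 0)
  expect_equal(wc_gain(0), 0)
  # semi-saturation input gives exactly half the maximum rate
  expect_equal(wc_gain(30, c1 = 100, c2 = 30), 50)
  expect_lt(abs(wc_gain(1e6) - 100), 0.1)
  # monotone non-decreasing, bounded by c1
  x <- seq(-10, 500, by = 0.5)
  g <- wc_gain(x)
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g < 100))
  expect_error(wc_gain(1, c1 = -1), "positive")
})

test_that("unit derivatives relax E and I toward their gains", {
  expect_equal(unit_derivatives(0, 0, 0), c(dE = 0, dI = 0))
  # onset of drive: dE = a1 * gain(20) = 0.26 * 100 * 400 / 1300 = 8, dI = 0
  d <- unit_derivatives(0, 0, 20)
  expect_equal(unname(d), c(8, 0))
  expect_error(unit_derivatives(NaN, 0, 0), "invalid state")
  expect_error(unit_derivatives(0, Inf, 0), "invalid state")
})

test_that("unit derivatives match a central finite difference of the flow", {
  # independent oracle: second-order one-sided difference of micro RK4
  # steps of a single uncoupled unit around several states
  spec <- network_spec(1, 0, 0, memory_schedules = drive_schedule(0, 20))
  states <- list(c(5, 2), c(50, 30), c(86, 60), c(0.3, 0.1))
  h <- 1e-4
  for (s in states) {
    st <- list(E = c(0, s[1]), I = c(0, s[2]))
    s1 <- rk4_step(st, 0, h, spec)
    s2 <- rk4_step(s1, h, h, spec)
    fd_E <- (-3 * st$E[2] + 4 * s1$E[2] - s2$E[2]) / (2 * h)
    fd_I <- (-3 * st$I[2] + 4 * s1$I[2] - s2$I[2]) / (2 * h)
    d <- unit_derivatives(s[1], s[2], 20)
    expect_lt(abs(fd_E - d["dE"]), 1e-6)
    expect_lt(abs(fd_I - d["dI"]), 1e-6)
  }
})

test_that("memory drive combines base, synchronizing and desynchronizing terms", {
  expect_equal(memory_drive(20, 0, 0, 0, 0), 20)
  expect_equal(memory_drive(20, 10, 0, 0.1, 0), 21)
  expect_equal(memory_drive(20, 0, c(30, 20), 0, 0.02), 19)
  # linear in each activity argument
  expect_equal(memory_drive(0, 4, c(1, 2), 0.5, 0.25) * 2,
               memory_drive(0, 8, c(2, 4), 0.5, 0.25))
  expect_error(memory_drive(0, 0, 0, -1, 0), "non-negative")
})

test_that("R and compiled integrators take identical steps", {
  spec <- network_spec(2, 0.15, 0.01,
                       central_schedule = drive_schedule(0, 5),
                       memory_schedules = drive_schedule(0, 20))
  init <- list(E = c(1, 5, 9), I = c(0.5, 2, 4))
  # 50 steps of the R reference
  st <- init
  for (i in 0:49) st <- rk4_step(st, i * 0.01, 0.01, spec)
  sim <- simulate(spec, duration = 5e-4, dt = 0.01, init = init, stride = 50)
  expect_equal(sim$central_E[1], st$E[1], tolerance = 1e-12)
  expect_equal(sim$memory_E[1, ], st$E[2:3], tolerance = 1e-12)
  expect_equal(sim$memory_I[1, ], st$I[2:3], tolerance = 1e-12)
})

test_that("quiescent network stays at rest and rejects bad arguments", {
  spec <- network_spec(2, 0.1, 0.01)   # all drives zero
  sim <- simulate(spec, duration = 0.2,
                  init = list(E = numeric(3), I = numeric(3)))
  expect_true(all(sim$memory_E == 0), all(sim$central_E == 0))
  expect_error(simulate(spec, duration = -1), "duration")
  expect_error(simulate(spec, duration = 1, dt = 0), "dt")
  expect_error(network_spec(0, 0.1, 0.1), "n_memory")
})

test_that("single-unit attractors match the drive regimes", {
  # low drive: fixed point; moderate: limit cycle; saturating: fixed point
  for (cfg in list(list(K0 = 1, cls = "fixed_point"),
                   list(K0 = 20, cls = "limit_cycle"),
                   list(K0 = 30, cls = "fixed_point"))) {
    sim <- simulate_unit(cfg$K0, duration = 5, seed = 1)
    post <- sim$memory_E[sim$times > 2, 1]
    expect_identical(classify_attractor(post), cfg$cls)
  }
})

test_that("trajectories stay within the saturation bounds", {
  spec <- network_spec(4, 0.2, 0.02,
                       central_schedule = drive_schedule(0, 5),
                       memory_schedules = drive_schedule(0, 20))
  sim <- simulate(spec, duration = 4, seed = 7)
  for (m in list(sim$central_E, sim$central_I, sim$memory_E, sim$memory_I)) {
    expect_true(all(is.finite(m)))
    expect_true(all(m >= 0 & m <= 100))
  }
})

test_that("fixed-step integration agrees with an adaptive reference solver", {
  skip_if_not_installed("deSolve")
  p <- unit_params()
  spec <- network_spec(2, 0.1, 0.02,
                       central_schedule = drive_schedule(0, 5),
                       memory_schedules = drive_schedule(0, 20))
  init <- list(E = c(0.05, 0.02, 0.08), I = c(0.01, 0.04, 0.03))
  rhs <- function(t, y, parms) {
    st <- list(E = y[1:3], I = y[4:6])
    d <- wmsync:::network_derivatives(st, t, spec)
    list(c(d$E, d$I))
  }
  ref <- deSolve::ode(c(init$E, init$I), seq(0, 1000, by = 1), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  sim <- simulate(spec, duration = 1, dt = 0.01, init = init, stride = 100)
  # stored samples at 1, 2, ..., 1000 ms
  for (u in 1:2) {
    err <- max(abs(sim$memory_E[, u] - ref[-1, 1 + u + 1]))
    expect_lt(err, 1e-3)
  }
  expect_lt(max(abs(sim$central_E - ref[-1, 2])), 1e-3)
})

test_that("halving the step leaves end-state phases unchanged", {
  spec <- network_spec(2, 0.15, 0.005,
                       central_schedule = drive_schedule(0, 5),
                       memory_schedules = drive_schedule(0, 20))
  init <- list(E = c(0.05, 0.02, 0.08), I = c(0.01, 0.04, 0.03))
  s1 <- simulate(spec, 3, dt = 0.01, init = init, stride = 100)
  s2 <- simulate(spec, 3, dt = 0.005, init = init, stride = 200)
  e1 <- pair_error(s1, 1, 2, 2.2, 3)
  e2 <- pair_error(s2, 1, 2, 2.2, 3)
  expect_equal(e1 < 0.01, e2 < 0.01)   # same lock classification
  expect_lt(max(abs(s1$memory_E - s2$memory_E)), 0.5)
})

test_that("integration blow-up is reported with unit and time", {
  # huge negative current is fine (rectified), but a non-finite schedule is
  # rejected before integration
  expect_error(drive_schedule(0, Inf), "finite")
  expect_error(rk4_step(list(E = c(1e308, 0), I = c(0, 0)), 0, 1e6,
                        network_spec(1, 0, 0)), "blow-up|finite")
})
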