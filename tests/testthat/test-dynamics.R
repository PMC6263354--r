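test_that("interpolation is exact at nodes, linear between, held beyond", {
  tc <- time_course(c(0, 1, 3, 7), c(2, 4, 0, 8), "s")
  expect_equal(tc_interpolate(tc, c(0, 1, 3, 7)), c(2, 4, 0, 8))
  expect_equal(tc_interpolate(tc, 0.5), 3)
  expect_equal(tc_interpolate(tc, 2), 2)
  expect_equal(tc_interpolate(tc, -5), 2)
  expect_equal(tc_interpolate(tc, 100), 8)
})

test_that("time-course invariants are enforced", {
  expect_error(time_course(c(1, 1), c(0, 0)), "strictly increasing")
  expect_error(time_course(1, 1), "length >= 2")
  expect_error(time_course(c(2, 1), c(0, 0)), "strictly increasing")
})

test_that("gate ODE has the steady state as fixed point and correct sign", {
  p <- repressor_gate_params()
  g <- gate("g", "NOT", "x", p)
  cfg <- sim_config()
  y_ss <- repressor_response(p, 0.3)
  expect_equal(gate_rhs(g, list(0.3), y_ss, cfg), 0)
  expect_equal(gate_rhs(g, list(0), p$y_min, cfg),
               cfg$alpha * (p$y_max - p$y_min))
  # AND and ANDN fixed points likewise
  ga <- gate("a", "AND", c("u", "v"))
  expect_equal(gate_rhs(ga, list(0.2, 0.5),
                        and_response(ga$params, 0.2, 0.5), cfg), 0)
  gn <- gate("n", "ANDN", c("u", "v"))
  expect_equal(gate_rhs(gn, list(0.2, 0.5),
                        andn_response(gn$params, 0.2, 0.5), cfg), 0)
})

test_that("integrators match the closed-form exponential relaxation", {
  # single NOT gate, constant input x = K: y(t) = y_ss + (y0-y_ss) e^{-t}
  p <- repressor_gate_params()
  circ <- circuit("x", list(gate("g", "NOT", "x", p)))
  y_ss <- repressor_response(p, p$K)
  # start from the steady state of a different input (x = 0 -> y0 = y_max)
  cfg_e <- sim_config(t_end = 5, dt = 0.025,
                      init_sensor_values = c(x = 0))
  tcs <- list(x = constant_tc(p$K, "x", t_end = 5))
  tr_e <- simulate_circuit(circ, tcs, cfg_e)$g
  exact <- y_ss + (p$y_max - y_ss) * exp(-tr_e$times)
  err_euler <- max(abs(tr_e$values - exact))
  expect_lt(err_euler, 0.025)  # O(dt)

  cfg_r <- cfg_e; cfg_r$integrator <- "rk4"
  tr_r <- simulate_circuit(circ, tcs, cfg_r)$g
  expect_lt(max(abs(tr_r$values - exact)), 1e-7)  # O(dt^4)

  # halving dt halves the Euler error (first-order convergence)
  cfg_h <- cfg_e; cfg_h$dt <- 0.0125
  tr_h <- simulate_circuit(circ, tcs, cfg_h)$g
  exact_h <- y_ss + (p$y_max - y_ss) * exp(-tr_h$times)
  err_half <- max(abs(tr_h$values - exact_h))
  expect_lt(err_half, 0.62 * err_euler)
})

test_that("steady-state initialization matches an independent fixed point", {
  circ <- three_repressor_circuit()
  cfg <- sim_config()
  init <- steady_state_init(circ, cfg)
  oracle <- fixed_point_oracle(circ, cfg$init_sensor_values)
  expect_equal(unname(init[c("y1", "y2", "y3")]),
               unname(oracle[c("y1", "y2", "y3")]), tolerance = 1e-10)
  # alpha = gamma: identical to steady-state propagation
  ss <- circuit_steady_state(circ, cfg$init_sensor_values)
  expect_equal(init, ss[names(init)])
  # single gate, alpha != gamma: y = y_min + (alpha/gamma) * production
  p <- repressor_gate_params()
  c1 <- circuit("x", list(gate("g", "NOT", "x", p)))
  cfg2 <- sim_config(alpha = 2, gamma = 0.5, init_sensor_values = c(x = 0.3))
  prod <- (p$y_max - p$y_min) * p$K^p$n / (p$K^p$n + 0.3^p$n)
  expect_equal(unname(steady_state_init(c1, cfg2)), p$y_min + 4 * prod)
})

test_that("constant inputs relax to the circuit steady state by 27 h", {
  circ <- three_repressor_circuit()
  sv <- c(x1 = 0.237, x2 = 1.346, x3 = 0.7)
  tcs <- list(x1 = constant_tc(0.237, "x1"), x2 = constant_tc(1.346, "x2"),
              x3 = constant_tc(0.7, "x3"))
  # start away from the target steady state
  cfg <- sim_config(init_sensor_values = c(x1 = 1.294, x2 = 0.006,
                                           x3 = 0.028))
  traj <- simulate_circuit(circ, tcs, cfg)
  target <- circuit_steady_state(circ, sv)
  for (id in names(traj))
    expect_equal(tail(traj[[id]]$values, 1), unname(target[id]),
                 tolerance = 1e-6)
})

test_that("euler and rk4 agree within 1% on fixture circuits", {
  batch <- simulate_batch()
  wires <- sensor_outputs_from_batch(batch = batch)
  fixtures <- list(
    list(circ = pulse_circuit(),
         tcs = list(glucose = wires$glucose, oxygen = wires$oxygen,
                    acetate = wires$acetate)),
    list(circ = three_repressor_circuit(),
         tcs = list(x1 = wires$glucose, x2 = wires$oxygen,
                    x3 = wires$acetate)))
  for (fx in fixtures) {
    cfg_e <- sim_config(init_sensor_values = inoculum_sensor_values(
      wires = fx$circ$inputs))
    cfg_r <- cfg_e; cfg_r$integrator <- "rk4"
    tr_e <- simulate_circuit(fx$circ, fx$tcs, cfg_e)
    tr_r <- simulate_circuit(fx$circ, fx$tcs, cfg_r)
    for (id in names(tr_e)) {
      scale <- max(abs(tr_r[[id]]$values))
      expect_lt(max(abs(tr_e[[id]]$values - tr_r[[id]]$values)) / scale,
                0.01)
    }
  }
})

test_that("step response of an ANDN circuit falls as low oxygen rises", {
  batch <- simulate_batch()
  wires <- sensor_outputs_from_batch(batch = batch)
  circ <- circuit(c("glucose", "oxygen"),
                  list(gate("g", "ANDN", c("glucose", "oxygen"))))
  cfg <- sim_config(init_sensor_values = c(glucose = 0.006, oxygen = 0.020))
  tr <- simulate_circuit(circ, wires[c("glucose", "oxygen")], cfg)$g
  expect_gt(tc_interpolate(tr, 4), tc_interpolate(tr, 20))
})

test_that("simulation guards reject bad configurations", {
  circ <- circuit("x", list(gate("g", "NOT", "x")))
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(t_end = -1), "t_end")
  cfg <- sim_config(t_start = 0, t_end = 1, dt = 2)
  expect_error(simulate_circuit(circ, list(x = constant_tc(1, "x")), cfg),
               "smaller than the simulated span")
  expect_error(simulate_circuit(circ, list(), sim_config()),
               "no time course")
})
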