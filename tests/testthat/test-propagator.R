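test_that("linearization is exact for linear systems and first-order for Morse", {
  sys <- harmonic_system(k = 3, mu = 2)
  seg <- linearize(sys, 0, c(0.5, -1))
  set.seed(8)
  for (i in 1:10) {
    y <- stats::rnorm(2)
    cf <- qubode:::segment_coef(seg, 1, 1)
    expect_equal(cf$f0 + drop(cf$fk %*% y), sys$rhs(0, y), tolerance = 1e-12)
  }

  # Morse force linearized at r0 = 1.3 matches the analytic first-order Taylor
  p <- morse_parameters()
  msys <- morse_system(p)
  seg_m <- linearize(msys, 0, c(1.3, 0))
  cf <- qubode:::segment_coef(seg_m, 1, 1)
  for (r in c(1.25, 1.3, 1.35)) {
    lin <- cf$f0[2] + cf$fk[2, 1] * r
    taylor <- morse_force(1.3, p) + qubode:::morse_force_deriv(1.3, p) * (r - 1.3)
    expect_equal(lin, taylor, tolerance = 1e-10)
  }

  # without a Jacobian, central differences recover the analytic one
  msys_fd <- ode_system(msys$rhs, 2)
  seg_fd <- linearize(msys_fd, 0, c(1.3, 0))
  expect_equal(qubode:::segment_coef(seg_fd, 1, 1)$fk,
               qubode:::segment_coef(seg_m, 1, 1)$fk, tolerance = 1e-6)

  # constant right-hand side has zero linear coefficients
  cs <- ode_system(function(x, y) c(2, -1), 2)
  expect_equal(qubode:::segment_coef(linearize(cs, 0, c(0, 0)), 1, 1)$fk,
               matrix(0, 2, 2))
})

test_that("one-point-per-run continuous propagation is exactly forward Euler", {
  p <- morse_parameters()
  sys <- morse_system(p)
  grid <- time_grid(0, 0.4, 200)
  traj <- propagate(sys, grid, c(1.3, 0),
                    propagation_config(solver = "qp", mode = "sequential"))
  euler <- matrix(NA_real_, 201, 2)
  euler[1, ] <- c(1.3, 0)
  for (i in 1:200) {
    euler[i + 1, ] <- euler[i, ] + 0.4 * hamilton_rhs(euler[i, ], p)
  }
  expect_lt(max(abs(traj$values - euler)), 1e-12)
  expect_identical(traj$values[1, ], c(1.3, 0))
})

test_that("sequential and coupled modes coincide at one point per run", {
  sys <- morse_system()
  grid <- time_grid(0, 0.4, 100)
  t_seq <- propagate(sys, grid, c(1.3, 0),
                     propagation_config(solver = "qp", mode = "sequential"))
  t_cpl <- propagate(sys, grid, c(1.3, 0),
                     propagation_config(solver = "qp", mode = "coupled"))
  expect_lt(max(abs(t_seq$values - t_cpl$values)), 1e-12)
})

test_that("multi-point runs reproduce the per-cell minimizers for constant forcing", {
  cs <- ode_system(function(x, y) c(2, -1), 2,
                   jacobian = function(x, y) matrix(0, 2, 2))
  grid <- time_grid(0, 0.1, 6)
  traj <- propagate(cs, grid, c(0, 1),
                    propagation_config(solver = "qp", mode = "coupled", m = 3))
  ramp <- cbind(0 + 2 * grid$times, 1 - grid$times)
  expect_lt(max(abs(traj$values - ramp)), 1e-10)
})

test_that("final-state error on the harmonic fixture converges at first order", {
  sys <- harmonic_system(1, 1)
  sizes <- c(50, 100, 200, 400, 800)
  t_total <- 5
  errs <- vapply(sizes, function(S) {
    g <- time_grid(0, t_total / S, S)
    tr <- propagate(sys, g, c(1, 0), propagation_config(solver = "qp"))
    ref <- harmonic_reference(g$times, 1, 0)
    abs(tr$values[S + 1, 1] - ref[S + 1, "r"])
  }, numeric(1))
  slope <- convergence_slope(t_total / sizes, errs)
  expect_gte(slope, 0.8)
  expect_lte(slope, 1.2)
})

test_that("exhaustive-solver trajectory tracks the continuous one within quantization", {
  sys <- harmonic_system(1, 1)
  grid <- time_grid(0, 0.1, 60)
  cfg_b <- propagation_config(solver = "exhaustive", mode = "sequential",
                              scheme = fp_scheme(6, 15))
  t_bin <- propagate(sys, grid, c(1, 0), cfg_b)
  t_qp <- propagate(sys, grid, c(1, 0), propagation_config(solver = "qp"))
  expect_lt(max(abs(t_bin$values - t_qp$values)), 1e-3)
})

test_that("variable rescaling is an exact change of variables", {
  sys <- harmonic_system(k = 2, mu = 3)
  expect_error(apply_scaling(sys, c(1, -1)), "positive")

  # identity scaling leaves the right-hand side unchanged
  s1 <- apply_scaling(sys, c(1, 1))
  expect_equal(s1$rhs(0, c(0.3, -0.8)), sys$rhs(0, c(0.3, -0.8)))

  # momentum scale mu*omega equalizes the two components at equal amplitude
  w <- sqrt(2 / 3)
  s2 <- apply_scaling(sys, c(1, 3 * w))
  g <- s2$rhs(0, c(0.6, -0.4))
  expect_equal(g, c(w * -0.4, -w * 0.6), tolerance = 1e-12)

  # propagate-then-unscale reproduces the unscaled trajectory
  grid <- time_grid(0, 0.05, 80)
  t_plain <- propagate(sys, grid, c(1, 0), propagation_config(solver = "qp"))
  sc <- c(1, 3 * w)
  t_scaled <- unscale_trajectory(
    propagate(apply_scaling(sys, sc), grid, c(1, 0) / sc,
              propagation_config(solver = "qp")),
    sc
  )
  expect_lt(max(abs(t_plain$values - t_scaled$values)), 1e-9)
})

test_that("binary propagation aborts with the step index when the state saturates", {
  runaway <- ode_system(function(x, y) 10, 1,
                        jacobian = function(x, y) matrix(0, 1, 1))
  grid <- time_grid(0, 1, 10)
  cfg <- propagation_config(solver = "exhaustive", mode = "sequential",
                            scheme = fp_scheme(3, 2))
  expect_error(propagate(runaway, grid, 3, cfg), "step")
})

test_that("sequential mode refuses multi-point runs", {
  expect_error(propagation_config(m = 2, mode = "sequential"), "one grid point")
})
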