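test_that("one-step least-squares cell is minimized by the forward-Euler update", {
  qp <- euler_cell_qp(y1 = 1.0, f = 2.5, dx = 0.1)
  ystar <- solve_qp_continuous(qp)
  expect_equal(ystar, 1.0 + 0.1 * 2.5, tolerance = 1e-12)
  expect_lt(abs(qp_energy(qp, ystar)), 1e-12)
})

test_that("zero right-hand side keeps the solution constant over many steps", {
  seg <- linear_segment(f0 = c(0, 0), fk = matrix(0, 2, 2), n = 2)
  qp <- build_qp(seg, dx = 0.2, m = 4, y_init = c(1.5, -0.5))
  ystar <- solve_qp_continuous(qp)
  expect_equal(ystar, rep(c(1.5, -0.5), 4), tolerance = 1e-10)
})

test_that("naturally linear harmonic cell reproduces the explicit first-order step", {
  mu <- 2; k <- 3
  J <- matrix(c(0, -k, 1 / mu, 0), 2, 2)
  seg <- linear_segment(f0 = c(0, 0), fk = J, n = 2)
  y0 <- c(0.7, -0.3)
  dx <- 0.05
  qp <- build_qp(seg, dx = dx, m = 1, y_init = y0)
  expect_equal(solve_qp_continuous(qp), y0 + dx * drop(J %*% y0),
               tolerance = 1e-12)
})

test_that("1x1 QP with a 1-bit scheme compiles to the hand-derived QUBO", {
  # y = -1 + q; h y^2 + d y = q (d - h) + (h - d)
  h <- 1.7; d <- -0.4
  qp <- structure(list(H = matrix(h), d = d, offset = 0, labels = NULL),
                  class = "qp_problem")
  qb <- qp_to_qubo(qp, fp_scheme(1, 0))
  expect_equal(dim(qb$Q), c(1L, 1L))
  expect_equal(qb$Q[1, 1], d - h)
  expect_equal(qb$offset, h - d)
})

test_that("off-diagonal blocks carry the bit-weight product of H", {
  qp <- random_spd_qp(3, seed = 4)
  sc <- fp_scheme(2, 1)
  qb <- qp_to_qubo(qp, sc)
  k <- sc$k
  wj <- 2^(-sc$positions)
  # element between variable 1 bit a and variable 2 bit b (folded upper
  # triangle sums the (1,2) and (2,1) contributions)
  for (a in 1:k) for (b in 1:k) {
    expect_equal(qb$Q[a, k + b],
                 wj[a] * wj[b] * (qp$H[1, 2] + qp$H[2, 1]))
  }
})

test_that("zero QP compiles to zero QUBO with unchanged offset", {
  qp <- structure(list(H = matrix(0, 2, 2), d = c(0, 0), offset = 3.25,
                       labels = NULL), class = "qp_problem")
  qb <- qp_to_qubo(qp, fp_scheme(2, 2))
  expect_true(all(qb$Q == 0))
  expect_equal(qb$offset, 3.25)
})

test_that("QUBO energy plus offset equals the QP functional at the decoded state", {
  # the module's central contract, on random bit strings
  for (seed in c(11, 12)) {
    qp <- random_spd_qp(3, seed = seed)
    qb <- qp_to_qubo(qp, fp_scheme(3, 3))
    set.seed(seed)
    for (i in 1:50) {
      bits <- sample(0:1, nrow(qb$Q), replace = TRUE)
      e_bin <- qubo_energy(qb, bits, include_offset = TRUE)
      e_cont <- qp_energy(qp, decode_solution(qb, bits))
      expect_energy_equal(e_bin, e_cont)
    }
  }
})

test_that("small 2-bit QUBO enumerates to the hand-computed energies", {
  qb <- toy_qubo(matrix(c(-1, 0, 2, -1), 2, 2))
  states <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  energies <- vapply(states, function(b) qubo_energy(qb, b), numeric(1))
  expect_equal(energies, c(0, -1, -1, 0))
})

test_that("exhaustive QUBO minimum equals the QP minimum on the representable lattice", {
  sc <- fp_scheme(2, 2)  # 4 bits per unknown, 2 unknowns -> 256 states
  qp <- random_spd_qp(2, seed = 21)
  qb <- qp_to_qubo(qp, sc)
  rep <- solve_exhaustive(qb)
  # independent lattice enumeration in the continuous picture
  step <- 2^-2
  vals <- seq(fp_range(sc)$min, fp_range(sc)$max, by = step)
  grid <- expand.grid(y1 = vals, y2 = vals)
  lattice_min <- min(apply(grid, 1, function(y) qp_energy(qp, y)))
  expect_energy_equal(rep$energy + qb$offset, lattice_min)
  # and the continuous minimum bounds the lattice minimum from below
  cont_min <- qp_energy(qp, solve_qp_continuous(qp))
  expect_lte(cont_min, lattice_min + 1e-12)
})

test_that("reordering equations permutes the compiled problem consistently", {
  J <- matrix(c(0.1, -1, 0.5, -0.2), 2, 2)
  seg12 <- linear_segment(f0 = c(0.3, -0.7), fk = J, n = 2)
  seg21 <- linear_segment(f0 = c(-0.7, 0.3), fk = J[2:1, 2:1], n = 2)
  y0 <- c(1, -2)
  qp12 <- build_qp(seg12, dx = 0.1, m = 1, y_init = y0)
  qp21 <- build_qp(seg21, dx = 0.1, m = 1, y_init = y0[2:1])
  set.seed(3)
  for (i in 1:20) {
    y <- stats::rnorm(2)
    expect_equal(qp_energy(qp12, y), qp_energy(qp21, y[2:1]),
                 tolerance = 1e-12)
  }
})

test_that("decode_solution recovers per-slot values and round trips", {
  sc <- fp_scheme(6, 15)
  qp <- random_spd_qp(3, seed = 5)
  qb <- qp_to_qubo(qp, sc)
  # all-zero bits decode to the scheme minimum in every slot
  expect_equal(decode_solution(qb, rep(0, nrow(qb$Q))), rep(-32, 3))
  # encoding a target vector and decoding recovers it within a half step
  target <- c(1.7, -0.33, 12.125)
  bits <- unlist(lapply(target, fp_encode, scheme = sc))
  expect_equal(decode_solution(qb, bits), target, tolerance = 2^-16)
})

test_that("lattice optimum of a single cell sits within curvature times quantization of the continuous one", {
  sc <- fp_scheme(6, 15)
  qp <- euler_cell_qp(y1 = 1.3, f = -0.37, dx = 0.4)
  qb <- qp_to_qubo(qp, sc)
  rep <- solve_exhaustive(qb)
  e_lattice <- rep$energy + qb$offset
  e_cont <- qp_energy(qp, solve_qp_continuous(qp))
  curvature <- qp$H[1, 1] + qp$H[1, 1]  # second derivative of the 1-d quadratic
  expect_gte(e_lattice, e_cont - 1e-12)
  expect_lte(e_lattice - e_cont, curvature * (2^-16)^2 + 1e-12)
})
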