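test_that("continuous QP solve returns the stationary point", {
  qp <- structure(list(H = diag(3), d = rep(-2, 3), offset = 0, labels = NULL),
                  class = "qp_problem")
  expect_equal(solve_qp_continuous(qp), rep(1, 3), tolerance = 1e-12)

  qp2 <- euler_cell_qp(y1 = 0.4, f = 1.1, dx = 0.25)
  expect_equal(solve_qp_continuous(qp2), 0.4 + 0.25 * 1.1, tolerance = 1e-12)

  qp3 <- random_spd_qp(5, seed = 9)
  ystar <- solve_qp_continuous(qp3)
  grad <- drop((qp3$H + t(qp3$H)) %*% ystar + qp3$d)
  expect_lt(sqrt(sum(grad^2)), 1e-9)
})

test_that("singular QP falls back to a least-norm stationary point with a warning", {
  qp <- structure(list(H = matrix(0, 2, 2), d = c(0, 0), offset = 1,
                       labels = NULL), class = "qp_problem")
  expect_warning(y <- solve_qp_continuous(qp), "singular")
  expect_equal(y, c(0, 0))
})

test_that("exhaustive enumeration finds the global minimum and breaks ties as documented", {
  qb <- toy_qubo(matrix(c(-1, 0, 2, -1), 2, 2))
  rep <- solve_exhaustive(qb)
  expect_equal(rep$energy, -1)
  # degenerate with (0,1); tie resolved toward the lower little-endian value
  expect_equal(rep$bits, c(1L, 0L))

  z <- solve_exhaustive(toy_qubo(matrix(0, 3, 3)))
  expect_equal(z$energy, 0)
  expect_equal(z$bits, rep(0L, 3))

  expect_error(solve_exhaustive(rand_qubo(30, 1), max_bits = 24), "limit")
})

test_that("exhaustive kernel agrees with an independently coded brute force", {
  for (seed in c(101, 102, 103, 104)) {
    qb <- rand_qubo(10, seed)
    rep <- solve_exhaustive(qb)
    bf <- brute_force_min(qb$Q)
    expect_energy_equal(rep$energy, bf$energy)
    expect_energy_equal(qubo_energy(qb, rep$bits), rep$energy)
  }
})

test_that("simulated annealing is reproducible and solves trivial problems", {
  qb <- toy_qubo(matrix(0, 4, 4))
  expect_equal(solve_sa(qb, anneal_schedule(reads = 2, sweeps = 5))$energy, 0)

  qb2 <- rand_qubo(12, 7)
  sched <- anneal_schedule(reads = 5, sweeps = 50, seed = 42)
  r1 <- solve_sa(qb2, sched)
  r2 <- solve_sa(qb2, sched)
  expect_identical(r1$bits, r2$bits)
  expect_identical(r1$attempt_energies, r2$attempt_energies)
})

test_that("annealing with enough reads reaches the exhaustive optimum of fixed-point cells", {
  sc <- fp_scheme(6, 15)
  set.seed(5)
  hits <- 0
  n_trials <- 20
  for (trial in seq_len(n_trials)) {
    qp <- euler_cell_qp(y1 = stats::runif(1, 0.8, 2.2),
                        f = stats::runif(1, -1, 1))
    qb <- qp_to_qubo(qp, sc)
    opt <- solve_exhaustive(qb)
    sa <- solve_sa(qb, anneal_schedule(reads = 50, sweeps = 200, seed = trial))
    if (sa$energy <= opt$energy + 1e-9 * (1 + abs(opt$energy))) hits <- hits + 1
  }
  expect_gte(hits, round(0.9 * n_trials))
})

test_that("greedy descent is monotone, deterministic, and 1-flip optimal", {
  # single negative bit: one flip to the optimum
  qb1 <- toy_qubo(matrix(-1, 1, 1))
  g1 <- greedy_descent(qb1, 0L)
  expect_equal(g1$bits, 1L)
  expect_equal(g1$energy, -1)

  # starting at a local minimum returns it unchanged
  opt <- solve_exhaustive(rand_qubo(8, 31))
  g2 <- greedy_descent(rand_qubo(8, 31), opt$bits)
  expect_identical(g2$bits, opt$bits)

  # random starts: never worse than start, and no single flip improves the end
  for (seed in c(61, 62, 63)) {
    qb <- rand_qubo(12, seed)
    set.seed(seed)
    start <- sample(0:1, 12, replace = TRUE)
    g <- greedy_descent(qb, start)
    expect_lte(g$energy, qubo_energy(qb, start) + 1e-12)
    for (k in 1:12) {
      flipped <- g$bits
      flipped[k] <- 1L - flipped[k]
      expect_gte(qubo_energy(qb, flipped), g$energy - 1e-12)
    }
  }
})

test_that("restart wrapper keeps the best attempt and respects early stopping", {
  qb <- rand_qubo(12, 55)
  inner <- function(q, s) solve_sa(q, anneal_schedule(reads = 1, sweeps = 10,
                                                      seed = s))
  one <- solve_with_restarts(inner, qb, max_attempts = 1, seed = 9)
  expect_equal(one$attempts, 1L)
  expect_identical(one$bits, inner(qb, bitwXor(9L, 1L))$bits)

  ten <- solve_with_restarts(inner, qb, max_attempts = 10, seed = 9)
  expect_lte(ten$energy, one$energy)
  expect_equal(ten$attempts, 10L)
  # best-of-k is monotone non-increasing in k along the same seed stream
  expect_equal(ten$energy, min(ten$attempt_energies))
  expect_true(all(diff(cummin(ten$attempt_energies)) <= 0))

  # with an always-satisfied acceptance threshold only one attempt is consumed
  early <- solve_with_restarts(inner, qb, max_attempts = 10, seed = 9,
                               accept_threshold = Inf)
  expect_equal(early$attempts, 1L)
})

test_that("solver quality is ordered: exhaustive <= sa+greedy <= sa", {
  sc <- fp_scheme(6, 15)
  set.seed(77)
  for (trial in 1:5) {
    qp <- euler_cell_qp(y1 = stats::runif(1, 0.8, 2.2),
                        f = stats::runif(1, -1, 1))
    qb <- qp_to_qubo(qp, sc)
    sched <- anneal_schedule(reads = 2, sweeps = 30, seed = trial)
    e_ex <- solve_exhaustive(qb)$energy
    e_sa <- solve_sa(qb, sched)$energy
    e_hy <- solve_sa_greedy(qb, sched)$energy
    expect_lte(e_ex, e_hy + 1e-12)
    expect_lte(e_hy, e_sa + 1e-12)
  }
})

test_that("solver reports serialize to JSON with bits as 0/1 strings", {
  qb <- rand_qubo(6, 3)
  rep <- solve_exhaustive(qb)
  js <- jsonlite::fromJSON(report_to_json(rep))
  expect_identical(js$best_bits, bits_to_string(rep$bits))
  expect_equal(js$best_energy, rep$energy)
})
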