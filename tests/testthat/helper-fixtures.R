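# shared fixtures: toy QUBOs, Euler cells, and an independent brute-force
# minimizer used as the oracle for the C++ enumeration kernel

# wrap a bare upper-triangular matrix as a qubo_problem (1-bit-per-variable
# scheme; decode is irrelevant for pure solver tests)
toy_qubo <- function(Q, offset = 0) {
  structure(
    list(Q = Q, offset = offset, scheme = fp_scheme(1, 0),
         n_vars = nrow(Q), index_map = NULL, labels = NULL),
    class = "qubo_problem"
  )
}

rand_qubo <- function(nbits, seed) {
  set.seed(seed)
  Q <- matrix(0, nbits, nbits)
  Q[upper.tri(Q, diag = TRUE)] <- stats::rnorm(nbits * (nbits + 1) / 2)
  toy_qubo(Q)
}

# independent R-level brute force: full enumeration, energy via matrix algebra
brute_force_min <- function(Q) {
  n <- nrow(Q)
  best_e <- Inf
  best_b <- NULL
  for (s in 0:(2^n - 1)) {
    b <- as.integer(intToBits(s)[1:n])  # little-endian bit order
    e <- drop(t(b) %*% Q %*% b)
    if (e < best_e - 1e-15) {
      best_e <- e
      best_b <- b
    }
  }
  list(energy = best_e, bits = best_b)
}

# one-step single-equation least-squares cell: unknown y2, known y1, constant f
euler_cell_qp <- function(y1, f, dx = 0.4) {
  build_qp(linear_segment(f0 = f, fk = matrix(0, 1, 1), n = 1L),
           dx = dx, m = 1L, y_init = y1)
}

random_spd_qp <- function(n, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n)
  structure(list(H = crossprod(A) + diag(n) * 0.1, d = stats::rnorm(n),
                 offset = stats::rnorm(1), labels = NULL),
            class = "qp_problem")
}

expect_energy_equal <- function(e1, e2, rel = 1e-9) {
  expect_lte(abs(e1 - e2), rel * (1 + abs(e2)))
}
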