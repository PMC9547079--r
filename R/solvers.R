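#' Annealing schedule for the simulated-annealing QUBO solver
#'
#' A classical stand-in for the read/anneal controls of annealing hardware:
#' `reads` independent restarts of a single-bit-flip Metropolis chain, each
#' running `sweeps` full passes over the bits while the temperature is
#' interpolated geometrically from `t_initial` down to `t_final`.
#'
#' When `t_initial` is `NULL` it is set per problem to the largest
#' single-flip `|dE|` from a random probe state (so the first sweeps accept
#' almost any move). When `t_final` is `NULL` it is set to a tenth of the
#' smallest nonzero diagonal magnitude of the QUBO, so that even the
#' weakest-field bits freeze before the anneal ends. A fixed ratio such as
#' `1e-3 * t_initial` is a poor default here because the fixed-point bit
#' weights make the couplings span roughly `2^(2K)` in magnitude: the low
#' bits would still be molten when the schedule stops.
#'
#' @param reads Number of independent chain restarts (>= 1).
#' @param sweeps Metropolis sweeps per read (>= 1).
#' @param t_initial,t_final Initial/final temperatures (> 0,
#'   `t_initial >= t_final`), or `NULL` to derive per problem.
#' @param seed Integer RNG seed.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(reads = 10L, sweeps = 100L,
                            t_initial = NULL, t_final = NULL, seed = 1L) {
  if (reads < 1) stop("reads must be >= 1")
  if (sweeps < 1) stop("sweeps must be >= 1")
  if (!is.null(t_initial) && t_initial <= 0) stop("t_initial must be > 0")
  if (!is.null(t_final) && t_final <= 0) stop("t_final must be > 0")
  if (!is.null(t_initial) && !is.null(t_final) && t_initial < t_final) {
    stop("t_initial must be >= t_final")
  }
  structure(
    list(reads = as.integer(reads), sweeps = as.integer(sweeps),
         t_initial = t_initial, t_final = t_final, seed = as.integer(seed)),
    class = "anneal_schedule"
  )
}

solver_report <- function(bits, energy, attempt_energies, attempts,
                          reads = NA_integer_, seed = NA_integer_,
                          notes = "") {
  structure(
    list(bits = as.integer(bits), energy = energy,
         attempt_energies = attempt_energies, attempts = attempts,
         reads = reads, seed = seed, notes = notes),
    class = "solver_report"
  )
}

#' @export
print.solver_report <- function(x, ...) {
  cat(sprintf("Solver report: best energy %.6g over %d attempt(s)\n",
              x$energy, x$attempts))
  cat(sprintf("  bits: %s\n", bits_to_string(x$bits)))
  if (nzchar(x$notes)) cat(sprintf("  notes: %s\n", x$notes))
  invisible(x)
}

#' Serialize a solver report to JSON
#'
#' @param report A `solver_report`.
#' @param path Optional file path; when `NULL`, the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    best_bits = bits_to_string(report$bits),
    best_energy = report$energy,
    attempt_energies = report$attempt_energies,
    attempts = report$attempts,
    reads = report$reads,
    seed = report$seed,
    notes = report$notes
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Minimize the continuous quadratic program
#'
#' Returns the stationary point of `y' H y + y' d`, i.e. the solution of
#' `(H + H') y = -d`. The least-squares construction guarantees the form is
#' positive semidefinite; after elimination of the initial condition it is
#' positive definite on the problems treated here, so the stationary point is
#' the unique minimizer. A singular system falls back to the least-norm
#' solution (via the pseudoinverse) with a warning.
#'
#' @param qp A `qp_problem`.
#' @return Numeric vector `y*` of the continuous minimizer.
#' @export
solve_qp_continuous <- function(qp) {
  A <- qp$H + t(qp$H)
  y <- tryCatch(
    solve(A, -qp$d),
    error = function(e) {
      warning("singular QP system; returning least-norm solution")
      sv <- svd(A)
      pos <- sv$d > max(sv$d) * 1e-12
      drop(sv$v[, pos, drop = FALSE] %*%
             ((crossprod(sv$u[, pos, drop = FALSE], -qp$d)) / sv$d[pos]))
    }
  )
  drop(y)
}

#' Exhaustive QUBO minimization (ground-truth oracle)
#'
#' Enumerates all `2^k` bit assignments (Gray-code incremental energies) and
#' returns the global minimum. Deterministic; energy ties are broken toward
#' the state with the lowest little-endian integer value (the first bit
#' counts least).
#'
#' @param qubo A `qubo_problem`.
#' @param max_bits Refuse problems larger than this many bits (default 24).
#' @return A `solver_report`.
#' @export
solve_exhaustive <- function(qubo, max_bits = 24L) {
  nb <- nrow(qubo$Q)
  if (nb > max_bits) {
    stop(sprintf("problem has %d bits, exhaustive limit is %d", nb, max_bits))
  }
  res <- exhaustive_min_cpp(qubo$Q)
  solver_report(res$bits, res$energy, attempt_energies = res$energy,
                attempts = 1L, notes = "exhaustive enumeration")
}

#' Simulated-annealing QUBO minimization
#'
#' Single-bit-flip Metropolis chains with geometric cooling; the best state
#' over all reads is returned. Fully reproducible: the chain consumes R's
#' RNG stream after `set.seed(schedule$seed)`.
#'
#' @param qubo A `qubo_problem`.
#' @param schedule An [anneal_schedule()].
#' @param polish Drive each read's best state to its 1-flip local minimum
#'   with greedy descent before comparing reads (used by
#'   [solve_sa_greedy()]).
#' @return A `solver_report` with per-read best energies in
#'   `attempt_energies`.
#' @export
solve_sa <- function(qubo, schedule = anneal_schedule(), polish = FALSE) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  set.seed(schedule$seed)
  t0 <- schedule$t_initial
  if (is.null(t0)) {
    probe <- as.integer(stats::runif(nrow(qubo$Q)) < 0.5)
    t0 <- max_abs_flip_delta_cpp(qubo$Q, probe)
    if (t0 <= 0) t0 <- 1
  }
  t1 <- schedule$t_final
  if (is.null(t1)) {
    dmag <- abs(diag(qubo$Q))
    dmag <- dmag[dmag > 0]
    t1 <- if (length(dmag)) min(dmag) / 10 else 1e-3 * t0
    t1 <- min(t1, t0)
  }
  res <- sa_min_cpp(qubo$Q, schedule$reads, schedule$sweeps, t0, t1,
                    polish = polish)
  solver_report(res$bits, res$energy,
                attempt_energies = as.numeric(res$read_energies),
                attempts = 1L, reads = schedule$reads, seed = schedule$seed,
                notes = sprintf("sa: %d reads x %d sweeps, T %.3g -> %.3g",
                                schedule$reads, schedule$sweeps, t0, t1))
}

#' Greedy single-bit-flip descent
#'
#' Steepest-descent local search: repeatedly flips the single bit giving the
#' largest energy decrease until no flip decreases the energy. The result is
#' a 1-flip local minimum and the energy is non-increasing along the path.
#' Ties are broken toward the lowest bit index, making the search
#' deterministic. Typically used to polish a sampled solution.
#'
#' @param qubo A `qubo_problem`.
#' @param start 0/1 vector, the starting state.
#' @return A `solver_report`.
#' @export
greedy_descent <- function(qubo, start) {
  if (length(start) != nrow(qubo$Q)) stop("start has wrong length")
  res <- greedy_descent_cpp(qubo$Q, as.integer(start))
  solver_report(res$bits, res$energy, attempt_energies = res$energy,
                attempts = 1L,
                notes = sprintf("greedy descent: %d flips", res$n_flips))
}

#' Best-of-several-restarts wrapper
#'
#' Runs an inner solver up to `max_attempts` times with distinct derived
#' seeds (attempt `r` uses `xor(seed, r)`), keeping the solution with the
#' smallest energy. Optionally stops early once the energy reaches
#' `accept_threshold`; by default all attempts run and the overall best is
#' kept.
#'
#' @param solver A function `(qubo, seed) -> solver_report`.
#' @param qubo A `qubo_problem`.
#' @param max_attempts Maximum restarts (>= 1).
#' @param seed Master seed; per-attempt seeds are derived from it.
#' @param accept_threshold Energy at or below which to stop early
#'   (default `-Inf`: never stop early).
#' @return A `solver_report` whose `attempt_energies` lists each attempt's
#'   best energy and whose `attempts` counts attempts actually consumed.
#' @export
solve_with_restarts <- function(solver, qubo, max_attempts = 10L,
                                seed = 1L, accept_threshold = -Inf) {
  if (max_attempts < 1) stop("max_attempts must be >= 1")
  best <- NULL
  energies <- numeric(0)
  used <- 0L
  for (r in seq_len(max_attempts)) {
    attempt_seed <- bitwXor(as.integer(seed), r)
    rep_r <- solver(qubo, attempt_seed)
    used <- used + 1L
    energies <- c(energies, rep_r$energy)
    if (is.null(best) || rep_r$energy < best$energy) best <- rep_r
    if (best$energy <= accept_threshold) break
  }
  solver_report(best$bits, best$energy, attempt_energies = energies,
                attempts = used, reads = best$reads, seed = as.integer(seed),
                notes = sprintf("best of %d attempt(s); inner: %s",
                                used, best$notes))
}

#' Hybrid sample-then-polish solve
#'
#' The headline strategy: sample with simulated annealing and polish each
#' read's best state with [greedy_descent()], keeping the overall best.
#' Greedy never worsens the energy, and on the small per-step problems
#' arising in trajectory propagation this hybrid reliably reaches the
#' exhaustive optimum even with few reads: the sampler places the state in
#' the basin of the global minimum and greedy descends the rest of the way.
#'
#' @inheritParams solve_sa
#' @return A `solver_report`.
#' @export
solve_sa_greedy <- function(qubo, schedule = anneal_schedule()) {
  rep <- solve_sa(qubo, schedule, polish = TRUE)
  rep$notes <- paste(rep$notes, "+ per-read greedy polish")
  rep
}
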