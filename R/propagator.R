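#' Specify a first-order ODE system dy/dx = f(x, y)
#'
#' @param rhs Function `(x, y) -> numeric(n)`, the right-hand side.
#' @param n Number of equations.
#' @param jacobian Optional function `(x, y) -> n x n matrix` of
#'   `df_n / dy_k`. When absent, [linearize()] falls back to central finite
#'   differences.
#' @param scales Optional positive per-variable scale factors (see
#'   [apply_scaling()]).
#' @param weights Optional positive per-equation penalty factors passed to
#'   [build_qp()].
#' @return An object of class `ode_system`.
#' @export
ode_system <- function(rhs, n, jacobian = NULL, scales = NULL, weights = NULL) {
  stopifnot(is.function(rhs), n >= 1)
  if (!is.null(scales) && (length(scales) != n || any(scales <= 0))) {
    stop("scales must be positive, one per variable")
  }
  if (!is.null(weights) && (length(weights) != n || any(weights <= 0))) {
    stop("weights must be positive, one per equation")
  }
  structure(
    list(rhs = rhs, n = as.integer(n), jacobian = jacobian,
         scales = scales, weights = weights),
    class = "ode_system"
  )
}

#' Equidistant time grid
#'
#' @param t0 Start abscissa.
#' @param dt Step size (> 0).
#' @param steps Number of propagation steps `S` (>= 1); the grid has
#'   `S + 1` points `t0 + (i-1) dt`, `i = 1 .. S+1`.
#' @return An object of class `time_grid` with a `times` vector.
#' @export
time_grid <- function(t0 = 0, dt, steps) {
  if (!(dt > 0)) stop("dt must be > 0")
  if (steps < 1) stop("steps must be >= 1")
  steps <- as.integer(steps)
  structure(
    list(t0 = t0, dt = dt, steps = steps,
         times = t0 + dt * (seq_len(steps + 1L) - 1L)),
    class = "time_grid"
  )
}

#' Propagation configuration
#'
#' @param m Grid points solved per run (>= 1). At `m = 1` the right-hand
#'   side values are fully known from the previous step, every equation
#'   decouples, and the continuous minimizer reduces to one explicit
#'   forward-Euler step.
#' @param mode `"sequential"` solves one equation at a time (requires
#'   `m = 1`); `"coupled"` solves all equations of a run jointly.
#' @param scheme [fp_scheme()] used by the binary solvers.
#' @param solver One of `"qp"` (continuous reference), `"exhaustive"`,
#'   `"sa"`, `"sa_greedy"`.
#' @param schedule [anneal_schedule()] for the annealing solvers.
#' @param attempts Restart attempts per task (>= 1); the best-energy
#'   solution over the attempts is kept.
#' @param seed Master seed for the stochastic solvers; per-step, per-equation
#'   and per-attempt seeds are derived from it.
#' @param gauss_seidel In sequential mode, use freshly solved components of
#'   the current step when evaluating the right-hand side for later
#'   equations (default `FALSE`: all right-hand sides use the previous
#'   step's state).
#' @return An object of class `propagation_config`.
#' @export
propagation_config <- function(m = 1L,
                               mode = c("sequential", "coupled"),
                               scheme = fp_scheme(6, 15),
                               solver = c("qp", "exhaustive", "sa", "sa_greedy"),
                               schedule = anneal_schedule(),
                               attempts = 1L,
                               seed = 1L,
                               gauss_seidel = FALSE) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  if (m < 1) stop("m must be >= 1")
  if (mode == "sequential" && m != 1) {
    stop("sequential mode propagates one grid point at a time (m = 1)")
  }
  if (attempts < 1) stop("attempts must be >= 1")
  structure(
    list(m = as.integer(m), mode = mode, scheme = scheme, solver = solver,
         schedule = schedule, attempts = as.integer(attempts),
         seed = as.integer(seed), gauss_seidel = isTRUE(gauss_seidel)),
    class = "propagation_config"
  )
}

#' Linearize a right-hand side around a state
#'
#' First-order Taylor expansion of `f(x, y)` at `(x0, y0)`:
#' `f(x, y) ~ f0 + J y` with `J = df/dy |_(x0,y0)` and
#' `f0 = f(x0, y0) - J y0`. When the system supplies no Jacobian, `J` is
#' estimated by central finite differences with step `1e-6` per component.
#'
#' @param system An [ode_system()].
#' @param x0 Abscissa of the expansion point.
#' @param y0 State at the expansion point.
#' @param fd_step Finite-difference step for the numerical Jacobian.
#' @return A [linear_segment()] with `f0` and `fk = J`.
#' @export
linearize <- function(system, x0, y0, fd_step = 1e-6) {
  n <- system$n
  f <- system$rhs(x0, y0)
  if (length(f) != n) stop("rhs returned wrong length")
  if (!is.null(system$jacobian)) {
    J <- system$jacobian(x0, y0)
    if (!all(dim(J) == c(n, n))) stop("jacobian has wrong shape")
  } else {
    J <- matrix(0, n, n)
    for (k in seq_len(n)) {
      yp <- y0; yp[k] <- yp[k] + fd_step
      ym <- y0; ym[k] <- ym[k] - fd_step
      J[, k] <- (system$rhs(x0, yp) - system$rhs(x0, ym)) / (2 * fd_step)
    }
  }
  linear_segment(f0 = f - drop(J %*% y0), fk = J, n = n)
}

# derive a sub-2^31 seed for (step, equation) tasks from the master seed
derive_seed <- function(master, step, eq = 0L) {
  as.integer((as.numeric(master) + 7919 * step + 104729 * eq) %% 2147483647)
}

solve_task <- function(qp, config, task_seed) {
  if (config$solver == "qp") {
    y <- solve_qp_continuous(qp)
    return(list(y = y, energy = qp_energy(qp, y), attempts = 1L))
  }
  qubo <- qp_to_qubo(qp, config$scheme)
  inner <- switch(config$solver,
    exhaustive = function(q, s) solve_exhaustive(q),
    sa = function(q, s) {
      sched <- config$schedule
      sched$seed <- s
      solve_sa(q, sched)
    },
    sa_greedy = function(q, s) {
      sched <- config$schedule
      sched$seed <- s
      solve_sa_greedy(q, sched)
    }
  )
  rep <- if (config$attempts == 1L || config$solver == "exhaustive") {
    inner(qubo, task_seed)
  } else {
    solve_with_restarts(inner, qubo, max_attempts = config$attempts,
                        seed = task_seed)
  }
  list(y = decode_solution(qubo, rep$bits),
       energy = rep$energy + qubo$offset,
       attempts = rep$attempts)
}

check_in_range <- function(y, scheme, step) {
  rng <- fp_range(scheme)
  if (any(y < rng$min - rng$max_rounding_error |
          y > rng$max + rng$max_rounding_error)) {
    stop(sprintf(
      "state out of representable range [%g, %g] at step %d (encoding saturation)",
      rng$min, rng$max, step
    ), call. = FALSE)
  }
}

# a decoded solution sitting on the edge of the lattice means the true
# minimizer lay at or beyond the representable boundary: the encoding has
# saturated and continuing would silently clamp the trajectory
check_not_saturated <- function(y, scheme, step) {
  rng <- fp_range(scheme)
  tol <- 2^(-scheme$k_frac - 1)
  if (any(y <= rng$min + tol | y >= rng$max - tol)) {
    stop(sprintf(
      "decoded state reached the representable boundary [%g, %g] at step %d (encoding saturation)",
      rng$min, rng$max, step
    ), call. = FALSE)
  }
}

#' Propagate a trajectory by repeated quadratic minimization
#'
#' Walks the time grid in chunks of `m` steps. At each chunk start the
#' right-hand side is linearized about the current state ([linearize()]),
#' the chunk's least-squares functional is assembled ([build_qp()]), the
#' configured backend minimizes it (continuously, or over the fixed-point
#' bit lattice after [qp_to_qubo()]), and the decoded grid values extend the
#' trajectory. In sequential mode each equation's one-step cell is solved
#' independently using the previous step's full state.
#'
#' With the `"qp"` backend and `m = 1` the method is algebraically identical
#' to explicit forward Euler: the single squared residual is minimized
#' exactly by `y_{i+1} = y_i + dt f(x_i, y_i)`.
#'
#' @param system An [ode_system()].
#' @param grid A [time_grid()].
#' @param y_init Initial state (length `n`).
#' @param config A [propagation_config()].
#' @return An object of class `trajectory`: list with `times`, `values`
#'   (matrix `(steps+1) x n`, first row equals `y_init`), `diagnostics`
#'   (data.frame with per-step functional value and attempts), and the
#'   `config`.
#' @export
propagate <- function(system, grid, y_init,
                      config = propagation_config()) {
  stopifnot(inherits(system, "ode_system"), inherits(grid, "time_grid"))
  n <- system$n
  if (length(y_init) != n) stop("y_init must have length n")
  s <- grid$steps
  dt <- grid$dt
  values <- matrix(NA_real_, s + 1L, n)
  values[1L, ] <- y_init
  energies <- rep(NA_real_, s)
  attempts <- rep(NA_integer_, s)
  weights <- system$weights
  binary <- config$solver != "qp"

  i <- 1L
  while (i <= s) {
    x_cur <- grid$times[i]
    y_cur <- values[i, ]
    if (binary) check_in_range(y_cur, config$scheme, i)
    m_chunk <- min(config$m, s - i + 1L)
    if (config$mode == "sequential") {
      f_all <- system$rhs(x_cur, y_cur)
      y_new <- y_cur
      e_tot <- 0
      att <- 0L
      for (nn in seq_len(n)) {
        f_n <- if (config$gauss_seidel) system$rhs(x_cur, y_new)[nn] else f_all[nn]
        seg <- linear_segment(f0 = f_n, fk = matrix(0, 1, 1), n = 1L)
        qp <- build_qp(seg, dx = dt, m = 1L, y_init = y_cur[nn],
                       weights = if (is.null(weights)) NULL else weights[nn])
        res <- solve_task(qp, config, derive_seed(config$seed, i, nn))
        if (binary) check_not_saturated(res$y, config$scheme, i)
        y_new[nn] <- res$y
        e_tot <- e_tot + res$energy
        att <- att + res$attempts
      }
      values[i + 1L, ] <- y_new
      energies[i] <- e_tot
      attempts[i] <- att
      i <- i + 1L
    } else {
      seg <- linearize(system, x_cur, y_cur)
      qp <- build_qp(seg, dx = dt, m = m_chunk, y_init = y_cur,
                     weights = weights)
      res <- solve_task(qp, config, derive_seed(config$seed, i))
      pts <- matrix(res$y, nrow = m_chunk, ncol = n, byrow = TRUE)
      if (binary) check_not_saturated(pts, config$scheme, i)
      values[i + seq_len(m_chunk), ] <- pts
      energies[i:(i + m_chunk - 1L)] <- res$energy / m_chunk
      attempts[i:(i + m_chunk - 1L)] <- res$attempts
      i <- i + m_chunk
    }
  }
  structure(
    list(times = grid$times, values = values,
         diagnostics = data.frame(step = seq_len(s), energy = energies,
                                  attempts = attempts),
         config = config),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d steps, %d variable(s), solver '%s' (%s mode)\n",
              nrow(x$values) - 1L, ncol(x$values),
              x$config$solver, x$config$mode))
  cat(sprintf("  t in [%g, %g]; mean per-step functional %.3g\n",
              x$times[1], x$times[length(x$times)],
              mean(x$diagnostics$energy, na.rm = TRUE)))
  invisible(x)
}

#' Rescale the variables of an ODE system
#'
#' Changes variables to `z_n = y_n / s_n`, transforming the right-hand sides
#' to `g_n(x, z) = f_n(x, s * z) / s_n` (and the Jacobian accordingly).
#' Rescaling equalizes the contributions the different equations make to the
#' least-squares functional when their natural ranges differ — e.g. position
#' and momentum of a heavy oscillator — which matters for the binary solvers
#' because all variables share one fixed-point scheme. Propagating the
#' scaled system and multiplying back by `s` reproduces the unscaled
#' continuous-backend trajectory exactly.
#'
#' @param system An [ode_system()].
#' @param scales Positive scale factors, one per variable.
#' @return A new `ode_system` in the scaled variables (with `scales`
#'   recorded for [unscale_trajectory()]).
#' @export
apply_scaling <- function(system, scales) {
  n <- system$n
  if (length(scales) != n || any(!is.finite(scales)) || any(scales <= 0)) {
    stop("scales must be positive and finite, one per variable")
  }
  rhs0 <- system$rhs
  jac0 <- system$jacobian
  rhs_scaled <- function(x, z) rhs0(x, scales * z) / scales
  jac_scaled <- if (is.null(jac0)) NULL else function(x, z) {
    J <- jac0(x, scales * z)
    sweep(J, 1, scales, "/") * rep(scales, each = n)
  }
  ode_system(rhs_scaled, n, jacobian = jac_scaled, scales = scales,
             weights = system$weights)
}

#' Undo variable scaling on a propagated trajectory
#'
#' @param traj A `trajectory` obtained from a system produced by
#'   [apply_scaling()].
#' @param scales The scale factors used.
#' @return The trajectory with `values` multiplied back to original units.
#' @export
unscale_trajectory <- function(traj, scales) {
  traj$values <- sweep(traj$values, 2, scales, "*")
  traj
}
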