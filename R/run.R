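#' Assemble a validated run configuration
#'
#' Bundles every knob of a trajectory run into one echoing record. The
#' defaults reproduce the low-energy H2 benchmark: a Morse bond started at
#' `r0 = 1.3` Bohr with `p0 = 0`, propagated for 400 a.u. of time in 1000
#' equal steps (about 10 attoseconds each), one equation at a time.
#'
#' @param system `"morse-h2"`, `"harmonic"`, or an [ode_system()] for a
#'   user-supplied system.
#' @param y_init Initial state; for `"morse-h2"` defaults to `c(r0, p0)`.
#' @param r0,p0 Morse initial bond length (Bohr) and momentum (a.u.).
#' @param t_total Total propagated time (a.u.).
#' @param steps Number of time steps `S` (`dt = t_total / steps`).
#' @param mode `"sequential"` or `"coupled"`.
#' @param m Grid points per run.
#' @param k_int,k_frac Fixed-point bits (integer/fractional).
#' @param solver `"qp"`, `"exhaustive"`, `"sa"`, or `"sa_greedy"`.
#' @param attempts Restart attempts per task.
#' @param reads,sweeps Annealing schedule knobs.
#' @param seed Master seed.
#' @param scales Optional per-variable scale factors.
#' @param morse Optional [morse_parameters()] override.
#' @param harmonic_k,harmonic_mu Harmonic fixture stiffness and mass.
#' @return An object of class `run_config`.
#' @export
run_config <- function(system = "morse-h2",
                       y_init = NULL, r0 = 1.3, p0 = 0,
                       t_total = 400, steps = 1000L,
                       mode = "sequential", m = 1L,
                       k_int = 6L, k_frac = 15L,
                       solver = "qp", attempts = 1L,
                       reads = 10L, sweeps = 100L, seed = 1L,
                       scales = NULL, morse = morse_parameters(),
                       harmonic_k = 1, harmonic_mu = 1) {
  if (!(t_total > 0)) stop("t_total must be > 0")
  if (steps < 1) stop("steps must be >= 1")
  if (is.character(system) && !system %in% c("morse-h2", "harmonic")) {
    stop("system must be 'morse-h2', 'harmonic', or an ode_system")
  }
  if (identical(system, "morse-h2") && r0 <= 0) stop("r0 must be positive")
  structure(
    list(system = system, y_init = y_init, r0 = r0, p0 = p0,
         t_total = t_total, steps = as.integer(steps), mode = mode,
         m = as.integer(m), k_int = as.integer(k_int),
         k_frac = as.integer(k_frac), solver = solver,
         attempts = as.integer(attempts), reads = as.integer(reads),
         sweeps = as.integer(sweeps), seed = as.integer(seed),
         scales = scales, morse = morse,
         harmonic_k = harmonic_k, harmonic_mu = harmonic_mu),
    class = "run_config"
  )
}

#' Harmonic oscillator test system
#'
#' `dr/dt = p/mu`, `dp/dt = -k r`: the naturally linear fixture, with closed
#' form `r(t) = r0 cos(w t) + (p0 / (mu w)) sin(w t)`, `w = sqrt(k / mu)`.
#'
#' @param k Stiffness.
#' @param mu Mass.
#' @return An [ode_system()] with `n = 2`.
#' @export
harmonic_system <- function(k = 1, mu = 1) {
  ode_system(
    rhs = function(x, y) c(y[2] / mu, -k * y[1]),
    n = 2L,
    jacobian = function(x, y) matrix(c(0, -k, 1 / mu, 0), 2, 2)
  )
}

#' Closed-form harmonic reference
#'
#' @param times Evaluation times.
#' @param r0,p0 Initial state.
#' @inheritParams harmonic_system
#' @return Matrix with columns `t`, `r`, `p`.
#' @export
harmonic_reference <- function(times, r0, p0, k = 1, mu = 1) {
  w <- sqrt(k / mu)
  cbind(t = times,
        r = r0 * cos(w * times) + p0 / (mu * w) * sin(w * times),
        p = -r0 * mu * w * sin(w * times) + p0 * cos(w * times))
}

materialize_config <- function(config) {
  if (is.character(config$system) && config$system == "morse-h2") {
    system <- morse_system(config$morse)
    y_init <- if (is.null(config$y_init)) c(config$r0, config$p0) else config$y_init
    ref_fun <- function(times) {
      reference_trajectory(config$morse, y_init[1], y_init[2], times)
    }
    var_names <- c("r_bohr", "p_au")
  } else if (is.character(config$system) && config$system == "harmonic") {
    system <- harmonic_system(config$harmonic_k, config$harmonic_mu)
    y_init <- if (is.null(config$y_init)) c(config$r0, config$p0) else config$y_init
    ref_fun <- function(times) {
      harmonic_reference(times, y_init[1], y_init[2],
                         config$harmonic_k, config$harmonic_mu)
    }
    var_names <- c("r", "p")
  } else {
    system <- config$system
    y_init <- config$y_init
    if (is.null(y_init)) stop("y_init is required for a user-supplied system")
    ref_fun <- NULL
    var_names <- paste0("y", seq_len(system$n))
  }
  scales <- config$scales
  if (!is.null(scales)) system <- apply_scaling(system, scales)
  pcfg <- propagation_config(
    m = config$m, mode = config$mode,
    scheme = fp_scheme(config$k_int, config$k_frac),
    solver = config$solver,
    schedule = anneal_schedule(reads = config$reads, sweeps = config$sweeps,
                               seed = config$seed),
    attempts = config$attempts, seed = config$seed
  )
  list(system = system, y_init = y_init, ref_fun = ref_fun,
       var_names = var_names, pcfg = pcfg, scales = scales)
}

config_echo <- function(config) {
  e <- config[setdiff(names(config), c("morse", "system", "y_init"))]
  e$system <- if (is.character(config$system)) config$system else "custom"
  e$morse <- if (identical(config$system, "morse-h2")) {
    config$morse[c("De", "a", "re", "mu")]
  } else NULL
  e
}

#' Run one configured trajectory and write its outputs
#'
#' Propagates the configured system and writes a trajectory CSV (`time_au`
#' plus one column per variable) and a JSON report (config echo, per-step
#' functional values, attempts, seed, and coordinate RMSE against the
#' reference when one is defined). Deterministic given the seed: re-running
#' the same configuration reproduces the files byte for byte.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing). `NULL` skips file
#'   output.
#' @return Invisibly, a list with the `trajectory`, the `rmse` (or `NA`),
#'   and the output `files`.
#' @export
run_trajectory <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  mat <- materialize_config(config)
  grid <- time_grid(0, config$t_total / config$steps, config$steps)
  y_start <- if (is.null(mat$scales)) mat$y_init else mat$y_init / mat$scales
  traj <- propagate(mat$system, grid, y_start, mat$pcfg)
  if (!is.null(mat$scales)) traj <- unscale_trajectory(traj, mat$scales)
  rmse <- NA_real_
  if (!is.null(mat$ref_fun)) {
    rmse <- trajectory_rmse(traj, mat$ref_fun(grid$times))
  }
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, "trajectory.csv")
    df <- data.frame(time_au = traj$times, traj$values)
    names(df) <- c("time_au", mat$var_names)
    utils::write.csv(df, csv, row.names = FALSE)
    js <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(config = config_echo(config),
           rmse = rmse,
           classification = if (is.na(rmse)) NULL else classify_accuracy(rmse),
           steps = list(energy = traj$diagnostics$energy,
                        attempts = traj$diagnostics$attempts)),
      js, auto_unbox = TRUE, digits = NA, na = "null"
    )
    files <- c(trajectory = csv, report = js)
  }
  invisible(list(trajectory = traj, rmse = rmse, files = files))
}

#' Run a grid-refinement convergence experiment and write its table
#'
#' @param config A [run_config()] (its solver field is ignored; the
#'   `solvers` list decides the series).
#' @param grid_sizes Strictly increasing step counts.
#' @param solvers Character vector of backend labels (subset of `"qp"`,
#'   `"exhaustive"`, `"sa"`, `"sa_greedy"`), or a named list of
#'   [propagation_config()]s for full control. For the character form,
#'   `"sa"` uses 1 attempt and `"sa_x10"` may be included for best-of-10.
#' @param out_file Optional CSV path for the tidy table.
#' @return The convergence `data.frame` (columns `solver`, `grid_points`,
#'   `rmse`, `mean_epsilon`, `attempts_mean`, `status`).
#' @export
run_convergence <- function(config = run_config(), grid_sizes,
                            solvers = c("qp", "sa", "sa_x10", "sa_greedy"),
                            out_file = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (length(grid_sizes) == 0) stop("grid_sizes must not be empty")
  mat <- materialize_config(config)
  if (is.null(mat$ref_fun)) stop("convergence experiments need a reference")
  if (is.character(solvers)) {
    scheme <- fp_scheme(config$k_int, config$k_frac)
    mk <- function(solver, attempts = 1L) {
      propagation_config(
        m = config$m, mode = config$mode, scheme = scheme, solver = solver,
        schedule = anneal_schedule(reads = config$reads,
                                   sweeps = config$sweeps,
                                   seed = config$seed),
        attempts = attempts, seed = config$seed
      )
    }
    cfgs <- list()
    for (s in solvers) {
      cfgs[[s]] <- switch(s,
        qp = mk("qp"),
        exhaustive = mk("exhaustive"),
        sa = mk("sa"),
        sa_x10 = mk("sa", attempts = 10L),
        sa_greedy = mk("sa_greedy"),
        stop(sprintf("unknown solver label '%s'", s))
      )
    }
    solvers <- cfgs
  }
  tab <- convergence_sweep(mat$system, mat$y_init, config$t_total,
                           grid_sizes, solvers, mat$ref_fun)
  if (!is.null(out_file)) {
    utils::write.csv(tab, out_file, row.names = FALSE)
  }
  tab
}

#' Export the QUBO of one propagation step
#'
#' Re-plays the configured trajectory up to `step`, builds that step's QUBO
#' exactly as [propagate()] would, and writes it as a plain-text coordinate
#' list plus JSON index map (see [write_qubo()]).
#'
#' @param config A [run_config()].
#' @param step Step index (1-based, <= steps).
#' @param path Output path for the coordinate list.
#' @return The `qubo_problem`, invisibly.
#' @export
export_qubo <- function(config, step, path) {
  stopifnot(inherits(config, "run_config"))
  if (step < 1 || step > config$steps) {
    stop(sprintf("step must be in 1..%d", config$steps))
  }
  mat <- materialize_config(config)
  dt <- config$t_total / config$steps
  y_cur <- mat$y_init
  if (!is.null(mat$scales)) y_cur <- y_cur / mat$scales
  # walk with the continuous backend up to the requested step
  if (step > 1) {
    grid <- time_grid(0, dt, step - 1L)
    cfg_qp <- mat$pcfg
    cfg_qp$solver <- "qp"
    traj <- propagate(mat$system, grid, y_cur, cfg_qp)
    y_cur <- traj$values[step, ]
  }
  x_cur <- dt * (step - 1)
  if (mat$pcfg$mode == "sequential") {
    # concatenate the per-equation one-step cells into one block-diagonal QUBO
    f_all <- mat$system$rhs(x_cur, y_cur)
    qps <- lapply(seq_len(mat$system$n), function(nn) {
      seg <- linear_segment(f0 = f_all[nn], fk = matrix(0, 1, 1), n = 1L)
      build_qp(seg, dx = dt, m = 1L, y_init = y_cur[nn])
    })
    H <- as.matrix(Matrix_bdiag(lapply(qps, `[[`, "H")))
    qp <- structure(
      list(H = H, d = unlist(lapply(qps, `[[`, "d")),
           offset = sum(vapply(qps, `[[`, numeric(1), "offset")),
           labels = NULL),
      class = "qp_problem"
    )
  } else {
    seg <- linearize(mat$system, x_cur, y_cur)
    qp <- build_qp(seg, dx = dt, m = min(mat$pcfg$m, config$steps - step + 1L),
                   y_init = y_cur)
  }
  qubo <- qp_to_qubo(qp, mat$pcfg$scheme)
  write_qubo(qubo, path)
  invisible(qubo)
}

# tiny block-diagonal helper (dense; per-step problems are small)
Matrix_bdiag <- function(mats) {
  sizes <- vapply(mats, nrow, integer(1))
  total <- sum(sizes)
  out <- matrix(0, total, total)
  at <- 0L
  for (m in mats) {
    idx <- at + seq_len(nrow(m))
    out[idx, idx] <- m
    at <- at + nrow(m)
  }
  out
}
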