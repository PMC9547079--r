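#' Root-mean-square error of a trajectory against a reference
#'
#' Computed on the coordinate only (variable 1 by default), in its native
#' units (Bohr for the Morse bond):
#' `sqrt(mean((y_i - y_ref_i)^2))` over all `S + 1` grid points. Reference
#' values must be given at the same grid times; no interpolation is
#' performed. A momentum-inclusive variant is available by passing all
#' variable indices with weights.
#'
#' @param traj A `trajectory` (or numeric matrix of values).
#' @param ref Reference values: output of [reference_trajectory()] (columns
#'   `t`, `r`, `p`), a `trajectory`, or a numeric matrix/vector aligned with
#'   the grid.
#' @param variables Column indices of the compared variables (default `1`,
#'   coordinate only).
#' @param weights Optional per-variable weights for a multi-variable RMSE
#'   (default equal).
#' @return RMSE (same units as the compared variable).
#' @export
trajectory_rmse <- function(traj, ref, variables = 1L, weights = NULL) {
  vals <- if (inherits(traj, "trajectory")) traj$values else as.matrix(traj)
  refm <- if (inherits(ref, "trajectory")) {
    ref$values
  } else {
    rm <- as.matrix(ref)
    if (!is.null(colnames(rm)) && all(c("r", "p") %in% colnames(rm))) {
      rm <- rm[, c("r", "p"), drop = FALSE]
    }
    rm
  }
  if (nrow(refm) != nrow(vals)) {
    stop(sprintf("grid mismatch: trajectory has %d points, reference %d",
                 nrow(vals), nrow(refm)))
  }
  if (is.null(weights)) weights <- rep(1, length(variables))
  if (length(weights) != length(variables)) {
    stop("weights must match variables")
  }
  sq <- 0
  for (idx in seq_along(variables)) {
    v <- variables[idx]
    sq <- sq + weights[idx] * (vals[, v] - refm[, v])^2
  }
  sqrt(mean(sq / sum(weights)))
}

#' Classify a trajectory RMSE as accurate or inaccurate
#'
#' An "accurate" trajectory has coordinate RMSE strictly below
#' `threshold` (default 1e-2 Bohr).
#'
#' @param rmse Non-negative RMSE value (Bohr).
#' @param threshold Accuracy threshold (Bohr).
#' @return `"accurate"` or `"inaccurate"`.
#' @export
classify_accuracy <- function(rmse, threshold = 1e-2) {
  if (any(rmse < 0)) stop("rmse must be non-negative")
  ifelse(rmse < threshold, "accurate", "inaccurate")
}

#' Grid-refinement convergence experiment
#'
#' Propagates a system over a fixed total time at a series of grid sizes
#' with one or more solver backends, and reports the coordinate RMSE against
#' a reference at each size. A propagation failure (e.g. encoding
#' saturation) is recorded as a failed row and the sweep continues.
#'
#' @param system An [ode_system()].
#' @param y_init Initial state.
#' @param t_total Total propagated time; `dt = t_total / S` at grid size `S`.
#' @param grid_sizes Integer vector (>= 2 entries) of step counts `S`,
#'   strictly increasing.
#' @param solvers Named list of [propagation_config()]s, one per series
#'   (names label the `solver` column).
#' @param reference Function `(times) -> matrix` returning reference values
#'   (first column may be time; coordinate must be the compared column).
#' @param variables Variable indices compared in the RMSE (default 1).
#' @return A `data.frame` with columns `solver`, `grid_points`, `rmse`,
#'   `mean_epsilon`, `attempts_mean`, `status`.
#' @export
convergence_sweep <- function(system, y_init, t_total, grid_sizes, solvers,
                              reference, variables = 1L) {
  if (length(grid_sizes) < 2) stop("grid_sizes needs at least 2 entries")
  if (is.unsorted(grid_sizes, strictly = TRUE)) {
    stop("grid_sizes must be strictly increasing")
  }
  if (is.null(names(solvers)) || any(!nzchar(names(solvers)))) {
    stop("solvers must be a named list of propagation configs")
  }
  rows <- list()
  for (label in names(solvers)) {
    cfg <- solvers[[label]]
    for (s in grid_sizes) {
      grid <- time_grid(0, t_total / s, s)
      row <- tryCatch({
        traj <- propagate(system, grid, y_init, cfg)
        ref <- reference(grid$times)
        data.frame(
          solver = label, grid_points = s,
          rmse = trajectory_rmse(traj, ref, variables = variables),
          mean_epsilon = mean(traj$diagnostics$energy, na.rm = TRUE),
          attempts_mean = mean(traj$diagnostics$attempts, na.rm = TRUE),
          status = "ok", stringsAsFactors = FALSE
        )
      }, error = function(e) {
        data.frame(solver = label, grid_points = s, rmse = NA_real_,
                   mean_epsilon = NA_real_, attempts_mean = NA_real_,
                   status = paste("failed:", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Log-log convergence slope
#'
#' Least-squares slope of `log(error)` against `log(dt)`; a first-order
#' scheme gives a slope of about 1.
#'
#' @param dt Step sizes.
#' @param err Corresponding errors (> 0).
#' @return Fitted slope.
#' @export
convergence_slope <- function(dt, err) {
  if (length(dt) != length(err) || length(dt) < 2) {
    stop("need matching dt and err with at least 2 points")
  }
  unname(stats::coef(stats::lm(log(err) ~ log(dt)))[2])
}
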