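#' Linear segment of an ODE right-hand side
#'
#' Within one propagation run the right-hand side of each equation is taken
#' to be (at most) linear in the state,
#' `f_n(x, y) = f0_n(x) + sum_k fk_{nk}(x) y_k`, which keeps the
#' least-squares functional of the discretized system exactly quadratic.
#'
#' @param f0 Constant coefficients: either a length-`n` vector (the same at
#'   every grid point) or an `n x m` matrix with one column per grid point.
#' @param fk Linear coefficients: an `n x n` matrix (constant over the
#'   segment) or an `n x n x m` array.
#' @param n Number of equations.
#' @return An object of class `linear_segment`.
#' @export
linear_segment <- function(f0, fk = NULL, n = NULL) {
  if (is.null(n)) n <- if (is.matrix(f0)) nrow(f0) else length(f0)
  f0 <- as.matrix(f0)
  if (nrow(f0) != n) stop("f0 must have one row per equation")
  if (is.null(fk)) fk <- matrix(0, n, n)
  if (is.matrix(fk)) {
    if (!all(dim(fk) == c(n, n))) stop("fk must be n x n")
  } else if (length(dim(fk)) == 3L) {
    if (!all(dim(fk)[1:2] == c(n, n))) stop("fk must be n x n x m")
  } else {
    stop("fk must be a matrix or 3-d array")
  }
  structure(list(n = n, f0 = f0, fk = fk), class = "linear_segment")
}

segment_coef <- function(segment, i, m) {
  # coefficients at interior step i (1-based), recycling constant forms
  f0 <- if (ncol(segment$f0) == 1L) segment$f0[, 1L] else segment$f0[, i]
  fk <- if (is.matrix(segment$fk)) segment$fk else segment$fk[, , i]
  list(f0 = f0, fk = fk)
}

#' Build the quadratic least-squares functional for one segment
#'
#' Discretizes `dy/dx = f(x, y)` on `m` steps of size `dx` with a first-order
#' finite difference and forms the total squared residual
#' \deqn{\epsilon(\bar y) = \sum_{i=1}^{m}\sum_{n=1}^{N} w_n
#'   \left(\frac{y_{n,i+1}-y_{n,i}}{\Delta x} - f_{n,i}\right)^2}
#' as an explicit quadratic form `y' H y + y' d + offset` over the unknown
#' grid values. The known initial point is eliminated by substitution: its
#' contributions are folded into the linear term and the constant offset, so
#' the functional stays exactly quadratic and its minimizer over the reals
#' coincides with the least-squares solution of the discretized system.
#'
#' Unknowns are ordered grid-point-major: `y_{1,2}, ..., y_{N,2}, y_{1,3}, ...`
#' (grid point `i = 2 .. m+1`, equation `n = 1 .. N`).
#'
#' @param segment A [linear_segment()].
#' @param dx Grid step (> 0).
#' @param m Number of propagation steps in this run (>= 1).
#' @param y_init Known state at the first grid point (length `n`).
#' @param weights Optional per-equation penalty factors (default all 1).
#' @return An object of class `qp_problem`: list with symmetric matrix `H`,
#'   vector `d`, scalar `offset`, and `labels` (data.frame of `(eq, point)`
#'   per unknown).
#' @export
build_qp <- function(segment, dx, m, y_init, weights = NULL) {
  stopifnot(inherits(segment, "linear_segment"))
  n <- segment$n
  if (!(length(dx) == 1L && is.finite(dx) && dx > 0)) stop("dx must be > 0")
  if (m < 1) stop("m must be >= 1")
  if (length(y_init) != n) stop("y_init must have length n")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    stop("weights must be positive, one per equation")
  }

  n_unknown <- n * m
  # residual r_{n,i} = (y_{n,i+1} - y_{n,i})/dx - f0_n - sum_k fk_{nk} y_{k,i}
  # linear in unknowns: r = A u + b; H = A' W A, d = 2 A' W b, offset = b' W b
  n_res <- n * m
  A <- matrix(0, n_res, n_unknown)
  b <- numeric(n_res)
  w <- numeric(n_res)
  col_of <- function(eq, point) (point - 2L) * n + eq  # point in 2..m+1
  row <- 0L
  for (i in seq_len(m)) {
    cf <- segment_coef(segment, i, m)
    for (nn in seq_len(n)) {
      row <- row + 1L
      w[row] <- weights[nn]
      A[row, col_of(nn, i + 1L)] <- A[row, col_of(nn, i + 1L)] + 1 / dx
      b[row] <- b[row] - cf$f0[nn]
      if (i == 1L) {
        b[row] <- b[row] - y_init[nn] / dx - sum(cf$fk[nn, ] * y_init)
      } else {
        A[row, col_of(nn, i)] <- A[row, col_of(nn, i)] - 1 / dx
        for (k in seq_len(n)) {
          A[row, col_of(k, i)] <- A[row, col_of(k, i)] - cf$fk[nn, k]
        }
      }
    }
  }
  WA <- A * w
  H <- crossprod(A, WA)
  d <- 2 * crossprod(WA, b)[, 1L]
  offset <- sum(w * b^2)
  labels <- data.frame(
    eq = rep(seq_len(n), m),
    point = rep(seq.int(2L, m + 1L), each = n)
  )
  structure(
    list(H = H, d = d, offset = offset, labels = labels, dx = dx,
         m = m, n = n, y_init = y_init),
    class = "qp_problem"
  )
}

#' Evaluate the quadratic functional of a QP problem
#'
#' @param qp A `qp_problem`.
#' @param y Vector of unknown values.
#' @param include_offset Include the constant term (default `TRUE`).
#' @return The functional value `y' H y + y' d (+ offset)`.
#' @export
qp_energy <- function(qp, y, include_offset = TRUE) {
  stopifnot(length(y) == nrow(qp$H))
  e <- drop(t(y) %*% qp$H %*% y + sum(qp$d * y))
  if (include_offset) e <- e + qp$offset
  e
}

#' Compile a quadratic program to a QUBO over fixed-point bits
#'
#' Substitutes the signed fixed-point representation of each continuous
#' unknown into `y' H y + y' d` and collects coefficients of the binary
#' variables. Each element of `H` expands into a `K x K` block; the element
#' at block position `(j, j')` of block `(i, i')` is
#' `2^(-(j+j')) H_{ii'}`, except on the overall diagonal
#' (`i = i'` and `j = j'`) where, using `q^2 = q`, the entry becomes
#' \deqn{2^{-2j} H_{ii} + 2^{-j} d_i - \sum_k 2^{K_I-1-j} (H_{ik} + H_{ki}).}
#' The constant generated by the offsets, `2^{2(K_I-1)} \sum H -
#' 2^{K_I-1} \sum d`, is accumulated into the QUBO offset (together with the
#' incoming QP offset) so that energies are directly comparable between the
#' continuous and binary representations.
#'
#' @param qp A `qp_problem` (or any list with `H`, `d`, `offset`).
#' @param scheme An [fp_scheme()].
#' @return An object of class `qubo_problem`: upper-triangular matrix `Q`,
#'   scalar `offset`, the `scheme`, `n_vars` continuous slots, and an
#'   `index_map` data.frame with one row per bit (`var`, `bit`, `j`, `flat`).
#' @export
qp_to_qubo <- function(qp, scheme) {
  stopifnot(inherits(scheme, "fp_scheme"))
  H <- qp$H
  d <- qp$d
  nv <- nrow(H)
  k <- scheme$k
  js <- scheme$positions
  wj <- 2^(-js)                      # bit weights, MSB first
  nb <- nv * k

  # full (non-triangular) block expansion, then fold to upper triangle
  Qf <- matrix(0, nb, nb)
  for (i in seq_len(nv)) {
    ri <- ((i - 1L) * k + 1L):(i * k)
    for (ip in seq_len(nv)) {
      rip <- ((ip - 1L) * k + 1L):(ip * k)
      Qf[ri, rip] <- outer(wj, wj) * H[i, ip]
    }
    diag_add <- wj * d[i] - 2^(scheme$k_int - 1) * wj * sum(H[i, ] + H[, i])
    Qf[cbind(ri, ri)] <- Qf[cbind(ri, ri)] + diag_add
  }
  Q <- matrix(0, nb, nb)
  ut <- upper.tri(Qf)
  Q[ut] <- Qf[ut] + t(Qf)[ut]
  diag(Q) <- diag(Qf)

  offset <- qp$offset +
    2^(2 * (scheme$k_int - 1)) * sum(H) -
    2^(scheme$k_int - 1) * sum(d)

  index_map <- data.frame(
    var = rep(seq_len(nv), each = k),
    bit = rep(seq_len(k), nv),
    j = rep(js, nv),
    flat = seq_len(nb)
  )
  structure(
    list(Q = Q, offset = offset, scheme = scheme, n_vars = nv,
         index_map = index_map, labels = qp$labels),
    class = "qubo_problem"
  )
}

#' Evaluate the QUBO energy of a bit assignment
#'
#' @param qubo A `qubo_problem`.
#' @param bits 0/1 vector over all bits (concatenated per-variable bit
#'   vectors, most-significant first within each variable).
#' @param include_offset Add the constant offset so the value matches the QP
#'   functional at the decoded state (default `FALSE`, the bare `q' Q q`).
#' @return Scalar energy.
#' @export
qubo_energy <- function(qubo, bits, include_offset = FALSE) {
  if (length(bits) != nrow(qubo$Q)) {
    stop(sprintf("expected %d bits, got %d", nrow(qubo$Q), length(bits)))
  }
  if (!all(bits %in% c(0, 1))) stop("bits must be 0 or 1")
  e <- qubo_energy_cpp(qubo$Q, as.integer(bits))
  if (include_offset) e <- e + qubo$offset
  e
}

#' Decode a QUBO bit assignment back to continuous unknowns
#'
#' @inheritParams qubo_energy
#' @return Numeric vector of the continuous unknowns, in QP row order.
#' @export
decode_solution <- function(qubo, bits) {
  if (length(bits) != nrow(qubo$Q)) {
    stop(sprintf("expected %d bits, got %d", nrow(qubo$Q), length(bits)))
  }
  k <- qubo$scheme$k
  vapply(seq_len(qubo$n_vars), function(v) {
    fp_decode(bits[((v - 1L) * k + 1L):(v * k)], qubo$scheme)
  }, numeric(1))
}

#' @export
print.qubo_problem <- function(x, ...) {
  cat(sprintf(
    "QUBO problem: %d binary variables (%d unknowns x %d bits), offset %g\n",
    nrow(x$Q), x$n_vars, x$scheme$k, x$offset
  ))
  invisible(x)
}

#' Export / import a QUBO as a plain-text coordinate list
#'
#' The format is line-oriented: comment headers carrying the scheme and the
#' constant offset, then one `row col coefficient` triple per nonzero
#' upper-triangular element (1-based indices). A JSON sidecar with the
#' bit index map is written next to the coordinate file.
#'
#' @param qubo A `qubo_problem`.
#' @param path Output file path for the coordinate list.
#' @param write_map Also write `<path>.map.json` with the index map.
#' @return `write_qubo` returns `path` invisibly; `read_qubo` returns a
#'   `qubo_problem` equivalent to the exported one.
#' @export
write_qubo <- function(qubo, path, write_map = TRUE) {
  nz <- which(qubo$Q != 0, arr.ind = TRUE)
  nz <- nz[nz[, 1] <= nz[, 2], , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# qubo coordinate list: row col coefficient (1-based, upper triangular)"),
    sprintf("# bits_per_variable %d k_int %d k_frac %d",
            qubo$scheme$k, qubo$scheme$k_int, qubo$scheme$k_frac),
    sprintf("# n_variables %d", qubo$n_vars),
    sprintf("# offset %.17g", qubo$offset),
    sprintf("# bit order within each variable: most-significant (j = %d) first",
            -qubo$scheme$k_int + 1L)
  ), con)
  if (nrow(nz) > 0) {
    writeLines(sprintf("%d %d %.17g", nz[, 1], nz[, 2], qubo$Q[nz]), con)
  }
  if (write_map) {
    jsonlite::write_json(
      list(scheme = list(k_int = qubo$scheme$k_int, k_frac = qubo$scheme$k_frac),
           offset = qubo$offset,
           index_map = qubo$index_map),
      paste0(path, ".map.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_qubo
#' @export
read_qubo <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_num <- function(key) {
    ln <- hdr[grepl(paste0("# ", key, " "), hdr, fixed = TRUE)][1]
    as.numeric(strsplit(sub(paste0("# ", key, " "), "", ln, fixed = TRUE), " ")[[1]][1])
  }
  ln <- hdr[grepl("bits_per_variable", hdr)][1]
  toks <- strsplit(ln, "\\s+")[[1]]
  k_int <- as.integer(toks[which(toks == "k_int") + 1L])
  k_frac <- as.integer(toks[which(toks == "k_frac") + 1L])
  scheme <- fp_scheme(k_int, k_frac)
  nv <- as.integer(get_num("n_variables"))
  offset <- get_num("offset")
  nb <- nv * scheme$k
  Q <- matrix(0, nb, nb)
  if (length(body) > 0) {
    m <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
    Q[cbind(m[, 1], m[, 2])] <- m[, 3]
  }
  index_map <- data.frame(
    var = rep(seq_len(nv), each = scheme$k),
    bit = rep(seq_len(scheme$k), nv),
    j = rep(scheme$positions, nv),
    flat = seq_len(nb)
  )
  structure(
    list(Q = Q, offset = offset, scheme = scheme, n_vars = nv,
         index_map = index_map, labels = NULL),
    class = "qubo_problem"
  )
}
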