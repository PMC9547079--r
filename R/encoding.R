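#' Signed fixed-point discretization scheme
#'
#' Defines the binary representation used for each continuous unknown when a
#' quadratic program is compiled to a QUBO. A variable is represented by
#' `K = K_I + K_D` bits with weights `2^(-j)` for bit positions
#' `j = -K_I+1, ..., K_D` (most-significant first), plus a fixed offset
#' `-2^(K_I-1)`:
#'
#' \deqn{y = -2^{K_I-1} + \sum_{j=-K_I+1}^{K_D} 2^{-j} q_j, \quad q_j \in \{0,1\}}
#'
#' With `K_I` integer bits and `K_D` fractional bits the scheme spans
#' `[-2^(K_I-1), 2^(K_I-1) - 2^(-K_D)]` on an equidistant lattice of spacing
#' `2^(-K_D)`, so rounding a real number onto the lattice incurs an error of at
#' most `2^(-K_D-1)`.
#'
#' @param k_int Number of integer bits (>= 1).
#' @param k_frac Number of fractional bits (>= 0).
#' @return An object of class `fp_scheme` with elements `k_int`, `k_frac`,
#'   `k` (total bits), and `positions` (the bit-position exponents `j`,
#'   most-significant first).
#' @examples
#' sc <- fp_scheme(6, 15)
#' fp_range(sc)
#' fp_decode(rep(0, sc$k), sc)  # lowest representable value: -32
#' @export
fp_scheme <- function(k_int, k_frac) {
  if (length(k_int) != 1L || length(k_frac) != 1L ||
      !is.finite(k_int) || !is.finite(k_frac) ||
      k_int != round(k_int) || k_frac != round(k_frac)) {
    stop("k_int and k_frac must be single integers")
  }
  if (k_int < 1L) stop("k_int must be >= 1")
  if (k_frac < 0L) stop("k_frac must be >= 0")
  k_int <- as.integer(k_int)
  k_frac <- as.integer(k_frac)
  structure(
    list(
      k_int = k_int,
      k_frac = k_frac,
      k = k_int + k_frac,
      positions = seq.int(-k_int + 1L, k_frac)
    ),
    class = "fp_scheme"
  )
}

#' @export
print.fp_scheme <- function(x, ...) {
  rng <- fp_range(x)
  cat(sprintf(
    "Signed fixed-point scheme: %d integer + %d fractional bits (%d total)\n",
    x$k_int, x$k_frac, x$k
  ))
  cat(sprintf("  representable range [%g, %g], step %g, max rounding error %g\n",
              rng$min, rng$max, 2^(-x$k_frac), rng$max_rounding_error))
  invisible(x)
}

check_bits <- function(bits, scheme) {
  if (length(bits) != scheme$k) {
    stop(sprintf("bit vector has length %d but scheme uses %d bits",
                 length(bits), scheme$k))
  }
  if (!all(bits %in% c(0, 1))) stop("bits must be 0 or 1")
  invisible(TRUE)
}

#' Decode a fixed-point bit vector to its real value
#'
#' @param bits Numeric or integer vector of 0/1, most-significant bit first.
#' @param scheme An [fp_scheme()].
#' @return The represented real value
#'   `-2^(k_int-1) + sum_j 2^(-j) * bits_j`.
#' @examples
#' sc <- fp_scheme(6, 15)
#' fp_decode(rep(1, sc$k), sc)  # largest representable value: 32 - 2^-15
#' @export
fp_decode <- function(bits, scheme) {
  check_bits(bits, scheme)
  -2^(scheme$k_int - 1) + sum(2^(-scheme$positions) * bits)
}

#' Encode a real value as the nearest representable fixed-point bit vector
#'
#' Rounds to the nearest lattice point (ties toward +Inf), which attains the
#' half-step error bound `|decode(encode(v)) - v| <= 2^(-k_frac-1)`. Values
#' outside the representable interval extended by one half step raise an
#' error; no silent clamping is performed, because saturation would corrupt a
#' trajectory invisibly.
#'
#' @param value A single finite real number.
#' @inheritParams fp_decode
#' @return Integer vector of 0/1, most-significant bit first.
#' @export
fp_encode <- function(value, scheme) {
  if (length(value) != 1L || !is.finite(value)) {
    stop("value must be a single finite number")
  }
  rng <- fp_range(scheme)
  half <- rng$max_rounding_error
  if (value < rng$min - half || value > rng$max + half) {
    stop(sprintf(
      "value %g outside representable range [%g, %g] (+/- half step %g)",
      value, rng$min, rng$max, half
    ))
  }
  step <- 2^(-scheme$k_frac)
  # lattice index 0 .. 2^k - 1; round half up (ties toward +Inf)
  idx <- floor((value - rng$min) / step + 0.5)
  idx <- max(0, min(2^scheme$k - 1, idx))
  int_to_bits(idx, scheme$k)
}

#' Representable range and rounding error of a scheme
#'
#' @inheritParams fp_decode
#' @return A list with `min` (`-2^(k_int-1)`), `max` (largest exactly
#'   representable value, `2^(k_int-1) - 2^(-k_frac)`) and
#'   `max_rounding_error` (`2^(-k_frac-1)`, half the lattice spacing).
#' @export
fp_range <- function(scheme) {
  stopifnot(inherits(scheme, "fp_scheme"))
  list(
    min = -2^(scheme$k_int - 1),
    max = 2^(scheme$k_int - 1) - 2^(-scheme$k_frac),
    max_rounding_error = 2^(-scheme$k_frac - 1)
  )
}

# integer 0 .. 2^k-1 -> 0/1 vector, most-significant first
int_to_bits <- function(idx, k) {
  bits <- integer(k)
  for (pos in k:1) {
    bits[pos] <- idx %% 2
    idx <- idx %/% 2
  }
  bits
}

# 0/1 vector (most-significant first) -> integer
bits_to_int <- function(bits) {
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}

#' Serialize / parse bit vectors as 0/1 strings
#'
#' Bit strings are written most-significant bit first, matching the order in
#' which [fp_decode()] consumes them.
#'
#' @param bits 0/1 vector.
#' @return `bits_to_string` returns a character scalar; `string_to_bits`
#'   returns an integer 0/1 vector.
#' @export
bits_to_string <- function(bits) paste(as.integer(bits), collapse = "")

#' @rdname bits_to_string
#' @param s A string of 0/1 characters.
#' @export
string_to_bits <- function(s) {
  bits <- suppressWarnings(as.integer(strsplit(s, "", fixed = TRUE)[[1]]))
  if (any(is.na(bits)) || !all(bits %in% c(0L, 1L))) {
    stop("bit string must contain only 0 and 1")
  }
  bits
}

#' Fully connected logical-qubit capacity of an annealer
#'
#' Given a number of fully connected logical qubits and a fixed-point scheme,
#' returns how many equations can be propagated simultaneously through
#' `m` time steps per run (each unknown consumes `k` logical qubits, and each
#' equation contributes `m` unknowns per run).
#'
#' @param n_logical Number of fully connected logical qubits available.
#' @inheritParams fp_decode
#' @param m Grid points (time steps) solved per run.
#' @return Integer count of simultaneously propagatable equations.
#' @examples
#' annealer_capacity(177, fp_scheme(6, 15))  # 8 equations at 21 bits each
#' @export
annealer_capacity <- function(n_logical, scheme, m = 1L) {
  stopifnot(n_logical >= 1, m >= 1)
  as.integer(floor(n_logical / (scheme$k * m)))
}
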