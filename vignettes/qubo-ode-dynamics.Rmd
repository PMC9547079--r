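---
title: "Propagating classical trajectories through quadratic binary optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Propagating classical trajectories through quadratic binary optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qubode)
```

## The method

`qubode` solves systems of first-order ordinary differential equations

$$\frac{dy_n}{dx} = f_n(x, \bar y), \qquad n = 1 \dots N,$$

by turning time propagation into a sequence of minimization problems of the
kind a quantum annealer natively accepts, and then minimizing them with
classical annealing-style solvers. On an equidistant grid with step
$\Delta x$, the first-order finite difference turns the system into the
least-squares cost functional

$$\epsilon(\bar y) = \sum_{i=1}^{M} \sum_{n=1}^{N} w_n
  \left( \frac{y_{n,i+1} - y_{n,i}}{\Delta x} - f_{n,i} \right)^2 ,$$

whose global minimum (zero residual, when reachable) is the discrete
solution. If every $f_n$ is at most linear in $\bar y$ — either naturally,
as for a harmonic oscillator, or after linearizing about the state at the
start of a short run of $M$ grid points — the functional is exactly
quadratic and can be written as $\epsilon(\bar y) = \bar y^T H \bar y +
\bar y^T d + c$. `build_qp()` assembles $H$, $d$ and $c$ with the known
initial point of each run eliminated by substitution rather than by a
penalty term, which keeps the functional exactly quadratic and makes the
one-step continuous minimizer *identical* to a forward-Euler update — the
anchor oracle used throughout the test suite.

Each continuous unknown is then written in signed fixed-point binary with
$K_I$ integer and $K_D$ fractional bits,

$$y = -2^{K_I - 1} + \sum_{j = -K_I + 1}^{K_D} 2^{-j} q_j,
  \qquad q_j \in \{0, 1\},$$

which spans $[-2^{K_I-1},\, 2^{K_I-1} - 2^{-K_D}]$ with a rounding error of
at most $2^{-K_D-1}$. Substituting this representation into the quadratic
form expands every element of $H$ into a $K \times K$ block
($K = K_I + K_D$); using $q^2 = q$, the linear terms fold onto the
diagonal, producing the binary functional $\epsilon(\bar q) = \bar q^T Q
\bar q$ handled by `qp_to_qubo()`. The dropped constants
($2^{2(K_I-1)} \sum H - 2^{K_I-1} \sum d$ plus the incoming offset) are
tracked explicitly so that binary and continuous energies are directly
comparable — this equality, checked on random bit strings to $10^{-9}$
relative, is the compiler's central correctness contract.

## Solvers

Four backends minimize the per-run problem:

* **qp** — the exact continuous reference: solve $(H + H^T)\bar y = -d$.
  It shows the best any binary solver could do at a given discretization.
* **exhaustive** — Gray-code enumeration of all $2^K$ states (up to 24
  bits), the ground-truth oracle. Energy ties break toward the state whose
  little-endian integer value is lowest, making it fully deterministic.
* **sa** — single-bit-flip Metropolis annealing with geometric cooling,
  restarted for a configurable number of `reads`; the classical stand-in
  for annealing hardware or heuristic QUBO software.
* **sa_greedy** — the hybrid: each read's best state is pushed to its
  1-flip local minimum by steepest greedy descent before the reads are
  compared.

Two schedule choices matter and both are deliberate:

1. **Temperature range.** The hot end defaults to the largest single-flip
   $|\Delta E|$ from a random probe state. The cold end defaults to a tenth
   of the smallest nonzero diagonal magnitude of $Q$ — *not* a fixed ratio
   of the hot end — because the fixed-point bit weights make the
   coefficients of one problem span roughly $2^{2K}$ in magnitude. With a
   fixed ratio like $10^{-3}$ the low-order bits are still effectively
   molten when the anneal stops, and the sampled states are random in their
   last several bits.
2. **Per-read polishing.** Single-bit-flip descent cannot cross carry
   chains: the states `x0111…1` and `x1000…0` represent adjacent lattice
   values but differ in many bits, so each is 1-flip stable. Greedy applied
   to a *single* final SA state therefore often strands one or two lattice
   steps from the optimum. Polishing every read and keeping the best
   polished state turns each read into an independent basin sample, and in
   the bundled tests the hybrid then reaches the enumerated global optimum
   on 100/100 seeded 21-bit one-step cells with the default
   `reads = 10, sweeps = 100`.

`solve_with_restarts()` wraps any backend in a best-of-$k$ loop (attempt
$r$ uses seed $\mathrm{xor}(\text{seed}, r)$) and by default keeps the best
of all attempts without early stopping. All reported energies are
recomputed from the final bit state rather than from accumulated flip
deltas, so identical states always report identical energies — with
per-step energies of order $10^4$, accumulated double round-off otherwise
breaks exact-optimum comparisons at the $10^{-12}$–$10^{-10}$ level.

## Propagation

`propagate()` walks the grid in runs of `m` points. At each run start the
right-hand side is linearized (analytic Jacobian when supplied, central
differences with step $10^{-6}$ otherwise), the functional is compiled and
minimized, and the decoded points extend the trajectory.

* In **sequential** mode (one equation at a time, `m = 1`) every $f_{n,i}$
  is known from the previous step, all equations decouple, and each task is
  a single 21-bit cell. Coupled quantities use the previous step's full
  state (a Jacobi update); a Gauss–Seidel variant is available behind the
  `gauss_seidel` flag but off by default.
* In **coupled** mode all $N$ equations of a run are solved jointly
  ($N \cdot m \cdot K$ bits).

Both modes reduce exactly to forward Euler at `m = 1` with the continuous
backend. Because a first-order scheme is first-order in $\Delta x$, the
trajectory error shrinks linearly with the step size; the test suite fits
the log–log slope on the harmonic fixture over $S \in \{50, \dots, 800\}$
steps and requires $1.0 \pm 0.2$.

If a decoded value reaches the edge of the representable interval the
propagation **aborts with the step index** rather than clamping: a lattice
value at the boundary means the true minimizer lay outside the encodable
range, and silent clamping would corrupt the trajectory invisibly.

`apply_scaling()` changes variables to $z_n = y_n / s_n$. This matters for
binary solvers because all variables share one fixed-point scheme: for an
oscillator with heavy reduced mass the momentum is numerically much larger
than the coordinate, and the scale $s_p = \mu\omega$ equalizes the two
residual contributions at equal phase-space amplitude.

## The Morse application

The bundled physical system is the vibration of H$_2$ on a Morse potential
$V(r) = D_e (1 - e^{-a(r - r_e)})^2$, propagated through Hamilton's
equations $\dot r = p/\mu$, $\dot p = F(r) = -dV/dr$. Default parameters
(Hartree atomic units throughout; conversions only at I/O):

| parameter | value | meaning |
|---|---|---|
| $D_e$ | 0.17449 Ha | dissociation energy |
| $a$   | 1.02764 Bohr$^{-1}$ | range (stiffness) parameter |
| $r_e$ | 1.40201 Bohr | equilibrium bond length |
| $\mu$ | 918.076 $m_e$ | reduced mass (half the proton mass) |

These are standard literature values for the ground-state H$_2$ Morse fit,
chosen once and kept fixed. They put the small-amplitude vibrational period
$2\pi / (a\sqrt{2 D_e / \mu})$ at $\approx 314$ a.u., so a 400 a.u. window
covers $\approx 1.28$ periods; they place the potential energy of a bond
compressed to 0.90 Bohr at $\approx 46\%$ of $D_e$ (a strongly anharmonic
bound trajectory), and a start at 0.70 Bohr above the dissociation
threshold (the bond breaks). The three standard starting points
$r_0 \in \{1.3, 0.90, 0.70\}$ Bohr with $p_0 = 0$ therefore probe the
nearly harmonic, strongly anharmonic, and dissociative regimes.

For bound energies $0 < E < D_e$ the classical Morse oscillator has the
closed form

$$r(t) = r_e + \frac{1}{a} \ln \frac{1 - \sqrt{E/D_e}\,\cos(\omega t +
\phi)}{1 - E/D_e}, \qquad \omega = a \sqrt{2 (D_e - E)/\mu},$$

with the phase fixed by $(r_0, p_0)$; `reference_trajectory()` evaluates it
directly. Above threshold no periodic closed form exists and the reference
is produced by adaptive integration (`deSolve`, relative and absolute
tolerance $10^{-12}$). The two routes agree to $\sim 10^{-11}$ Bohr where
both apply, and both conserve energy to better than $10^{-9}$ relative over
800 a.u. — the closed form is validated against the integrator before it is
trusted as the reference.

## Accuracy evaluation

`trajectory_rmse()` is the root-mean-square deviation of the *coordinate*
from the reference at the same grid times (no interpolation), in Bohr; a
trajectory is called *accurate* when the RMSE is strictly below $10^{-2}$
Bohr. The RMSE is defined on the coordinate only because that is the
variable the accuracy threshold is quoted in; a momentum-inclusive weighted
variant is available through the `variables`/`weights` arguments for
sensitivity checks. `convergence_sweep()` repeats a propagation over a list
of grid sizes and solver backends and reports a tidy table; a propagation
failure (encoding saturation) becomes an explicit `failed` row rather than
a silently dropped point.

```{r example}
params <- morse_parameters()
sys <- morse_system(params)
grid <- time_grid(0, 400 / 1000, 1000)
traj <- propagate(sys, grid, c(1.3, 0),
                  propagation_config(solver = "qp", mode = "sequential"))
ref <- reference_trajectory(params, 1.3, 0, grid$times)
trajectory_rmse(traj, ref)
```

## Problem sizes and numerical choices

The shipped tests and experiments use these sizes, chosen to exercise every
contract at full fidelity on the H$_2$ benchmark scale:

* headline trajectory: $S = 1000$ steps over 400 a.u. ($\Delta t \approx
  10$ as), scheme $(K_I, K_D) = (6, 15)$, 21 bits per unknown;
* convergence fits: $S \in \{50, 100, 200, 400, 800\}$ on the harmonic
  fixture and $S \in \{125, 250, 500, 1000\}$ on the Morse system;
* hybrid-solver validation: 100 random 21-bit one-step cells with the
  enumerated optimum as ground truth; binary-vs-continuous trajectory
  comparisons at $S = 60$–$100$ with the exhaustive backend.

Numerical conventions, all deliberate:

* `fp_encode()` rounds to nearest with ties toward $+\infty$ (attains the
  half-step bound) and raises an error outside the representable interval
  extended by half a step — never clamps;
* the exhaustive solver breaks energy ties toward the lowest little-endian
  bit-pattern value; greedy descent breaks tied flips toward the lowest bit
  index; both are therefore deterministic;
* per-equation penalty weights default to 1 and are exposed through
  `ode_system(weights = )`;
* within-block off-diagonal QUBO elements follow the general
  $2^{-(j+j')} H_{ii'}$ rule with $i = i'$, which is easy to misread as
  part of the diagonal case;
* bit vectors serialize most-significant bit first everywhere.

## Limitations

* The scheme is first-order in time and neither symplectic nor adaptive:
  energy drifts over long windows at large steps, and accuracy comes only
  from grid refinement.
* Linearization is frozen at the start of each run; runs with `m > 1` on
  strongly nonlinear forces inherit that segment error.
* Single-flip solvers cannot cross carry-chain barriers at zero
  temperature; the hybrid's reliability rests on sampling, so
  pathologically rugged problems may need more reads.
* The annealing backend emulates the *algorithmic* behaviour of annealing
  hardware, not its noise, precision limits, or connectivity constraints;
  hardware-specific effects (chain breaks, analog control error) are out of
  scope. A sampler adapter can be built on `write_qubo()`/`read_qubo()`
  coordinate lists if real hardware output is to be polished and evaluated
  with this package.
* Dissociative trajectories eventually leave the $[-32, 32)$ representable
  window of the default scheme; propagation then stops with a saturation
  error by design.
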