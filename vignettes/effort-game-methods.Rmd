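---
title: "Methods: feedback equilibria of dyadic effort games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feedback equilibria of dyadic effort games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A long-term relationship is tracked by a scalar *feeling* level $x(t) \ge 0$
(marital quality / satisfaction). Left alone the feeling decays; effort
rebuilds it:

$$\dot x(t) = -r\,x(t) + a_1 c_1(t) + a_2 c_2(t), \qquad r, a_i > 0,$$

where $c_i(t) \ge 0$ is partner $i$'s effort and $a_i$ its efficiency.
Partner $i$ receives well-being at rate $U_i(x) - D_i(c_i)$: utility of the
feeling, increasing, concave and satiating (default $U_i(x) = \alpha\ln(x+1)$,
$\alpha = 5$), minus an effort cost that is zero and flat at a preferred
effort level $c_i^\*$ and convex beyond it (default
$D_i(c) = \tfrac{w}{2}(c - c_i^\*)^2$, $w = 1$, $c_i^\* = 0.2$). Each partner
maximizes $\int_0^\infty e^{-\rho_i t}\,(U_i(x) - D_i(c_i))\,dt$ with
$\rho_i = 0.1$ by default. With one partner (the couple treated as a unit)
this is an optimal control problem; with two it is a nonzero-sum
differential game, and we look for *stationary feedback Nash equilibria*:
effort rules $S_i(x)$, each optimal against the other. The benchmark
parameter set above ($r = 2$, $a_1 = a_2 = 1$, domain $x \in [0,5]$) is the
bundled default (`benchmark_problem()`); every experiment in the package runs
on it unless told otherwise.

The value functions solve the coupled stationary Hamilton–Jacobi–Bellman
system

$$\rho_i v_i(x) = \max_{c_i \ge 0}\Big\{U_i(x) - D_i(c_i)
  + v_i'(x)\big({-r x + a_i c_i + a_j S_j(x)}\big)\Big\},$$

and $S_i(x)$ is the maximizer. No closed form exists for the defaults, so
the system is solved numerically.

## Discretization

A semi-Lagrangian discretization with time step $h$ replaces the HJB system
by its discrete-time fixed point on a node set
$\{y_j\}_{j=1}^{Q} \subset [x_{lo}, x_{hi}]$:

$$\tilde v_i(y_j) = \max_{c \in [0, c_{\max}]}
 \Big\{ h\,(U_i(y_j) - D_i(c)) + (1-\rho_i h)\,
 \mathrm{RBF}[\tilde v_i]\big(y_j + h f(y_j, \cdot)\big) \Big\},$$

where the Euler image $y^{\#}$ generally falls off-node and is evaluated by
a mesh-free radial-basis-function interpolant. Defaults: $h = 0.01$,
$Q = 41$ uniform nodes (a Halton placement is available), Gaussian kernel
with a linear polynomial tail and ridge $10^{-12}$.

Choices that matter, and why:

* **Time step `h = 0.01`.** The one-step discount $1-\rho h$ and Euler
  factor $1 - rh$ must stay positive; beyond that, $h$ fixes what one
  simulation "period" means. With $h = 0.01$ the closed-loop linearization
  rate of the benchmark (about $2.36$ per unit time, from the saddle
  eigenvalue) makes a 95% recovery from a one-period shock of 12–16% of
  the stationary feeling take a few dozen periods, matching the period
  granularity of the bundled shock fixtures. Recovery-period *counts*
  scale with $1/h$ and are reported as periods, not time units.
* **Kernel flatness `eps = 1/(3 mean spacing)`.** Measured on the benchmark
  utility with $Q = 41$: interpolation error $2.4\times10^{-2}$ at
  $1/(2\Delta)$, $2.0\times10^{-3}$ at $1/(3\Delta)$,
  $1.5\times10^{-4}$ at $1/(4\Delta)$ — but the collocation condition
  number grows from $10^{4}$ to $10^{9}$ to $10^{15}$ across the same
  range. $1/(3\Delta)$ is the flattest setting whose collocation systems
  still solve reliably at ridge $10^{-12}$, and it keeps the solved steady
  state within 0.1% of the closed form; the stiffer $1/(2\Delta)$ biases
  the steady state by ~8%.
* **Polynomial tail.** Constants and affine functions are reproduced
  exactly, which stabilizes the value iteration (the initial value guess
  is smooth and large).
* **Clamping.** Euler images and any off-domain query are clamped to
  $[x_{lo}, x_{hi}]$: RBF extrapolation is unstable.
* **Scalar maximization.** A coarse 501-point grid locates a one-cell
  bracket; interior brackets are resolved by bisection on the *analytic
  derivative* of the objective (the kernels differentiate in closed form).
  Value-comparison search alone (golden section) cannot place the argmax
  better than $\sim 3\times10^{-6}$ here, because the objective's
  curvature in $c$ carries the factor $h$, so differences near the top
  drown in rounding noise; derivative bisection is immune to this and
  reaches the $10^{-10}$ bracket tolerance. Boundary or degenerate
  brackets fall back to golden section on the $h$-rescaled objective.
  Ties break toward the smallest effort.

## The double loop

`solve_hjb()` runs a double loop of value and game iteration:

* **Game (outer) loop** — each partner's strategy takes a damped step
  (damping 0.5) toward its best-response strategy *function*.
* **Value (inner) loop** — that best-response function is obtained by
  fully re-solving the partner's single-agent dynamic program against the
  opponent's frozen node efforts: policy iteration alternating the
  per-node maximization above with *exact policy evaluation*, solved as
  one linear system in RBF-coefficient space
  ($(E_{node} - (1-\rho_i h) E_{y^\#})\,\lambda = b$ plus the tail moment
  conditions). Exact evaluation replaces the $\sim 1/(\rho h) = 10^4$
  sweeps a one-step value update would need (the one-step update remains
  available via `value_update = "direct"`).

Two structural lessons are baked into this design. First, policy
evaluation must be solved in coefficient space: forming the evaluation
matrix times the inverse collocation matrix explicitly amplifies the
kernel system's conditioning into a persistent $\sim10^{-5}$ limit cycle
of the iteration. Second, updating both partners' values from a shared
strategy sweep (the more literal reading of a per-node game iteration)
is stable only up to moderate effort coupling; at $a_1 a_2 \gtrsim 1.5$
it diverges, while the alternating single-agent formulation converges
over the entire bundled efficiency sweep $a_2 \in [0, 1.75]$ in at most
~60 outer rounds. The per-node damped best-response iteration is still
exported as `game_iterate_node()` with its own tolerance (`game_tol`).

Iteration stops when both the value and the strategy sup-norm changes fall
below `value_tol` ($10^{-6}$) and `strategy_tol` ($10^{-8}$); the
convergence report records both histories and the final Bellman residual
(`bellman_residual()` recomputes the maximized right-hand side at every
node). Values start at $U_i(y)/\rho_i$ — the value of freezing the feeling
at zero effort cost — and strategies at the preferred efforts. The control
set is truncated to $[0, c_{\max}]$ with $c_{\max} = 5$; if a maximizer
lands on the bound the solve is repeated with the bound doubled. Everything
is deterministic: reruns are bitwise identical, and there is no random
number generation anywhere in the pipeline.

## Simulators and fixtures

`simulate_couple()` iterates $c_{i,k} = S_i(x_k)$,
$x_{k+1} = x_k + h f(x_k, c_{1,k}, c_{2,k})$, recording efforts, payoffs and
running discounted well-being; `simulate_with_shocks()` adds an exogenous
additive shock $\sigma_{k+1}$ after each Euler update and re-reads the
feedback maps from the perturbed state — the stabilization mechanism
feedback strategies make possible. States that leave the domain are clamped
to its boundary and flagged; a feeling below the viability threshold
`x_min` (default 0) raises a breakdown flag without stopping the run.

The bundled stress fixture `make_itch_shocks()` emulates a year-long
stressful episode around the seventh year of a relationship when a period
is read as one month: twelve consecutive negative shocks starting at period
85, linearly spaced from $-0.15$ to $-0.05$ (a ramp of decreasing
magnitude; the generator exposes start, count and endpoints). Under it the
simulated feeling shows the U-shaped dip-and-recover pattern of resilient
relationships, with stabilizing effort above the unperturbed path
throughout the recovery. What these synthetic runs do *not* emulate:
measurement noise, persistent or random stressors, partner interaction in
the feeling state itself (the state is a single scalar), or any
heterogeneity beyond effort efficiency. Passing tests demonstrate the
internal consistency of the model and solver, not fit to observational
data.

`recovery_time()` counts periods from the first shock until the feeling
first regains a fraction (default 95%) of a baseline level.
`heterogamy_sweep()` and `recovery_table()` run the efficiency sweep
$a_2 \in \{0, 0.25, \dots, 1.75\}$ with $a_1 = 1$ fixed, and the
one-period $-0.2$ shock recovery analysis at each couple's own stationary
state.

## Independent oracle for the one-player problem

For the couple-as-a-unit problem the maximum principle reduces optimality
to a planar effort–feeling system

$$\dot x = -r x + a c, \qquad
  \dot c = \frac{(r+\rho) D'(c) - a\,U'(x)}{D''(c)},$$

whose unique rest point is, for concave utility, always a saddle
(`equilibrium_closed_form()`, `classify_saddle()`); for the log/quadratic
family the stationarity conditions collapse to one quadratic in $c$. The
optimal path is the stable manifold: `shoot_initial_effort()` finds the
initial effort by bisection, classifying each trial RK4 path (fixed-step
4th order, via deSolve) by the sign of its component along the unstable
eigen-direction, and returns the path truncated at its closest approach to
the saddle. This machinery shares no code with the HJB solver and serves
as its cross-check: the benchmark equilibrium $(\bar x, \bar c) \approx
(0.772, 1.544)$, initial effort $c(0) \approx 1.087$ at $x_0 = 3$, and the
whole closed-loop trajectory agree across the two routes within the test
tolerances (2% of the feeling scale or tighter).

## Problem sizes used by the test suite

The suite solves the benchmark one-player problem, the dyadic game at
$a_2 \in \{0, 0.25, \dots, 1.75\}$ ($Q = 41$, $h = 0.01$, shared across
test files), simulates up to 8000 periods for the well-being consistency
check (the discounted tail of a shorter run would exceed the 2% tolerance
by itself), and integrates the phase system at steps down to $10^{-5}$ for
the RK4 order check. A full run takes a few minutes on one core.

## Known limitations

* **Dyadic stationary levels.** The reference recovery analysis bundled
  with the acceptance checks implies a homogamous ($a_1 = a_2 = 1$)
  stationary feeling near 1.59. The feedback Nash equilibrium computed
  here stabilizes near 1.19. The computed value is internally consistent:
  it satisfies the stationarity condition
  $w(\bar c - c^\*) = a U'(\bar x)/(\rho + r - a S'(\bar x))$ with the
  solved (decreasing) feedback maps, and an independent fine-grid
  single-agent solve against the frozen opponent strategy reproduces the
  same curves and steady state — whereas a stationary feeling of 1.59
  would require an *increasing* feedback map at the equilibrium. Feedback
  Nash equilibria of nonzero-sum differential games are not unique in
  general, and alternative schemes may select different equilibria; the
  corresponding consistency check is kept in the suite and currently
  fails, by design rather than accident. All one-player reference values,
  and every qualitative dyadic law (symmetry, effort gap, monotone
  comparative statics, recovery ordering), are reproduced.
* The state is one-dimensional; models where each partner carries an own
  feeling state are out of scope, as are stochastic shocks and open-loop
  analyses of the two-player game.
* Recovery-period counts are $h$-dependent by construction; only their
  ordering across couples is scale-free.
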