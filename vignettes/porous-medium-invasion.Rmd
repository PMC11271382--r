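---
title: "Sharp invasion fronts under porous-medium diffusion in heterogeneous landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sharp invasion fronts under porous-medium diffusion in heterogeneous landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmfront)
```

## The model

`pmfront` simulates the invasion of a biological population whose dispersal
is density-dependent (porous-medium diffusion) and whose growth is logistic
against a spatially varying carrying capacity \(k(x) > 0\):

\[
U_t \;=\; \varepsilon\,\Delta U^m \;+\; \frac{1}{\varepsilon}\,
U\Big(1 - \frac{U}{k(x)}\Big),
\qquad \frac{\partial U}{\partial \nu} = 0 \text{ on } \partial D,
\]

with exponent \(m \ge 2\) and a scale-separation parameter
\(\varepsilon > 0\): space and time are observed at a scale \(1/\varepsilon\)
coarser than the biology (for a habitat scale of 100 m observed over
100 km, \(\varepsilon \sim 10^{-3}\)).  All results are reported in the
relative density \(u = U/k \in [0, 1+O(\varepsilon^2)]\).

Two structural features drive everything:

* **Degenerate diffusion.** \(\Delta U^m\) with \(m > 1\) has vanishing
  diffusivity at \(U = 0\); compactly supported data stay compactly
  supported and the population spreads behind a genuinely sharp front, not
  an exponential tail.
* **Singular reaction.** As \(\varepsilon \to 0\), \(u\) converges to a 0/1
  step function.  The discontinuity set \(\Gamma_t\) (the interface) moves
  in its outward normal direction with
  \[
  V_n = c_0\,k(x)^p, \qquad p = \frac{m-1}{2},
  \]
  where \(c_0 = c_0(m)\) is the minimal speed of the sharp traveling wave
  of the homogeneous (\(k \equiv 1\)) 1-d problem.  For linear diffusion
  (\(m = 1\), outside the package's regime) the exponent vanishes and the
  carrying capacity would not affect the invasion speed at all; the
  \(k^{(m-1)/2}\) law is the signature of the nonlinear dispersal.

The package implements both levels — the \(\varepsilon\)-problem and the
limiting interface flow — plus the traveling-wave machinery connecting
them, and diagnostics that verify the limit predictions numerically.

## The minimal wave and its computation

In the wave coordinate the profile solves
\((U^m)'' - c_0 U' + U(1-U) = 0\) with \(U \equiv 0\) behind the front.
Writing \(P = (U^m)'\), the profile is a phase-plane connection from the
saddle \((1,0)\) to the degenerate point \((0,0)\) that exists only at the
minimal speed.  `minimal_wave_speed()` shoots along the unstable manifold
of \((1,0)\), integrating \(dP/dU = c - m U^m (1-U)/P\) downward with a
fixed-step fourth-order Runge–Kutta scheme on a grid log-refined toward
both endpoints (4000 steps; 12000 for profile reconstruction).  The
bisection classifier is the observed dichotomy: for \(c\) too large the
flux \(P\) hits zero at positive \(U\); for \(c\) too small it reaches
\(U \to 0\) with \(P/U\) bounded away from \(c\).  A fixed-step integrator
is used deliberately: adaptive stiff solvers stall at the degenerate corner
\(P \to 0\), where the step collapses below machine resolution.

The profile is rebuilt from the phase-plane trajectory by quadrature of
\(dz/dU = m U^{m-1}/P\), anchored at the sharp edge with the local law
\(U \sim ((m-1)c_0 z/m)^{1/(m-1)}\) (so the support edge is exactly
\(z = 0\)) and continued beyond the last tabulated point with the saddle
linearization \(1 - U \propto e^{-\beta z}\).  Interpolation is done in the
variable \(U^{m-1}\), which is linear in \(z\) at the front, so a monotone
spline is uniformly accurate there.  For \(m = 2\) the construction can be
checked against the closed form \(U(z) = 1 - e^{-z/2}\), \(c_0 = 1\); the
test suite requires \(10^{-3}\) in sup norm and the observed agreement is
three orders better.  For other exponents no reference value is printed
anywhere we know of; the shooting value (e.g. \(c_0(3) \approx 0.802\)) is
instead cross-checked against the measured front speed of the
\(\varepsilon\)-problem, an entirely independent oracle.

`perturbed_wave()` implements the two-parameter family
\(V(z;\delta,\zeta) = (1+\delta)\,U((1+\delta)^{1-m/2}\zeta z)\) with speed
\(c(\delta,\zeta) = c_0 (1+\delta)^{m/2}\zeta\) — the analytical building
block of the sub/supersolutions that sandwich the transition layer.  Its
scaling identity \(V_\zeta = (z/\zeta)V_z\) holds exactly for any
differentiable interpolant, which the tests exploit.

## The perturbed solver

`evolve()` advances the equation in \(U\) (not \(u\)) by Strang splitting:

1. half a reaction step, solved **exactly** cellwise
   (\(U \mapsto kU/(U + (k-U)e^{-dt/\varepsilon})\)),
2. one explicit finite-volume diffusion step on \(w = U^m\) (3-point/5-point
   stencil, zero flux by mirrored ghosts),
3. the second reaction half step.

Solving in \(U\) keeps all heterogeneity inside the exactly solvable
reaction.  With this discretization the \(u\)-form update is the \(U\)-form
update divided pointwise by \(k\) — the two formulations coincide
identically at the discrete level, so no separate cross-check is
meaningful.  Equilibria \(u \in \{0, 1\}\) are machine-exact fixed points,
exact zeros are preserved (the scheme never invents an exponential tail
ahead of the support), and under the CFL bound
\(dt \le h^2 / (2\,\mathrm{dims}\,\varepsilon\, m\, (\max U)^{m-1})\)
the update is monotone, which makes the comparison principle hold to
rounding — one of the structural tests.  The step is recomputed every
iteration from the current \(\max U\) (default safety factor 0.8) and
shortened to land exactly on requested snapshot times.  An explicit scheme
was chosen over implicit alternatives because the degenerate nonlinearity
makes implicit solves delicate while desk-scale grids (\(\le 512^2\),
\(\varepsilon \ge 0.05\)) keep explicit costs at seconds to minutes.

The reaction-free spreading of a compact bump recovers the self-similar
support growth \(t^{1/(m+1)}\) (slope test within 10%), and the measured
front speeds of the full problem match \(c_0 k^{(m-1)/2}\) within 5% for
\(k \in \{0.5, 1, 2, 4\}\) at \(\varepsilon = 0.05\) — in scaled variables
the traveling-wave speed is exactly \(\varepsilon\)-independent, so the
residual error is discretization, not modeling.

## The interface flow

In 1-d the limit law is the scalar ODE \(\dot x = \pm c_0 k(x)^p\)
(classical RK4; on the ramp landscape below it integrates in closed form,
which the tests use at \(10^{-6}\)).  In 2-d the front is the zero set of a
level-set function \(\phi\), positive inside the invaded region to match
the signed-distance convention of the limit theory, advanced by
\(\phi_t = F|\nabla\phi|\) with \(F = c_0 k^p > 0\) and first-order Godunov
upwinding (with \(F > 0\) the upwind direction is always outward; errors
are dominated by grid resolution, which is acceptable at desk scale).
Every 10 steps — and before every stored snapshot — \(\phi\) is
reinitialized to the exact distance to its marching-squares zero polyline,
signed by the current sign.  Two speed-evaluation modes are provided:
`local` (\(k\) at the cell) and `footpoint` (\(k\) at the closest front
point \(x - \phi\nabla\phi\), the form the signed-distance PDE of the
theory takes off the front).  They coincide on the front itself and the
tests confirm the front positions agree to a few cells; `local` is the
default because it needs no gradient evaluation.

Numerical fine print: the polyline reinitialization carries an
\(O(h^2)\)-curvature bias (about \(h^2/6\) against a circle), so the
fixed-point property is exact only for straight fronts; the
\(|\nabla\phi| \in [0.95, 1.05]\) band near the front is nevertheless
maintained on every reinitialized snapshot.  The flow stops with a flag
when the zero set comes within 3 cells of the domain boundary, where the
limit law ceases to be meaningful (the theory assumes the interface stays
away from \(\partial D\)).

The cut-off distance `cutoff_distance()` — identity on \([-d_0, d_0]\),
clamped to \(\pm 2d_0\) outside, joined by a quintic Hermite blend with two
matching derivatives — realizes the theory's localization device as an
explicit, testable function.  The scale \(d_0\) is an existence-proof
constant with no canonical value; it defaults to 10% of the domain
diameter and is exposed as configuration.

## Study landscapes (the synthetic-data layer)

All inputs are generated in code; there is no external data.

* **1-d ramp** (`k_ramp_1d()`): \(k = 0.5\) for \(x < -1.5\), \(k = x+2\)
  beyond — piecewise harmonic with a Lipschitz cusp.  Default domain
  \([-4, 8]\): the printed experiments do not state a domain; this one
  holds the generation-phase features through \(t = 0.6\).  The
  propagation preset extends it to \([-4, 13]\) because the \(t = 4\)
  limit front sits at \(4 + 4\sqrt2 \approx 9.66\), outside the smaller
  box.
* **1-d step datum** (`u0_step_1d()`): \(u_0 = 0.5\) on \(\{x < 0\}\).
  Its support reaches the left boundary, so only a right-moving interface
  exists; this mirrors the printed experiment and is why the propagation
  preset tracks a single front.
* **1-d smooth bump** (`k_bump_1d()`): a Gaussian bump landscape
  satisfying the \(C^2\) structural bounds, used where the second-order
  theory needs its hypotheses to hold (see below).
* **2-d polar landscape** (`k_polar_2d()`): \(k = 2 + 1.5\cos\theta\) for
  \(r \ge 2\), regularized inside the disk by a quintic smoothstep radial
  ramp — one explicit \(C^2\) completion among many; the field equals the
  polar formula exactly outside the disk.
* **2-d elliptical colony** (`u0_ellipse_2d()`): plateau 1 with a linear
  edge of width 0.3 built from the exact signed distance to the ellipse.
  The preset default is a tall thin colony (semi-axes \(1.0 \times 3.5\))
  whose long flat side faces the slow sector (\(\theta = \pi\), where
  \(k = 0.5\)): flanking front points outrun the central ones and a
  nonconvex cavity forms within the simulated horizon.  A wide colony
  facing the fast sector stays convex until far beyond any domain that
  contains the fast front — measured directly with the level-set flow, and
  consistent with the polar-convexity estimate for
  \(r(\theta) = R_0(\theta) + c(\theta) t\) — so the wide geometry would
  demonstrate nothing.

These landscapes emulate the structure the theory addresses — smooth or
mildly singular heterogeneity at \(O(1)\) scale, steep compact initial
colonies — but not features of real invasions such as stochastic
demography, anisotropic dispersal, advection, or temporally varying
habitat.  Passing tests therefore validate the numerics and the limit law
in its stated regime; they do not calibrate the model to any organism.

## What the theorem checks do

`generation_check()` verifies, at the generation time
\(t^\varepsilon = \varepsilon|\ln\varepsilon|\), that the solution is
sandwiched by the theoretical envelopes: bounded by \(1 + \eta_\varepsilon\)
with \(\eta_\varepsilon = \varepsilon^2 \max(|\Delta k^m|/k)\,2^{m-1}\),
near 1 wherever \(u_0 \ge M\varepsilon\), and exactly zero (tested as
\(\le 10^{-10}\)) at distance \(\ge M\varepsilon\) from the initial
support.  \(M\) is an existence constant, so the check searches for the
smallest passing value on a grid rather than assuming one.
`propagation_check()` does the same at later times against the signed
distance to the limit interface (the 1-d front ODE, or the reinitialized
level set in 2-d); the measured band \(M\varepsilon\) halves when
\(\varepsilon\) halves, as the \(O(\varepsilon)\)-thickness prediction
requires.

**The cusp caveat.**  The second-order bound assumes \(k \in C^2\).  The
printed 1-d ramp violates that at its cusp, and the violation is not
cosmetic: the solver develops a persistent hump *at* the cusp whose height
is first order in \(\varepsilon\) (measured \(\approx 1.1\varepsilon\),
stable under grid refinement) — the same hump visible in the original
experiments.  On the ramp, \(\eta_\varepsilon\) computed with the cusp
cells excluded (\(= 8\varepsilon^2\)) does **not** bound the overshoot,
and applied literally the formula gives \(\eta = \infty\).  The
second-order statement is therefore exercised on the smooth bump
landscape, where the measured overshoot stays below
\(\eta_\varepsilon + 10^{-2}\) and its \(\varepsilon^2\)-normalized size
stabilizes for \(\varepsilon \le 0.2\); at \(\varepsilon = 0.4\) the
asymptotic regime has not set in (there \(\eta_{0.4} \approx 0.7\) is not
a small correction).  One acceptance-level check insists on the
second-order rate on the cusped landscape across
\(\varepsilon \in \{0.4, 0.2, 0.1\}\) and is expected to fail; it is kept
failing rather than silently re-scoped, and this section is the record of
why.

Cusp cells are identified from the field's own declaration (constructors
that build a kink record its location; only stencils straddling the kink
mix branches) plus a second-difference outlier sweep for undeclared
singularities.

## Problem sizes and determinism

The shipped experiments use desk-scale resolutions chosen so the whole
suite runs in about a minute: 1-d grids of 600–1250 cells
(\(h = 0.005\)–0.02), 2-d comparisons at \(128^2\), speed fits over 26
snapshots in the second half of each run (skipping the generation phase),
and \(\varepsilon\) down to 0.05 in 1-d and 0.1 in 2-d.  At \(128^2\) and
\(\varepsilon = 0.1\) the transition layer spans only a couple of cells,
which is the dominant contribution to the measured interface-band
constants.  Every preset is deterministic — no random numbers are drawn
anywhere in the pipeline — so re-running a preset reproduces its outputs
bit for bit; each preset writes a JSON manifest (package version, full
configuration, its MD5) sufficient to reproduce it.  Outputs are plain
CSV/JSON (and PNG figures), keeping every artifact diffable.

## Known limitations

* First-order upwinding and bilinear contouring limit 2-d front positions
  to \(O(h)\) accuracy; the interface-band constants inherit that floor.
* The explicit diffusion step makes the cost scale like
  \(h^{-2}\varepsilon^{-1}\); very small \(\varepsilon\) on fine grids calls
  for an implicit or semi-implicit scheme outside the current scope.
* `exact` zero preservation holds for the scheme, but reaction growth
  amplifies any mass that genuine flux deposits ahead of the front;
  exterior-nullity checks are therefore meaningful only up to the
  \(10^{-10}\) tolerance used.
* The wave module treats \(m \in (1, 2)\) on request (with a warning); the
  interface theory exercised here is stated for \(m \ge 2\), and no claims
  are tested below that.
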