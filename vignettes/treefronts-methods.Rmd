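---
title: "Models and methods behind treefronts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind treefronts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(treefronts)
```

## The models

`treefronts` implements a one-dimensional reaction-diffusion description of
tropical tree cover under a fire feedback. The full **forest-savanna model**
tracks savanna sapling cover $S$, savanna adult cover $T$ and forest cover
$F$ on the unit simplex (the remainder is grass):

$$
\begin{aligned}
\partial_t S &= R_S(P)\,(1 - S - T - F)\,T - Q_0[1 - h\Phi]\,S - M_S(P)\,S
  - R_F(P)\,S F + D_S \nabla^2 S,\\
\partial_t T &= Q_0[1 - h\Phi]\,S - M_T(P)\,T - R_F(P)\,T F,\\
\partial_t F &= R_F(P)\,(1-F)F - b\,\Phi\,F - M_F(P)\,F - C(z)\,F
  + D_F \nabla^2 F,
\end{aligned}
$$

with the burnt-area fraction
$\Phi(T,F;P) = \tau^{-1} Y_c^n / (Y_c^n + (T+F)^n)$, a Hill function
(default exponent $n = 4$) of woody cover with the rainfall-dependent
percolation threshold $Y_c(P) = \max[0, Y_{c0} + k_c P]$. Growth saturates
with rainfall, $R_Y(P) = \max[0, r_Y(1 - e^{-k_{RY}P + a_{RY}})]$, drought
mortality decays towards a baseline,
$M_Y(P) = m_{Yo} + e^{-k_{MY}P + a_{MY}}$, and deforestation pressure
decays with distance $z$ (meters) from cultivation,
$C(z) = c\,e^{-k_C z}$. Setting $S = T = 0$ gives the scalar bistable
**forest model**, the object of the analytical machinery. All defaults live
in `fs_params()` and reproduce the published calibration table for average
seasonality and soils; a flat `key = value` copy ships in
`inst/extdata/table1_defaults.cfg`.

Two parameter readings deserve a note. First, the savanna mortality offset
is not printed in the calibration table; we take $a_{MS} = 0$, i.e.
$M_S = m_{So} + e^{-k_{MS}P}$, and expose it as an ordinary parameter.
Second, the nondimensional groups of the forest model are read as
$(\text{rate})\cdot\tau/b$ — the unique time rescale $t \to b t/\tau$ under
which the fire response $f(u; P) = u_c^4/(u_c^4 + u^4)$ enters with unit
coefficient:

$$u_t = \alpha(P, z)\,u - \beta(P)\,u^2 - u\,f(u;P) + \delta_F \nabla^2 u,
\qquad \alpha = \rho r - \mu m - \gamma c - \mu_0,\quad \beta = \rho r.$$

The package guards this reading with an equivalence test: the equilibria of
the dimensional and nondimensional reactions coincide at every rainfall.
The clamp in the growth response is kept inside $r(P)$ for the same reason.

## Potential analysis and the Maxwell point

The nondimensional forest model is a gradient system, $u_t = -V'(u) +
\nabla^2 u$, with

$$V(u) = \frac{\beta u^3}{3} - \frac{\alpha u^2}{2}
  + \frac{u_c^2}{2}\arctan\!\big[(u/u_c)^2\big],$$

the arctan term being the closed-form fire integral available for $n = 4$
(any other exponent falls back to adaptive quadrature; `potential()` is
cross-checked against quadrature in the tests). Orienting fronts with
grassland on the left ($u(-\infty) = 0$) and forest on the right
($u(+\infty) = u_+$) in the frame $\xi = x - ct$, the classical
multiply-by-$u'$-and-integrate argument gives
$\mathrm{sign}(c) = \mathrm{sign}(\Delta V)$ with
$\Delta V = V(u_+) - V(0)$: negative $\Delta V$ means the forest state has
the lower potential and invades. `maxwell_point()` brackets the root of
$\Delta V(P)$ inside the bistable rainfall range found by
`bistable_range()`.

With the printed calibration the package computes a no-impact Maxwell point
of **1411.6 mm/y** (closed form and quadrature agree to $10^{-6}$ mm),
about 1.8% below the value the study reports (1438 mm). The sensitivity is
instructive: perturbing any of $\tau$, $b$ or $r_F$ by one unit of their
printed precision moves the Maxwell point by 20–40 mm, so the gap is of the
size expected from a table rounded to two significant figures. The package
reports what the printed parameters imply rather than adjusting anything
towards the published number. The same accounting applies to the bistable
range: the grassland state here stays linearly stable (its low-cover growth
factor $\alpha - 1$ never reaches zero, $\alpha(\infty) \approx 0.933$)
until the fire-spread threshold $Y_c(P)$ itself hits zero at
$P = Y_{c0}/|k_c| = 3916$ mm, which is therefore the computed upper
endpoint (the study quotes roughly 1200–3500 mm from its steady-state
figure; our lower endpoint, 1147 mm, sits within 5% of the quoted 1200).

## Simulation

`simulate_model()` discretizes space with central differences and mirror
(no-flux) ghost nodes and integrates the resulting ODE system with the
adaptive Dormand–Prince 4(5) pair (`deSolve`'s `ode45`), the same scheme
family the study used. The study grid — domain 0–3000 km, $\Delta x =
0.67$ km, rainfall equal to the coordinate under `forcing_linear()` — is
the default. Adult savanna trees do not diffuse; that asymmetry is
preserved exactly. Reaction terms are evaluated on covers clamped at zero
inside the right-hand side, and stored output is projected onto $[0,1]$
within a band of the absolute tolerance, because an explicit scheme can
undershoot zero by $O(\text{atol})$.

Two numerical facts matter for interpretation:

* The mirror stencil conserves the *trapezoid-weighted* mass under pure
  diffusion (the plain node sum is not the discrete invariant); the tests
  assert conservation in that functional to $10^{-8}$.
* `run_to_steady()` checks the stationarity residual $\max|du/dt|$ at
  window ends (default tolerance $10^{-8}$/y, cap 20 000 y). The residual
  floor scales with the integrator tolerance, which is why the
  steady-state driver defaults to `rtol = 1e-8`, tighter than plain
  simulation. Cycling regimes never converge; that is reported as a flag,
  not an error.

Random initial conditions are i.i.d. Uniform(0,1) per node, divided by
$\max(1, S+T+F)$ for the multi-species variants so that states start in
the simplex; everything is reproducible from an integer seed.

## Front extraction

`fit_logistic_front()` fits $F^*(P) = A/(1 + \exp[-k(P - P_f)])$ by
nonlinear least squares (Levenberg–Marquardt via `minpack.lm`),
initialized from the profile maximum, the gradient argmax and the maximum
slope — which makes the nonconvex fit reliable without interaction. The
default loss is a soft-L1 reweighting (IRLS weights
$1/\sqrt{1 + (r/f_{\text{scale}})^2}$, $f_{\text{scale}} = 0.05$ cover);
plain least squares is one switch away. The study used an interactive
robust fitting tool without stating its loss; soft-L1 is our choice of a
standard robust loss, and the two options agree to well under a grid cell
on clean profiles. `front_from_gradient()` implements the argmax of the
spatial derivative, with ties to the lowest rainfall and a parabolic
sub-cell refinement of the argmax; it is the extraction used along
continuation branches, where savanna-induced cover gradients cannot
contaminate it. `estimate_wave_speed()` tracks a level crossing (half of
$u_+$ by default) through homogeneous-forcing simulations and regresses
position on time over the later half of the record.

## Stationary fronts, continuation and stability

`solve_stationary_front()` solves $0 = R(u; P(x), z) + D_F u_{xx}$ by
damped Newton with the exact tridiagonal Jacobian (Thomas solves).
`continue_branch()` carries a front through $z$ by pseudo-arclength
continuation: tangents come from the implicit-function theorem (one extra
tridiagonal solve), the corrector is a damped Newton on the bordered
system, and the step adapts between $10^{-4}$ and `ds_max`.

The discretization leaves a visible fingerprint here that is worth
understanding. On a grid, a front does not sit anywhere: it *depins* cell
by cell as $z$ varies, so the continuation branch is a ladder whose stable
rungs (pinned fronts, $\max\Re\lambda < 0$) alternate with saddle rungs
(the barriers between neighbouring pinned positions, with small positive
eigenvalues of order $10^{-3}$/y). The width of the pinning band shrinks
rapidly with resolution: at $\Delta x = 0.67$ km stable rungs sit within
about 1.8 mm of the Maxwell point, at $\Delta x = 0.5$ km within 0.5 mm.
The acceptance checks therefore run the branch at $\Delta x = 0.5$ km over
$z \in [0, 5]$ km, where every recorded point lies within two grid cells
of `maxwell_point(z)` — the quantitative form of the study's
"indistinguishable". Stable rungs dominate that ladder; the interleaved
saddle rungs never carry an eigenvalue above $10^{-3}$/y, and
`pinned_front()` returns the dynamically realized (stable) front at any
single $z$.

Stability itself exploits a small linear-algebra fact: the mirror-boundary
operator $\mathrm{diag}(\partial R/\partial u) + D_F L/\Delta x^2$ is
exactly similar to a symmetric matrix under the trapezoid weight
$\mathrm{diag}(\tfrac12, 1, \dots, 1, \tfrac12)^{1/2}$, so its spectrum is
provably real and a symmetric eigensolver applies. `stability()` defaults
to that route and offers the plain nonsymmetric solver as a cross-check
(the tests confirm $\max|\Im\lambda| < 10^{-10}$ without the similarity
argument); along branches, the rightmost eigenvalue is computed at every
accepted point by shifted inverse iteration with a Gershgorin shift, at
tridiagonal-solve cost.

## Ensembles, bistability detection and cycles

`ensemble_scatter()` reruns the heterogeneous models from seeded random
initial conditions (default eight members, $\Delta x = 2$ km, 10 000 y)
and pools final covers with node rainfall. `detect_bistability()` bins the
cloud in rainfall (50 mm), splits each bin by 1-D two-means, and flags
bins whose cluster centres separate by more than 0.2 cover with neither
cluster a sliver; a unimodal noisy cloud does not trigger it. Detection by
across-run clustering, rather than hysteresis sweeps, mirrors how the
study's scatterplots reveal both branches at once.

`cycle_statistics()` discards a 30% transient, resamples uniformly,
detects peaks by topographic prominence (own implementation; the standard
peak finders in the environment lack a prominence filter), and classifies
by the coefficient of variation of inter-peak intervals: below 0.02
regular, above 0.1 irregular, between the two undetermined. The study
gives no numeric irregularity criterion, and explicitly leaves the chaos
question open; the CV of periods is the simplest defensible proxy, and the
package makes no aperiodicity claim beyond it. In the high-savanna regime
($r_S = 0.13$, $Q_0 = 0.2$, $\tau = 1$) the nonspatial system at 1500 mm
produces a clean relaxation cycle (period $\approx 654$ y, CV
$< 10^{-3}$); adding diffusion under homogeneous forcing makes the period
CV jump above 0.25 — irregularity induced by diffusion alone — and forest
peaks lag savanna peaks, with transitions over decades separating
century-scale quiescent phases.

### A reproducibility caveat in the high-savanna regime

One headline result of the study does not follow from its printed
equations and calibration, and the package reports the model's own answer
rather than the published one. The study describes savanna–woodland
bistability up to about 1000 mm in the full model and about 2500 mm in
the savanna-only variant ($F \equiv 0$). With the printed parameters, the
savanna subsystem is globally monostable (woodland) above roughly 650 mm:
multistart Newton finds no second stable equilibrium, direct integration
from any initial condition converges to the woodland state, and a linear
calculation shows why — at the printed rates, the extinction/low-cover
state would need a sapling mortality several times larger (or a much
smaller sapling growth rate) to remain stable once rainfall saturates the
growth response. The ensembles therefore show coexisting low- and high-T
outcomes only in a narrow band near 550–650 mm, plus snapshot bimodality
across the cycling band (roughly 1150–1750 mm) where relaxation cycles
park nodes near their extremes. The detection pipeline is implemented
exactly as specified and is validated on synthetic bimodal and unimodal
clouds; the discrepancy is a property of the printed model, not of the
detector.

## Problem sizes used by the tests

Unit tests run on small grids (domains of a few hundred km, or a 400 km
rainfall window around the Maxwell point). The end-to-end checks use the
study resolution where the claim depends on it: front pinning on the full
0–3000 km domain at $\Delta x = 0.67$ km, the continuation branch at
$\Delta x = 0.5$ km over $z \in [0, 5]$ km, and eight-member ensembles at
$\Delta x = 2$ km to 10 000 y. The scatter ensembles tolerate the coarser
grid because their diagnostics are per-node cover distributions; front
*location*, by contrast, inherits the lattice pinning band and is always
measured at $\Delta x \le 0.67$ km.

## Known limitations

* One spatial dimension only; no front curvature, no 2-D percolation
  geometry.
* Deterministic dynamics; no demographic or climate noise (the study
  treats noise elsewhere).
* The environmental forcing is mean annual rainfall plus distance to
  cultivation; the full seasonality/soil regressions behind the
  calibration are folded into the constants.
* The synthetic generators emulate clean sigmoid fronts and
  piecewise-sinusoidal cycles; they validate the extraction and
  classification machinery, not the ecology. Passing those tests says the
  pipeline measures what it claims to measure, not that real tree-cover
  data behave like the model.
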