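---
title: "Crowding functions, nonlinear diffusion and population fate: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowding functions, nonlinear diffusion and population fate: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdfate)
```

This vignette documents the modelling assumptions, numerical choices and
known limitations behind `crowdfate`. It is the companion to the README's
overview: the README says what the package computes, this document says how
and why.

## The two levels of the model

**Discrete.** Agents live on a periodic hexagonal lattice with spacing
$\Delta$ and exclusion (at most one agent per site). One time step $\tau$
consists of a movement sweep followed by a growth sweep. In each sweep,
$Q(t)$ agents are selected uniformly *with replacement*; a selected agent
with local density $K$ — the occupied fraction of its template
$\mathcal{N}_r$ of $3r(r+1)$ sites — moves with probability $M\,G(K)$ to a
uniformly chosen vacant template site, or (growth sweep) gives birth with
probability $P\,F(K)$ when $F(K)>0$, placing the daughter on a vacant site of
the growth template, and dies with probability $P\,|F(K)|$ when $F(K)<0$.
Defaults follow the biology: movement is nearest-neighbour ($r_\text{move} =
1$) while daughters are deposited over a wider neighbourhood
($r_\text{growth} = 4$), consistent with cell-scale observations that
proliferation disperses offspring further than a single motility step.

**Continuum.** With $\Delta = \tau = 1$ (all defaults are dimensionless) the
column density obeys
$$\partial_t C = \partial_x\!\left[D(C)\,\partial_x C\right] + \lambda C F(C),
\qquad D_0 = M/4,\ \lambda = P,$$
with
$$D(C) = D_0\!\left[C\,G'(C) + \frac{1+C}{1-C}\,G(C)\right].$$
The limit requires growth to be slow relative to movement; the package warns
when $P > M/10$ rather than refusing, because the discrete model itself is
well defined for any $P,M \in [0,1]$.

The growth law is the strong Allee form $F(C) = 2.5(1-C)(C-A)$ with
$A = 0.4$ by default, giving $F(0) = -1$ (isolated agents die fastest) and
roots at $A$ and the carrying capacity. Because $F$ scales an event
probability, constructors reject any $F$ with $|F| > 1$; movement crowding
functions that stray outside $[0,1]$ are only *flagged* invalid — the
framework deliberately keeps "less physically reasonable" crowding functions
usable for exploration, and the probability contract is enforced again, as a
hard error, when a simulation is configured.

## Numerical treatment of the crowding algebra

- **The pole at $C = 1$.** Every admissible $G$ vanishes at $C = 1$, so
  $\frac{1+C}{1-C}G(C)$ is finite there. Catalogue entries carry the
  cancelled form $G(C)/(1-C)$ explicitly and the limit is evaluated exactly.
  For user-supplied $G$ without that structure, the map is evaluated at
  $C = 1-10^{-9}$ and a value exceeding $10^6 D_0$ triggers a warning
  diagnosing $G(1) \neq 0$.
- **Power-law inverses.** Inverting $D = D_0 C^m$ gives
  $G(C) = C^m(1-C)^2\,{}_2F_1(2, m{+}1; m{+}2; C)/(m{+}1)$. For integer
  $m \in \{1,2,3\}$ the closed logarithmic forms are used, written in terms
  of $B(C) = (1-C)\ln(1-C)/C$ with the log singularity of $G'$ cancelled
  analytically before evaluation; for $C < 10^{-3}$, $B$ and $(1+B)/C$ switch
  to series (9 terms, error below $10^{-18}$ at the switch point) to avoid
  the $\ln(1-C)/C$ cancellation. For non-integer $m$ the Euler
  transformation ${}_2F_1(2,m{+}1;m{+}2;C) = (1-C)^{-1}
  {}_2F_1(m,1;m{+}2;C)$ keeps the series convergent and stable up to
  $C \to 1$; endpoints are returned as analytic limits, never as series
  evaluations.
- **Derivatives.** User-supplied $G$ without an analytic derivative get a
  fourth-order finite difference (step $10^{-5}$, one-sided at the
  endpoints), accurate to roughly $10^{-7}$ — sufficient for the forward map
  and far below the stochastic noise of any simulation driven by it.

The tests cross-check all of this against an independent direct Gauss-series
oracle and against the forward-map round trip $G_m \mapsto D_0 C^m$
(tolerances $10^{-10}$ and $10^{-8}$).

## Stochastic engine conventions

Several micro-decisions are not fixed by the verbal model description; the
package adopts the following and validates them through the
discrete–continuum agreement tests:

- The number of selections per sweep is fixed at $Q(t)$ evaluated at sweep
  start, but each draw is taken from the *current* live-agent list, so a
  dead agent can never be selected; a newborn can be selected later in the
  same sweep, and nothing prevents repeated selection (with replacement, as
  stated).
- The local density for a growth event is measured on the same template used
  for daughter placement.
- Each realization $v$ runs on its own R RNG stream seeded `base_seed + v`,
  with a fixed draw order (selection index, acceptance uniform, destination
  choice), so ensembles re-run bit-identically.
- Lattice occupancies are exchanged with R as plain integer vectors; the
  compiled core only accelerates the sweeps.

**Lattice shape.** The domain is "$L \times L$" in the sense of $I = L$
columns and $J = L$ rows (physical height $J\sqrt{3}/2\,\Delta \approx
0.87 L$). All reported quantities are column averages, which are independent
of $J$; the tests verify that doubling $J$ leaves column-density profiles
statistically unchanged. Column binning ignores the $\pm\Delta/2$ stagger of
odd rows — the stagger is below the column resolution $\Delta$. The strip
initial condition fills whole columns whose position $i\Delta$ lies in
$[(L-w)/2, (L+w)/2)$, matching the continuum indicator.

## Measuring the flux

The horizontal flux is tallied geometrically: vertical lines are placed at
$x^* = (k + \tfrac34)\Delta$, offset from the $x$-positions of both staggered
site columns, and every movement event whose (minimal-image) horizontal
displacement spans a line counts as a signed crossing. The net count divided
by the window duration and the row count $J$ estimates the column-density
flux directly comparable to $J_x = -D(C)\,\partial_x C$.

We initially considered the simpler convention of attributing diagonal moves
as half-crossings of the nearest column interface (mirroring the half-weights
the diagonal neighbours carry in the transition-probability expansion), but a
Taylor expansion of that tally shows it underestimates the continuum flux by
a factor $2/3$ on the hexagonal lattice: a diagonal step that *ends* on an
interface still crosses every line in the half-cell beyond it at full rate.
The offset-line tally needs no such calibration. The test suite checks it two
ways: against an exact enumeration of the $2^6$ neighbourhood configurations
under Bernoulli occupancies on a smooth profile (agreement with
$-D(C)\partial_x C$ within 5%, the residual being the $O(\Delta^2)$ expansion
error), and by replaying a single agent's trajectory through an independent
interval-logic bookkeeping.

## The continuum solver

Method of lines on the uniform periodic grid $x_k = kh$, $h = 0.5$ by
default (200 nodes for $L = 100$): conservative finite-volume differences
with arithmetic-mean interface diffusivities
$D_{k+1/2} = \tfrac12\{D(C_k) + D(C_{k+1})\}$, integrated by `deSolve`'s
stiff-capable `lsoda` with `rtol = 1e-8`, `atol = 1e-10`. Choices worth
recording:

- $D$ and $F$ are evaluated at the state clamped to $[0,1]$: adaptive steps
  may transiently leave the physical range by the integrator tolerance and
  the model functions are only defined on the unit interval. The *state* is
  never altered inside the right-hand side (that would break error
  control); undershoots are clipped to zero only between integrator
  outputs, with a warning past $-10^{-7}$.
- The scheme is exactly conservative: with $\lambda = 0$ the total density
  drifts by less than $10^{-8}$ over $t = 100$ for every catalogue
  diffusivity, including the degenerate power laws whose fronts are sharp.
- **Order of accuracy.** The discretization is second order, and measures as
  order $2.0$ on strips with smoothed ($\tanh$) edges. The exact indicator
  initial condition — which we keep for all physics runs because it matches
  the lattice strip — carries an $O(h)$ artefact of its own: the half-open
  sampled support shifts with the grid, so self-convergence of indicator
  runs saturates at first order regardless of the scheme. The convergence
  test therefore uses the smoothed strip; all cross-model comparisons run at
  a single fixed $h$ where the distinction is immaterial.
- The 2D equation is never solved: strip initial conditions keep the density
  independent of the vertical coordinate, so the 1D reduction is exact for
  every case the package addresses, and the 2D physics is exercised by the
  discrete model itself.

## Fate classification and the phase diagram

A run is classified by integrating from the strip initial condition with
early exit: extinction once the total density falls below $0.01$, survival
once it exceeds $0.99$, with a final $C(T) > 0.5$ rule at the decision
horizon $T = 10^4$ (default). A run still mid-range at $T$ with
$|\mathrm{d}\bar C/\mathrm{d}t| > 10^{-6}$ raises an explicit *undecided*
condition rather than silently labelling it. Two practical notes:

- The decision horizon must scale with the growth time $1/\lambda$: at
  $P/M = 10^{-3}$ the approach to carrying capacity takes $t \approx 1.2
  \times 10^4$, so those comparisons use $T = 2\times 10^4$.
- The bisection for the critical width $w^*$ necessarily walks into the
  undecided regime (dynamics slow down near the threshold); it therefore
  uses the $C(T) > 0.5$ fallback, and its result is validated by classifying
  $w^* \pm \mathrm{tol}$ with the strict rule.

The discrete-engine classifier runs $V$ realizations and takes a majority
vote, reporting the survival fraction rather than hiding near-boundary
stochasticity. The full $41\times40$ phase-diagram mesh is reproducible with
`phase_diagram()` at its default resolution (order of an hour of CPU); the
test suite exercises a $9\times8$ mesh of the same ranges plus the
critical-width ordering
$w^*(\text{decreasing}) \le w^*(\text{linear}) \le w^*(\text{increasing})$
at $P/M = 6/1000$, which decides the same scientific question at a fraction
of the cost. Problem sizes used by the stochastic tests — $V = 40$
realizations for the profile comparison at $t = 600$, $V = 4$ and $t = 400$
for the well-mixed tracking, $V = 30$ for flux profiles — were chosen so
that expected stochastic error sits comfortably inside the stated
tolerances.

## What the simulations do and do not emulate

The stochastic model generates exclusion-process dynamics with
crowding-modulated motility and Allee-type growth on an idealised lattice:
synchronous-rate sweeps, identical agents, periodic boundaries, strip or
well-mixed initial conditions. Passing tests therefore demonstrate internal
consistency of the framework (discrete model, its continuum limit, and the
maps between crowding functions and diffusivities) — they do not validate
the lattice abstraction against any particular biological dataset. Real
populations add heterogeneity, off-lattice movement, finite rest times and
boundary effects that are out of scope here, as are multi-species
interactions, non-strip initial shapes and travelling-wave analysis.

## Limitations

- The inverse map is implemented for power-law diffusivities only; inverting
  arbitrary $D(C)$ would require solving an ODE for $G$ with no guarantee of
  a crowding-function-like solution.
- Near the critical width the continuum classifier's answer depends on the
  horizon $T$; this is a property of the bistable dynamics (critical slowing
  down), not of the implementation, and is surfaced via the undecided
  condition.
- The flux tally attributes crossings to fixed vertical lines; profiles
  steeper than the lattice spacing are under-resolved, which is flagged in
  the tests by restricting comparisons to interfaces where the gradient is
  resolved.
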