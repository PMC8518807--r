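---
title: "Entropy production, the evolution criterion, and stability in mass-action networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy production, the evolution criterion, and stability in mass-action networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nessflow)
```

## The model

`nessflow` simulates deterministic mass-action chemical reaction networks in
well-mixed, isothermal, ideal solutions (activities = 1), either closed or
coupled to the surroundings as an ideal continuous-flow stirred-tank reactor
(CSTR): one dilution rate $f$ applies to every exchanged species $k$, each
with its own inflow concentration $c_{k,\mathrm{in}}$, so

$$\dot c = N\,v(c) + f\,(c_{\mathrm{in}} - c),$$

with $N$ the stoichiometric matrix and $v_\rho = k_\rho \prod_k
c_k^{m_{k\rho}}$ the unidirectional mass-action rates.  Following
stoichiometric network analysis (SNA), a reversible step is stored as *two*
reactions — forward and backward are different elementary processes — linked
by a `pair_id`.  Strictly irreversible steps are allowed for dynamics but
rejected by every thermodynamic operation, because the affinity of a pair,

$$\mathit{Af}_\rho = RT \,\ln\frac{v_{f\rho}}{v_{r\rho}},$$

diverges when one direction is missing.  Units are fixed: mol L$^{-1}$,
seconds, $R = 8.314$ J mol$^{-1}$ K$^{-1}$; stoichiometric coefficients are
non-negative integers up to 4 (mass action with small molecularity; the
Schlögl model needs order 3).

## Entropy bookkeeping

The specific internal entropy production (per unit volume, J K$^{-1}$
s$^{-1}$ L$^{-1}$) is a sum of force $\times$ current over pairs:

$$\sigma_{\mathrm{int}} = R \sum_\rho (v_{f\rho} - v_{r\rho})
\ln\frac{v_{f\rho}}{v_{r\rho}} \;=\; \frac1T \sum_\rho \mathit{Af}_\rho\,
(v_{f\rho} - v_{r\rho}) \;\ge\; 0,$$

zero exactly at detailed balance.  An equivalent *per-unidirectional-
reaction* form writes each one-way rate times its own force in relative
chemical potentials $\mu_k = RT \ln (c_k / c_{k,\mathrm{eq}})$, with
$c_{\mathrm{eq}}$ a detailed-balance equilibrium of the closed chemistry;
`entropy_production_relative()` implements it and the test suite verifies
the two forms agree to $10^{-10}$ relative on thousands of random
compositions.  The reference equilibrium exists exactly when the rate
constants satisfy the Wegscheider conditions ($\ln K_{eq}$ in the row space
of $N^\top$ over pairs); `wegscheider_check()` solves for species potentials
by pseudoinverse and `equilibrium_point()` exponentiates them (optionally
re-solving on a prescribed stoichiometric compatibility class).  Networks
with inconsistent constants have genuinely free reference potentials and
must supply them explicitly.

The entropy exchanged with the surroundings through the flow is
$\sigma_{\mathrm{exch}} = -(1/T)\sum_k \mu_k J_k$ with matter currents
$J_k = f\,(c_{k,\mathrm{in}} - c_k)$.  Because $\mathit{Af}_\rho = -\sum_k
\nu_{k\rho}\mu_k$ for any detailed-balance reference, the total satisfies
$\sigma_{\mathrm{int}} + \sigma_{\mathrm{exch}} = -(1/T)\sum_k \mu_k \dot
c_k$: it vanishes **exactly** at any stationary state, independent of which
reference equilibrium is used.  Away from stationarity the same expression
equals $-(1/T)\,dG/dt$ for the ideal free energy built from the same
potentials, which the tests confirm against finite differences.

Zero balance is a *necessary* condition only: whole curves of compositions
satisfy $\sigma_{\mathrm{int}} + \sigma_{\mathrm{exch}} = 0$.
`balance_residual()` therefore always reports the kinetic residual
$\max|\dot c|$ alongside, and `balance_zero_contour()` traces the zero set
over a 2-D concentration grid, marking the (typically single) point that is
also stationary.  For closed networks the balance surface touches zero
without crossing, and the contour is traced as the refined per-column
minimum — it degenerates to the equilibrium manifold.

Clamped species (fixed concentrations) are supported as the textbook
boundary idealization, but the entropy carried by the implicit chemostats is
not modeled, so every thermodynamic report on a clamped network carries an
explicit caveat and the exact NESS balance is not expected there.

## The general evolution criterion

Splitting the time derivative of the dissipation into the force part and the
current part,

$$\frac{dP}{dt} = \frac{d_F P}{dt} + \frac{d_J P}{dt},
\qquad
\frac{d_F P}{dt} = \frac1T \sum_\rho (v_{f\rho} - v_{r\rho})
\frac{d \mathit{Af}_\rho}{dt},$$

the general evolution criterion states $d_F P/dt \le 0$ along *any*
evolution.  For ideal mass action the chain rule gives the closed form
$d_F P/dt = -R \sum_k \dot c_k^2 / c_k$, manifestly non-positive with
equality only at stationarity — the package computes all derivatives
analytically (`gec_at()`, `gec_decomposition()`) and keeps a centered
finite-difference estimate (`gec_finite_difference()`, one fourth-order
Runge–Kutta step each way at $10^{-6}$ of the fastest local relaxation
time) purely as a cross-check.

Boundary exchange is folded in SNA-style as pseudo-pairs: inflow at
$f c_{\mathrm{in}}$ versus outflow at $f c$, with affinity
$RT\ln(c_{\mathrm{in}}/c)$.  A species that is only washed *out*
($c_{\mathrm{in}} = 0$) has no inflow process; it carries the outflow
affinity $-\mu_k$ instead, which leaves the force part identical (its
affinity derivative is $-RT\,\dot c_k/c_k$ either way) and keeps the current
part finite.  This bookkeeping is a convention chosen for exact balance and
finiteness, not a unique prescription; it requires a detailed-balance
reference (or explicit potentials) only when zero-inflow exchanged species
are present.

In the linear regime (all forces $\ll RT$; at 300 K that means affinities
well below $RT \approx 2.5$ kJ mol$^{-1}$, a very narrow window) forces and
currents are proportional, the two halves coincide ($d_F P = d_J P$), the
full $dP/dt \le 0$, and the dissipation relaxes monotonically to a minimum
at the stationary state.  The suite checks this on closed relaxations and on
a weakly driven CSTR whose inflows sit a fraction $2\times10^{-4}$ off the
equilibrium composition; note it is $P$ (total, including the boundary
pseudo-pairs) that decreases strictly, while $\sigma_{\mathrm{int}}$ alone
can undershoot its stationary value by a small fraction of its excess.

## Steady states, stability, scans, probes

`find_steady_states()` runs a multistart damped Newton iteration in
log-concentration space (strict positivity, well-conditioned across the
log-uniform start window $[10^{-6}, 10^2]$ mol L$^{-1}$, default 64 seeded
starts).  For closed systems the root problem is augmented with the
conserved-moiety constraints, pinning the compatibility class of the
declared initial composition.  A few starts are first relaxed by
integration, which catches stable roots that plain Newton walks away from
(e.g. beyond a fold of the rate function).  Roots are deduplicated at
$10^{-6}$ relative distance and validated by re-evaluating $\max|\dot c|
\le 10^{-9}$.

Stability is decided twice and must agree: the Routh–Hurwitz table of the
characteristic polynomial (Faddeev–LeVerrier coefficients; the table's
right-half-plane count) and the eigenvalues of the analytic Jacobian.
Structural zero modes — conserved moieties and clamped species — are
deflated by projecting onto the stoichiometric subspace first, so closed
systems are not misreported as marginal.  Disagreement (never observed on
$10^3$ random matrices up to $6\times6$) degrades the verdict to `marginal`
with a warning.

`scan_branch()` is a quasi-static sweep: each grid point is integrated to
steady state seeded from the previous one, then Newton-polished.  A tiny
deterministic seed perturbation ($10^{-7}$, alternating signs) lets the
sweep fall off a branch that loses stability — in particular off the exactly
racemic branch, which the mirror-symmetric equations would otherwise ride
forever.  Up/down sweep mismatch on an overlapping window raises the
hysteresis flag (bistability); the per-point entropy production is scanned
for slope breaks as the bifurcation signature.  The break detector combines
the second-difference outlier rule (5$\times$ the median slope change) with
a relative gate (the slope must change by more than 25%), because on a
smoothly curved branch with a long linear tail the raw median rule flags
mere curvature.

`local_potential_probe()` is the simulation counterpart of the stability
analysis: small displacements (default $10^{-3}$ of the smallest component)
along seeded random sphere directions — projected on the stoichiometric
subspace so closed-system probes stay on their class — plus user-supplied
symmetry modes; each probe is integrated for 50 slowest relaxation times and
its fate recorded (returned within $10^{-6}$ relative, escaped to a known
attractor within $10^{-4}$, or unbounded).  All directions returning = a
*well*; mixed fates = a *saddle*, with the returning subspace listed.  The
evolution criterion is verified along every probe path.  The probe verdict
matches the Jacobian verdict on every preset.

## Presets and the fixture generator

All presets are emitted in the plain-text network dialect and parsed back,
so each is exactly what a user could write in a file
(`system.file("extdata", "competitive.txt", package = "nessflow")` has one).

* **`make_ab()`** — closed $A \rightleftharpoons B$; equilibrium ratio
  $k_1/k_{-1}$ on its conservation class.
* **`make_competitive()`** — CSTR with channels $A\rightleftharpoons C$ and
  $A\rightleftharpoons D$; defaults $k_{1C}=10, k_{-1C}=1, k_{1D}=1,
  k_{-1D}=0.1$ share $K_{eq}=10$ with C kinetically favoured; the linear
  kinetics give the closed-form NESS $[C] = k_{1C}a/(k_{-1C}+f)$, so
  selectivity $[C]/[D] = 10(0.1+f)/(1+f)$ rises from 1 to 10 with flow.
  With mirror-identical constants the channels are enantiomers and the
  selectivity is exactly 1 at any NESS.
* **`make_schlogl()`** — $A\rightleftharpoons X$,
  $3X\rightleftharpoons 2X+B$ with A, B clamped; defaults make the
  steady-state condition $(x-1)(x-2)(x-3)=0$.  Clamped by design (the
  textbook form); its thermodynamic reports carry the clamped caveat.
* **`make_frank()`** — production $A\rightleftharpoons L/D$, autocatalysis
  $A+L \rightleftharpoons 2L$ (and mirror), inhibition
  $L+D\rightleftharpoons P$ in a CSTR.  Defaults: forward constants
  $(0.1, 1, 1)$, reverse $= 0.05\times$ forward, $a_\mathrm{in} = 1$,
  every species carried by the flow.  Two deliberate choices: (i) all
  species, including L and D, are diluted by the flow — without that, the
  antisymmetric mode's growth rate $\approx k_a[A] - k_{-p} - 2k_{-a}[L]$
  is positive at every practical flow and the racemic state is *never*
  stable; (ii) the reverse constants are appreciable (5%), because in the
  nearly irreversible limit the stabilizing back-reaction terms are so
  small that the racemic-stable window shrinks to immeasurably small flow
  rates.  With these defaults the symmetry-breaking threshold sits at a
  convenient $f^\ast \approx 0.013$ s$^{-1}$, located at run time by
  `find_smsb_threshold()` (bisection on the leading eigenvalue of the
  racemic NESS, itself solved on the racemic subspace by `racemic_ness()`
  so it is found even where unstable).  Mirror symmetry of the parameter
  set is validated structurally; chiral bias is an error, not a default.
* **`random_network()`** — seeded uni/bimolecular reversible pairs whose
  constants derive from random species potentials, hence exactly
  Wegscheider-consistent; `driven = TRUE` adds a CSTR drive on a random
  subset of species.  These are the property-test fixtures.

## Numerical choices

Integration uses `deSolve::lsoda`/`lsodar` with the analytic Jacobian and
tight tolerances (rtol $10^{-10}$, atol $10^{-12}$) — entropy balances are
differences of nearly equal numbers, so slack tolerances would drown the
$10^{-10}$-level checks.  Extended precision beyond double is out of scope;
tolerances are arguments everywhere.  Concentrations are solved in the
original variables; magnitudes below atol are clipped to zero afterwards
(preserving the exactness of linear networks), and the root searches work
in log space instead of clipping.  Steady-state arrival uses an event on
$\max|\dot c|$.  Deduplication ties break by first-found; probe radius
defaults to $10^{-3}$ of the smallest positive component.

Problem sizes in the shipped tests — 2–5 species, $\le 5$ pairs, 50-network
property sweeps, $10^4$-point criterion checks — were chosen so the whole
suite exercises every claim at the stated tolerances while remaining quick
on a laptop; all scale linearly if enlarged.

## What the tests do and do not show

The synthetic fixtures emulate small ideal well-mixed networks with exact
mass-action kinetics and (optionally) perfectly consistent thermodynamics.
They do not emulate activity corrections, temperature gradients or
inhomogeneity, stochastic fluctuations at small copy number, or uncertain
rate constants — so passing tests certify the *bookkeeping and the
dynamical/thermodynamic identities*, not agreement with any wet experiment.
In particular the entropy-exchange convention for zero-inflow species is a
documented convention (see above), and reaction–diffusion phenomena
(spatial dissipative structures) are outside the model class entirely.

```{r example}
net <- make_competitive(flow = 1)
ness <- find_steady_states(net)[[1]]
ness
thermo_state(net, ness$conc)
```
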