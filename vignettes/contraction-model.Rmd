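---
title: "Morphoelastic modelling of post-burn skin contraction: model, stability theory and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphoelastic modelling of post-burn skin contraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphocontract)
```

## The biological problem and the model

Post-burn contraction is driven by a feedback loop between chemistry and
mechanics. Signaling molecules $c$ (a lumped pool of growth factors such as
TGF-$\beta$) attract fibroblasts $N$ by chemotaxis and drive their
differentiation into myofibroblasts $M$; myofibroblasts exert an active
body force on the extracellular matrix and, together with fibroblasts,
secrete collagen $\rho$, which in turn stiffens the tissue (Young's modulus
$E\sqrt\rho$) and regulates the breakdown of both $c$ and $\rho$ through
matrix metalloproteinases (MMPs, assumed at local equilibrium, entering as
the inhibition factor $1/(1+a_c^{II}c)$). The tissue moves with velocity
$v$, and the *effective strain* $\varepsilon$ measures how far the current
configuration is from a hypothetical mechanically relaxed one.
Morphoelasticity decomposes the deformation into an elastic part and a
permanent ("growth", here: shrinkage) part; the evolution equation

$$\frac{\partial\varepsilon}{\partial t} + v\frac{\partial\varepsilon}{\partial x}
  + (\varepsilon-1)\frac{\partial v}{\partial x}
  = -\zeta\,\frac{(N+\eta^{II}M)\,c}{1+a_c^{II}c}\,\varepsilon$$

lets the relaxed configuration itself change at rate $\zeta$ wherever cells
and signaling coincide — this is what makes contraction permanent
(contracture). The four constituents obey advection–reaction balances with
passive convection $\partial(z v)/\partial x$; fibroblasts and
myofibroblasts additionally diffuse (density-dependent, $D_F(N+M)$) and
chemotax ($\chi_F z\,\partial c/\partial x$); proliferation is logistic
with crowding factor $1-\kappa_F(N+M)$ and exponent $1+q$. The momentum
balance is viscoelastic with inertia retained,

$$\rho_t\Bigl(\frac{\partial v}{\partial t}+2v\frac{\partial v}{\partial x}\Bigr)
 = \frac{\partial}{\partial x}\Bigl(\mu\frac{\partial v}{\partial x}
 + E\sqrt{\rho}\,\varepsilon\Bigr)
 + \frac{\partial}{\partial x}\frac{\xi M \rho}{R^2+\rho^2}.$$

Boundary conditions fix $c=0$, $N=\bar N$, $M=0$, $v=0$ on the outer
boundary. Collagen and strain satisfy ordinary differential equations along
material characteristics, so they carry no boundary conditions at all —
the solver deliberately assembles no boundary rows for them.

### Equilibrium and derived parameters

The analysed equilibrium is $(0,\bar N,0,\bar\rho,0,\bar\varepsilon)$ with
$\bar\rho=\sqrt{k_\rho/\delta_\rho}$ and
$\delta_N=r_F(1-\kappa_F\bar N)\bar N^{\,q}$. Two parameters of the packaged
reference set are therefore *consequences* of the others, and
`wound_params()` derives them unless they are supplied explicitly:

* $q$ from $\delta_N$ via `derive_q()` (natural logarithms; any consistent
  base gives the same ratio), giving $q\approx-0.4151$ for the defaults;
* $k_\rho=\delta_\rho\bar\rho^2 = 7.59375\times10^{-8}$ g/(cells day) for
  $\bar\rho=0.1125$ g/cm³.

Deriving them, rather than storing independently rounded values, keeps the
equilibrium an *exact* fixed point of the kinetics in floating point. The
solver's unconditional-stability tests (the equilibrium preserved to
machine precision over 100 implicit steps at any step size) rely on this;
with independently rounded values the residual imbalance of order $10^{-4}$
relative would masquerade as solver drift. Units are documented metadata
only; no runtime unit algebra is performed.

## Linear stability

Linearizing about the equilibrium and expanding perturbations in complex
Fourier modes $e^{2i\pi kx}$ on a unit domain decouples the system per mode
into $y' + Ay = 0$ with a $6\times6$ matrix in the variable order
$(c, M, N, \rho, v, \varepsilon)$. That ordering makes the chemical block
lower-triangular, so four eigenvalues are read off the diagonal, and the
mechanical $(v,\varepsilon)$ pair contributes
$\lambda = \tfrac12 A_{55}\pm\tfrac12\sqrt{A_{55}^2+4A_{56}A_{65}}$, where
the imaginary first-derivative couplings enter only through the real
product $A_{56}A_{65} = (2\pi k)^2\,(E\sqrt{\bar\rho}/\rho_t)(\bar\varepsilon-1)$.
With this sign convention non-negative real parts mean decay. Stability for
all modes reduces to three closed-form criteria (evaluated by
`check_stability_continuous()`):
$\delta_c\bar\rho \ge k_c/a_c^I$ (sufficient signaling decay — the $k=0$
mode is the most dangerous, so if constant perturbations decay, so do all
waves), $q\delta_N \le \kappa_F r_F\bar N^{1+q}$ (fibroblast crowding), and
$\bar\varepsilon\le 1$ (small strain). Equality cases are reported as
stable with a `marginal` flag, with a tolerance of $10^{-12}$ on the
boundary. The mechanical pair is real-valued —
monotonic relaxation — iff $\mu \ge \sqrt{\rho_t E\sqrt{\bar\rho}
(1-\bar\varepsilon)}/\pi$ (the $k=1$ mode is binding).

The Von Neumann analysis of the central finite-difference
semi-discretization on a uniform grid (`check_stability_discrete()`)
replaces $(2\pi k)^2$ by $4\sin^2(\pi\beta h)/h^2$ and $(2\pi k)$ by
$\sin(2\pi\beta h)/h$. Because the discrete Fourier ansatz uses the
conjugate exponential, the imaginary couplings flip sign relative to the
continuous matrix; eigenvalues are unaffected since only $A_{56}A_{65}$
enters. All added discrete terms are non-negative, so continuous stability
implies semi-discrete stability *for every* $h$ — the package's
property-style tests exercise this over randomized parameter sets — and the
discrete monotonicity threshold $h/\tan(\pi\beta h)\cdot
\sqrt{\rho_t E\sqrt{\bar\rho}(1-\bar\varepsilon)}$ is always below the
continuous one, approaching it at rate $O(h^2)$. Degenerate angles are
guarded explicitly: $\beta h$ an odd multiple of $1/2$ gives a zero
threshold ($\tan\to\infty$), integer $\beta h$ is an aliased mode and an
error; the guard band is $10^{-12}$.

Two independent oracles back the hard-coded matrix entries: a generic dense
eigensolver applied to the assembled complex matrix (agreement required to
$10^{-10}$ relative over randomized systems), and a finite-difference
Jacobian of the nonlinear reaction kinetics at the equilibrium, which must
reproduce the $k=0$ chemical block entry by entry.

## The moving-grid finite-element solver

The solver (`fem_advance()`, `simulate_contraction()`) uses linear basis
functions on a mesh whose nodes are advected with the material velocity —
the Lagrangian limit of an ALE scheme, in which the basis functions have
vanishing material derivative and passive convection is absorbed into the
mesh motion entirely. Applying the Leibniz–Reynolds transport theorem, each
constituent balance becomes
$\tfrac{d}{dt}\int z\varphi\,dx = \int J_z \varphi'\,dx + \int R_z\varphi\,dx$
on the moving elements; the strain equation simplifies beautifully to
$\tfrac{d}{dt}\int\varepsilon\varphi\,dx = \int \varphi\,\partial_x v\,dx
- \int\alpha\varepsilon\varphi\,dx$, with the $(\varepsilon-1)$ structure
recovered through the element-size changes.

Time integration is backward Euler (A-stable; together with the
semi-discrete result above, the equilibrium is unconditionally stable for
any $\Delta t$). Nonlinearity is handled by **monolithic Picard
iterations**: all six fields are solved simultaneously, with every
nonlinear coefficient (Hill and logistic factors, $v$ in the mesh motion,
$\rho$ in stiffness and body force) frozen at the previous iterate so the
unknowns enter linearly. Choices the original method description leaves
open, fixed here as package defaults:

* **Stopping rule**: global $\ell_2$ norm of the scaled update below
  $10^{-8}$ relative, at most 25 iterations. A per-field relative norm is
  ill-defined for fields that are identically zero at equilibrium, so the
  update is measured in scaled units (below).
* **Scaling**: the monolithic system is diagonally scaled by per-field
  characteristic magnitudes ($a_c^I$ for $c$, $\bar N$ for cells,
  $\bar\rho$ for collagen, 1 for $v$ and $\varepsilon$). Raw fields span
  $10^{-15}$–$10^4$ and the unscaled solve leaves roundoff noise large
  enough to defeat both the Picard test and the fixed-point property.
* **First iterate**: the mesh is moved with the *previous* step's velocity;
  if that tangles the mesh (the start-of-step velocity can grossly
  overshoot the strongly damped implicit one, e.g. for high-frequency
  velocity perturbations at $\Delta t = 0.5$), the first iterate falls back
  to a frozen mesh and the mesh moves with solved velocities thereafter.
  Tangling at a later iterate, a singular matrix, or non-finite solutions
  raise the blow-up signal, returning the last finite state.
* **Quadrature**: element-midpoint (trapezoid) averaging of coefficients;
  no convection stabilization is needed since the mesh carries convection.
* **Mass lumping** is on by default; the consistent-mass alternative is
  retained because the comparison (a pure-diffusion spike losing
  positivity under consistent mass but not under lumping) documents *why*
  lumping is used. Reaction terms are always lumped.
* **Fractional powers**: $z^{1+q}$ with $q<0$ is Picard-frozen as
  $(z^*)^q\,z$; for myofibroblasts near zero this coefficient diverges, so
  below $10^{-8}$ cells/cm³ the (then negligible) growth term is dropped.
  Densities that undershoot zero are warned about once and integration
  continues; the 1-D runs here never required flux correction.
* **Half-domain symmetry**: the left boundary carries the Dirichlet values;
  the right (symmetry) boundary carries $v=0$ plus natural zero flux for
  $c, N, M$ — consistent with signaling molecules rising at the skin
  centre, which a Dirichlet condition there would forbid. A mirrored
  full-domain run agrees with the half-domain run to discretization
  tolerance (tested).
* **Displacement** accumulates as $u^{t+\Delta t} = u^t + \Delta t\,
  v^{t+\Delta t}$ with $u(x,0)=0$; the wound's relative surface area (RSAW)
  is the distance between two material wound-edge marker nodes divided by
  its initial value.

## Scenario generators

`wound_scenario()` builds the convergence-study initial condition: a 10 cm
domain, a 4 cm wound plateau ($2000$ fibroblasts/cm³, $10^{-8}$ g/cm³
signaling molecules, $0.01125$ g/cm³ collagen — one tenth of the healthy
values for cells and collagen), and 1 cm half-period sine ramps to the
equilibria on each side, so the ramp midpoint is the arithmetic mean.
Myofibroblasts, velocity and strain start at zero.

`perturbation_scenario()` builds the stability-validation initial
conditions on the half domain $[0,1]$: sine perturbations of amplitude 10
cells/cm³ ($N$), $10^{-2}$ g/cm³ ($\rho$), 0.05 cm/day ($v$) and 0.5 ($\varepsilon$),
and strictly non-negative spline bumps for $M$ and $c$ through $2k+1$
uniform knots (boundary knots zero; interior knots alternating 3/6 cells/cm³
and $0.5/2\times10^{-15}$ g/cm³, starting with the lower level).
Conventions fixed here, where the construction was open:

* The sine waves use $k$ *full* periods, $\sin(2k\pi x)$: they vanish at
  both endpoints (Dirichlet-compatible) and are zero-mean. The zero mean
  matters for the strain: the $k=0$ mechanical eigenvalue vanishes, so any
  mean put into $\varepsilon$ initially is conserved by the linear dynamics
  — a half-wave convention would pin the long-time strain at
  $\approx 0.32/k$ rather than near zero. The full-period convention also
  matches the Fourier mode index of the stability analysis.
* The spline bumps are natural cubic interpolants computed at unit scale.
  For the signaling-molecule level ratio 1:4 the interpolant genuinely
  undershoots zero by a fraction of a percent of the upper level next to
  the boundary knots; since these profiles exist precisely to keep the
  densities positive, undershoot below 1% of the top level is truncated to
  zero and anything larger is treated as a generation error.
* The strain amplitude 0.5 about $\bar\varepsilon=0$ keeps
  $\varepsilon \le 1$ everywhere, respecting the small-strain requirement.

Generated profiles are functions of $x$ sampled at the nodes: refining the
mesh changes the samples, never the underlying profile.

## The numerical experiments

**Convergence** (`convergence_study()`): the wound scenario is run for one
simulated day with $\Delta t = h^2$ on a ladder of *nested* uniform grids —
node counts 41, 81, 161, 321 against a 641-node reference by default
(one refinement short of the 1281-node reference; the package's desk-scale
choice, selectable up to the full ladder) — so the 41 coarse nodes are
initially shared by every run. Errors per field are measured four ways: the
sum of absolute differences at the 41 shared points ($\epsilon_{|41|}$),
composite-trapezoid $L^1$ and $L^2$ norms on the reference mesh after
linear interpolation, and the absolute difference at the wound-edge node
($\epsilon_{boundary}$; these last three are reconstructions, labelled as
such). Because the meshes have moved slightly by day 1, solutions are
compared in physical space by linear interpolation. Log–log slopes are
ordinary least squares over the ladder; all land near 2, confirming
second-order convergence, with a method-of-manufactured-solutions diffusion
problem as an independent check of the machinery.

**Stability validation** (`stability_validation_run()`): $n=500$ elements,
$\Delta t = 0.5$ days ($0.01/1/2$-day stages for the low-viscosity runs,
which need the early velocity transient resolved), varying $\delta_c \in
\{2,3,5\}\times10^{-4}$ and $\mu\in\{1,100\}$. The run reports the
criterion verdict *and* the empirical outcome, classified as
converged-to-equilibrium (constituents and velocity within 1% of the
healthy equilibria), converged-to-new-equilibrium, or blow-up. The strain
is only required to be stationary: once $v=0$ and $c=0$, *every* strain
profile is an equilibrium (the vanishing $k=0$ mechanical eigenvalue
again), so the tissue legitimately retains a small permanent strain.
Sub-threshold decay at $\delta_c=3\times10^{-4}$ settles onto a shifted,
hypertrophic equilibrium whose centre values the acceptance tests check
against the homogeneous-kinetics attractor; at $\delta_c=2\times10^{-4}$
the signaling molecules regrow from the $10^{-15}$-scale seed at the rate
of the unstable $k=0$ eigenvalue
$\bar N(\delta_c\bar\rho - k_c/a_c^I) \approx -0.175$/day, so blow-up
arrives once that exponential reaches the nonlinear regime — the latency
therefore depends entirely on the seed amplitude of the initial bump.

**Reversion** (`reversion_experiment()`): resetting $c$ to zero at the end
of the hypertrophic run lifts the growth-factor over-stimulation. Recovery
of each constituent is timed as its deviation falling below a fixed
fraction ($10^{-3}$ by default) of its *own* post-reset deviation. This
decay-factor reading mirrors judging each field's own plot; it makes the
recovery order reflect the relaxation rates
($\delta_M = 0.06 > 2\delta_\rho\bar N\bar\rho \approx 0.0135 >
-q\delta_N + \kappa_F r_F\bar N^{1+q}\approx 0.0085$ per day), giving
myofibroblasts first, then collagen, then fibroblasts, robustly across
factors from $10^{-2}$ to $10^{-4}$. Under a uniform absolute threshold the
order would instead be dominated by the incidental sizes of the initial
gaps.

## What the synthetic scenarios do and do not show

The generators emulate the *study conditions* of the model: idealized 1-D
geometry, smooth prescribed wound and perturbation profiles, parameters
fixed at literature point estimates. Passing tests therefore demonstrate
the numerical method's correctness (convergence order, stability surfaces,
eigenstructure) and the model's qualitative regimes. They do not
demonstrate fidelity to any real wound: real burns are 2- or 3-dimensional
with irregular geometry, parameters vary by orders of magnitude between
patients and studies, mechanical boundary conditions are not rigid
clamps, and several constitutive choices (the $N^{1+q}$ logistic form, the
lumped MMP equilibrium) are modelling conveniences. Known limitations of
the implementation: no flux correction for negative densities (warn and
continue), no adaptive time stepping beyond the explicit schedule, no
2-D/3-D support, and blow-up detection by mesh tangling / singular matrix /
non-finite solution rather than by a physical criterion.
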