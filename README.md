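# morphocontract

One-dimensional morphoelastic modelling of post-burn skin contraction.

Serious burns contract while they heal: fibroblasts invade the wound,
differentiate into myofibroblasts under growth-factor signaling, deposit and
remodel collagen, and pull the wound edges together. Part of that
contraction is permanent (a contracture) because the tissue's mechanically
relaxed configuration itself changes. `morphocontract` is aimed at
researchers in computational tissue biomechanics and wound-healing
modelling: it implements a one-dimensional morphoelastic continuum model of
this process, the linear stability theory of its homogeneous equilibrium,
and a moving-grid finite-element solver that reproduces the model's
numerical behaviour — including the parameter regimes where it converges,
oscillates, settles onto a hypertrophic (scar-like) equilibrium, or blows
up.

## The model

Six coupled fields on a deforming interval: signaling molecules `c`
(lumped growth factors such as TGF-β), fibroblasts `N`, myofibroblasts `M`,
collagen `ρ`, tissue velocity `v`, and effective strain `ε` (the local
mismatch between the current and the mechanically relaxed configuration).
The constituents satisfy advection–reaction(–diffusion–chemotaxis) balances,

    ∂c/∂t + ∂(cv)/∂x = D_c ∂²c/∂x² + k_c [c/(a_c^I + c)](N + η^I M)
                        − δ_c (N + η^II M) ρ c / (1 + a_c^II c)

    ∂N/∂t + ∂(Nv)/∂x = −∂/∂x( −D_F (N+M) ∂N/∂x + χ_F N ∂c/∂x )
                        + r_F [1 + r_F^max c/(a_c^III + c)] [1 − κ_F(N+M)] N^(1+q)
                        − k_F c N − δ_N N

with an analogous balance for `M` (signaling-dependent proliferation,
differentiation influx `+k_F c N`, apoptosis `δ_M M`) and for `ρ`
(signaling-enhanced secretion, MMP-mediated breakdown). The mechanics is a
viscoelastic momentum balance with a myofibroblast body force and a
collagen-dependent stiffness `E√ρ`,

    ρ_t (∂v/∂t + 2v ∂v/∂x) = ∂/∂x( μ ∂v/∂x + E √ρ ε ) + ∂/∂x( ξMρ/(R²+ρ²) )

and the morphoelastic strain evolution

    ∂ε/∂t + v ∂ε/∂x + (ε−1) ∂v/∂x = −ζ [(N + η^II M) c/(1 + a_c^II c)] ε .

The homogeneous equilibrium is `(c,N,M,ρ,v,ε) = (0, N̄, 0, ρ̄, 0, ε̄)` with
`ρ̄ = √(k_ρ/δ_ρ)` and `δ_N = r_F (1−κ_F N̄) N̄^q`. Linearizing and expanding
in Fourier modes gives, per mode `k`, a 6×6 system `y′ + A y = 0` whose
eigenvalues are four chemical diagonal entries plus the mechanical pair
`½A₅₅ ± ½√(A₅₅² + 4A₅₆A₆₅)`. The equilibrium is linearly stable iff

    δ_c ρ̄ ≥ k_c / a_c^I ,    q δ_N ≤ κ_F r_F N̄^(1+q) ,    ε̄ ≤ 1 ,

and the relaxation is monotonic (real mechanical eigenvalues) iff
`μ ≥ √(ρ_t E √ρ̄ (1−ε̄))/π`. A Von Neumann analysis of the central
finite-difference semi-discretization replaces `(2πk)²` by `4sin²(πβh)/h²`
and `(2πk)` by `sin(2πβh)/h`; every added term is non-negative, so
continuous stability implies semi-discrete stability for every grid spacing,
and the discrete monotonicity threshold `h/tan(πβh)·√(ρ_t E √ρ̄ (1−ε̄))`
never exceeds the continuous one.

The solver discretizes all six fields with linear finite elements on a mesh
whose nodes move with the tissue velocity (so passive convection is carried
by the mesh), lumped mass matrices, backward Euler time integration, and
monolithic Picard iterations for the nonlinearities.

## Worked example

```r
library(morphocontract)

params <- wound_params()          # reference human-dermis parameter set
eq <- equilibrium_state(params)
check_stability_continuous(params, eq)
#> <stability_report> continuous problem
#>   signaling decay condition : TRUE (threshold delta_c >= 0.0003556)
#>   fibroblast condition      : TRUE (-0.008301 <= 0.000202)
#>   strain condition          : TRUE
#>   verdict: STABLE; min Re(lambda) over modes = 0
#>   monotonic relaxation: TRUE (mu threshold 2.78908)
```

The report says the reference parameters satisfy all three stability
criteria — the signaling decay rate `δ_c = 5e-4` exceeds the threshold
`k_c/(a_c^I ρ̄) ≈ 3.56e-4`, the fibroblast crowding condition holds with a
wide margin, and the equilibrium strain is below 1 — and that the viscosity
`μ = 100 (N day)/cm²` is far above the monotonicity threshold `≈ 2.79`, so
perturbations decay without oscillating.

Simulating a perturbed equilibrium on the half domain confirms the verdict
empirically:

```r
run <- stability_validation_run(delta_c = 5e-4, mu = 100, k = 1,
                                t_end = 400, n = 200)
run
#> <validation_run> delta_c = 0.0005, mu = 100, k = 1, n = 200
#>   criterion verdict: stable | empirical outcome: converged-to-equilibrium (t = 400.0 d)
#>   centre values: c = 3.936e-38 g/cm3, N = 9974.3, M = 0.00 cells/cm3, rho = 0.1125 g/cm3
```

By day 400 the fibroblasts are back at `N̄ = 10⁴ cells/cm³` (within 0.3%),
collagen at `ρ̄ = 0.1125 g/cm³`, and signaling molecules and myofibroblasts
have vanished. Lowering `delta_c` to `3e-4` (just below the threshold)
instead produces `converged-to-new-equilibrium` with elevated collagen and a
persistent myofibroblast population — a hypertrophic scar — and `2e-4`
produces a numerical blow-up.

A wound simulation with the 4 cm wound scenario and the
grid-convergence study:

```r
st <- wound_state(wound_scenario(), n = 200, params)
tr <- simulate_contraction(st, t_end = 15, solver_config(
  dt_schedule = data.frame(start = c(0, 2), dt = c(0.1, 0.5))))
relative_surface_area(tr$state)   # < 1: the wound has contracted

tab <- convergence_study()        # ladder of nested grids, ~2 min
tab$slopes                        # log-log error slopes, all near 2
```

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/morphocontract", package="morphocontract"))')" \
  stability continuous --config my.cfg --out out/
```

Subcommands: `simulate`, `stability continuous|discrete`, `converge`,
`validate-stability`, `scenario dump`. Configuration is a flat
`key = value` text format (see `?load_config`); every output directory
carries a manifest with file hashes and the echoed configuration.

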