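---
title: "Methods: a finite-strain mechanobioelectric model of a cell cluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a finite-strain mechanobioelectric model of a cell cluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poroelec)
```

## The model

`poroelec` treats a closely packed cell cluster as a Lagrangian mixture:
at every material point a compressible neo-Hookean solid network (the
cytoskeleton plus anchoring junctions) coexists with an intracellular
(IC) and an extracellular (EC) aqueous solution of mobile ions (Na+,
K+, Cl-) and impermeant fixed anions. Per unit reference volume the
balance laws are

* mechanical equilibrium of the nominal stress, `Div P = 0`, with
  traction-free outer boundary;
* mass balances for IC and EC water and for each mobile ion, with
  self-balancing transmembrane source terms weighted by the membrane
  area per cell volume, `A_c/V_c = 2/R_c`;
* Gauss laws for the IC and EC potentials, with the free charge of all
  (mobile and fixed) ions of the corresponding space.

Key constitutive assumptions, all visible in the code:

* **Ideal dilute solutions.** Chemical potential of water
  `mu_w = -R T C_osm/C_w + v_w p_w`; electrochemical potential of an
  ion `R T ln(C_i/C_w) + F z_i psi`. The osmotic concentration `C_osm`
  includes the fixed species, which is what makes the benchmark's
  initial 300 mol/m^3 bookkeeping and the steady-state arithmetic
  consistent.
* **Incompressible constituents.** The volume ratio is slaved to the
  water contents, `J = 1 + Phi0 (v_w C_w - 1) + Phi0_e (v_w C_w^e - 1)`;
  `C_w` is eliminated through this constraint and the water pressure
  `p_w` (its Lagrange multiplier) becomes the independent field
  (`water_from_constraint()`).
* **Onsager cross-diffusion.** The IC and EC flux laws couple water and
  all mobile ions through symmetric positive-definite mobility matrices
  (`mobility_matrices()`): water carries ions (convection), ions drag
  water (electro-osmosis), and the matrices reduce to Darcy and
  Nernst–Planck forms in the appropriate limits. The explicit flux
  expressions (`ic_fluxes()`, `ec_fluxes()`) are implemented as printed
  forms with the fixed-species term `(sum_j C_j / C_w) grad C_w`; an
  independent route through the potential gradients
  (`fluxes_via_potentials()`) is kept as a test oracle, and the two
  agree to 1e-10 relative on random dilute states.
* **Specific membrane transport.** Aquaporins carry only water (purely
  osmotic driving force — the shared `p_w` field means no pressure jump
  across the membrane) and channels carry only their ion, with a
  GHK-type flux law. The prefactors use the average of the IC and EC
  reference concentrations, neglecting membrane deformation; at the
  benchmark's concentration ranges the distinction from current
  concentrations is immaterial, but it is a modelling choice a user
  changing regimes should know about.
* **Thin-capacitor boundary.** At the cluster edge the membranes (and,
  when sealed, the tight-junction belt) act as parallel-plate capacitors
  against the grounded bath, providing the natural boundary conditions
  of the Gauss laws.

The dissipation rate (bulk flux-force products plus membrane exchange
terms) is evaluated at every accepted step and must be non-negative;
it is a structural property of the mobility laws, so a negative value
flags an implementation or convergence defect, not a modelling one.

## Parameters

`load_parameters(list(preset = "reference"))` returns the benchmark set
for an animal-cell cluster; values may be overridden individually and
may carry unit tags (`"500 um"`, `"0.4 kPa"`). The ones that matter
most:

| parameter | default | role |
|---|---|---|
| `R_cl`, `R_c` | 500 um, 5 um | cluster and cell reference radii; `2/R_c` scales all membrane exchange |
| `Phi0_ic`, `Phi0_ec` | 0.695, 0.005 | IC/EC porosities; their ratio controls how hard TJ sealing squeezes the EC reservoir |
| `E`, `nu` | 0.4 kPa, 0.3 | network stiffness; at 0.4 kPa the cluster is compliant and `p_w` is osmotically irrelevant |
| `D_i`, `D_w_ic` | 1e-12, 1e-9 m^2/s | gap-junction (IC) transport; zeroed when `gj_open = FALSE` |
| `D_i^e`, `D_w_ec` | 1e-9, 1e-7 m^2/s | cleft (EC) transport |
| `D_m` per ion | 1e-18 (Na, x10 in core), 5e-18 (K), 5e-17 (Cl) m^2/s | channel permeabilities; they set the -59.5 mV GHK resting potential |
| `D_w_m` | 1e-8 m^2/s | aquaporin permeability |

The region map places the sodium-channel-overexpressing core at
`[0, R_cl/2)`; the interface radius is itself a parameter so sweeps stay
possible, and the mesh always carries a node exactly on it so that the
material discontinuity never straddles a quadrature interval.

## Numerics

**Discretization.** Equal-order linear elements for all 11 nodal fields
on a graded radial mesh, 2-point Gauss quadrature with the axisymmetric
measure `R dR` evaluated at the quadrature points, backward-Euler time
stepping. No inf-sup pathology arises because `p_w` enters through the
algebraic volumetric constraint, not as an incompressibility multiplier
on `u` alone. The gradient of the eliminated `C_w` is reconstructed per
element from the two Gauss-point values of `J` — exact for fields linear
within an element.

**Plane stress.** The out-of-plane stretch solves
`sigma_zz = 0` pointwise by a safeguarded Newton
(`plane_stress_condense()`), polished to round-off so that the element
Jacobian can differentiate through it; the root satisfies
`|sigma_zz| <= 1e-10 E`. The condition zeroes the *full* zz stress
including the polarization terms; since those are orders of magnitude
below `p_w`, the alternative (mechanical + pressure only) differs
negligibly, and the polarization stresses can be switched off entirely
(`include_polarization = FALSE`) for conditioning experiments.

**Electrostatic regularization.** The physical Debye length (~1 nm)
cannot be meshed across a 500-um disc. The Gauss laws therefore use a
scaled solution permittivity `eps_r * eps_scale` (default `3e4`), which
thickens the charged boundary layers to a mesh-resolvable ~0.1 um while
leaving the quasi-neutral bulk — where the potentials are fixed by
charge balance, not by the permittivity — essentially unchanged; the
steady states are independent of `eps_scale`, and the test suite
compares bulk fields across scalings. The membrane/TJ capacitor
coefficients and the (tiny) Maxwell polarization stresses keep the
*physical* permittivities: the scaling is a regularization of the bulk
Gauss laws, not a change of the physics, and scaling the polarization
stress would have injected artificial stress where the physical one is
negligible.

**Mesh grading.** Geometric refinement toward the core/annulus
interface and the outer boundary (element sizes down to 0.05 um,
growth ratio 1.7, ~46 elements for the default benchmark mesh). A
uniform mesh is available for convergence studies.

**Nonlinear solve.** Monolithic damped Newton on all fields at once —
the membrane-capacitor condition couples the potential to the charge
stiffly, so splitting would need sub-iterations anyway. Element Jacobian
blocks are computed by central differences of the vectorized element
residual with per-field steps of `3e-6` times the field's
characteristic scale (displacement `R_cl`, pressure `E`, potentials
`RT/F ~ 26.7 mV`, water `1/v_w`, ions the initial osmotic
concentration); the assembled Jacobian is verified against a global
finite-difference Jacobian at 1e-5 relative. Rows are equilibrated and
columns scaled before the sparse direct solve; the line search only
enforces feasibility (positive concentrations and stretches) — there is
no clamping epsilon, so a solver straying out of the feasible set fails
loudly instead of silently.

**Time adaptivity and steadiness.** The step shrinks (factor 0.35) on
Newton failure and grows (factor 1.7, capped at 2 h) on easy
convergence, which resolves the benchmark's two-timescale structure
(seconds for the membrane transient, hours to steady state). Because
the printed source only says the steady state is reached "at about"
a given time without defining steadiness, the criterion here is a
relative rate threshold: max over nodes and fields of
`|dX/dt| / (|X| + 0.01 X_scale) < 1e-8 s^-1`. The trajectory is fully
deterministic.

## Verification strategy and what it does (not) show

The discretization is verified by a manufactured smooth solution of the
zero-mobile-species subsystem (displacement, pressure, both potentials
and EC water, coupled through the constraint, plane stress, fixed-ion
osmosis and transmembrane water exchange), with strong-form sources
obtained by Richardson numerical differentiation of the same pointwise
constitutive laws; the observed convergence order on uniform meshes of
8–32 elements is two. The species-coupling algebra is covered
separately by the dual-route flux oracle, the mobility
symmetry/definiteness properties and the dissipation inequality. The
two closed-form steady states (`open_boundary_steady()`,
`sealed_steady()`) are computed without the PDE solver and the solver is
required to match them to 1% at reduced resolution (it matches to
~0.1%); sealed runs conserve every species and water total to round-off
by construction of the Galerkin source terms.

The sealed steady state deserves one note: the closure implemented is
the exact membrane-equilibrium (Donnan) system — per-species totals,
water total, per-space electroneutrality, equal current osmolarities and
per-species concentration ratios `exp(z_i F psi_m / RT)`. For the
reference composition the solution lands on `psi_m = 0`, i.e. equal
current concentrations across the membrane, so the simpler
"concentrations equalize" description is recovered as an output rather
than imposed as an input.

The scenario conditions are the benchmark's: ideal dilute solutions, no
ion pumps, no voltage-gated or mechanosensitive channel dynamics, no
growth, a 1-D axisymmetric geometry, and a bath fixed at its initial
composition. Passing tests therefore demonstrate correctness of this
model and discretization — not fidelity to any particular real tissue,
where pumps and gating qualitatively change the steady states (with
pumps, the open-boundary state would not simply relax to the bath).

## Problem sizes and tolerances used in the tests

The default benchmark mesh has ~46 graded elements (517 unknowns); the
test suite uses ~32-element graded meshes for the steady cross-checks
and 6–32-element uniform meshes for Jacobian and convergence tests, and
integrates the open-boundary scenario to 4e5 s and the sealed one to
2e4 s of model time — both well past their slowest transients, chosen so
the finite-horizon error sits an order of magnitude inside the 1%
verification band. Newton tolerance is 1e-9 on the scaled update;
conservation drift is required below 1e-6 relative and observed at
round-off; the dissipation integral is required above `-1e-8` times its
magnitude scale.

## Known limitations

* First-order time accuracy (backward Euler); the fast membrane
  transient carries a visible discretization error under aggressive
  step growth (the concentration fields do not). A BDF2 option would be
  the natural extension.
* The permittivity scaling trades boundary-layer physics for
  tractability; charged-layer *profiles* within ~0.1 um of the boundary
  are regularized, only their integral effect on the bulk is faithful.
* One-dimensional axisymmetric geometry only; the constitutive layer is
  written against diagonal kinematics with the general tensor forms
  documented, so a 2-D/3-D extension changes the discretization, not
  the physics modules.
* No pumps, gating, mechanosensitivity, growth or external
  loads/fields/baths; these enter as future scenario terms, not as
  changes to the transport core.
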