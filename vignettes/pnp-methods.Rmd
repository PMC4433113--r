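---
title: "Methods: axisymmetric PNP simulation of nanopore ion transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: axisymmetric PNP simulation of nanopore ion transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpore)
```

## The physical model

`pnpore` solves the coupled Poisson and Nernst-Planck equations for ion
transport through a single nanopore in a dielectric membrane, in cylindrical
coordinates $(r, z)$ under rotational symmetry:

$$\nabla\cdot(\varepsilon\nabla V) = -F\sum_i z_i c_i, \qquad
  \mathbf{j}_i = -D_i\Big(\nabla c_i + c_i\frac{z_i e}{k_B T}\nabla V\Big),
  \qquad \frac{\partial c_i}{\partial t} = -\nabla\cdot\mathbf{j}_i .$$

The simulated domain is a cylinder of electrolyte split by a membrane with a
cylindrical or conical pore on the axis. The distinguishing modelling choice
is the boundary treatment: the Poisson equation is solved **through the
membrane** (relative permittivity $\varepsilon_{r,m}$), with fixed surface
charge densities $\sigma_S$ entering as interface source terms. No Neumann
condition $V_\perp = \sigma_S/\varepsilon$ is imposed at the pore wall and no
Donnan equilibrium condition at the pore mouths; ions sitting on the membrane
faces outside the pore can therefore participate in screening the wall
charge, and voltage equipotential lines need not be perpendicular to the
wall. Dirichlet voltages and bulk concentrations are applied only at the far
reservoir ends; the outer cylinder carries zero normal displacement and zero
ion flux, and all solid surfaces are ion-blocking.

The default system is the one the scenario presets describe: a 10 nm
diameter pore in a 20 nm Si$_3$N$_4$ membrane, 10 mM KCl
($D_{K^+} = 1.95\times10^{-9}$, $D_{Cl^-} = 2.03\times10^{-9}$ m$^2$/s),
reservoirs extending 250 nm from the membrane with a 250 nm domain radius.
At 10 mM the Debye length (`debye_length()`) is about 3 nm — comparable to
the pore radius and membrane thickness, which is what makes the scenarios
informative.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `membrane_thickness` | 20 nm | m | sets membrane capacitance, pore resistance |
| `pore_diameter` | 10 nm | m | small-opening diameter |
| `opening_angle` | 0 (cylinder); 20 for cones | degrees | full cone angle; large opening $d + 2L_m\tan(\theta/2)$ ($\approx$ 17 nm) |
| `reservoir_depth`, `domain_radius` | 250 nm | m | far-field extent; set solution resistance $R$ and access resistance |
| bulk concentration | 10 mM (100 mM thin-membrane preset) | mol/m$^3$ | Debye length, conductivity |
| `sigma` | $-50$ mC/m$^2$ ($-100$ for the thin preset) | C/m$^2$ | fixed wall/face charge |
| temperature | 298.15 K | K | thermal voltage 25.7 mV |
| $\varepsilon_{r,w}$, $\varepsilon_{r,m}$ | 78.4, 7.5 | — | water and Si$_3$N$_4$; 7.5 reproduces the 0.65 fF membrane capacitance of the canonical domain |
| `poisson_step_fraction` | 1/40 | — | $\delta t_P$ as fraction of $\tau_{RC}$ |
| `transport_step_fraction` | 1/5 | — | $\delta t_{NP}$ as fraction of $\Delta x^2/D$ |
| `rc_multiples` | 20 | — | duration of a recorded time simulation (0.2 µs) |
| `uniformity_tolerance` | 0.005 | — | plane-current stopping criterion |

Temperature, $\varepsilon_{r,w}$ and $\varepsilon_{r,m}$ are not stated by
the experimental sources for this system; room temperature and standard
water permittivity are assumed, and the membrane permittivity is pinned by
requiring the parallel-plate capacitance of the canonical domain to equal
the printed 0.65 fF. With the Nernst-Einstein conductivity of 10 mM KCl
(0.149 S/m) the simulated solution column then has $R \approx 17.0$ M$\Omega$
and $\tau = RC \approx 1.1\times10^{-8}$ s.

## Discretization

**Mesh.** The domain is meshed by a boundary-fitted, logically rectangular
graded grid: radial node positions are fractions of the local wall radius
$r_w(z)$ inside the pore and of $[r_w(z), R_{dom}]$ outside, so cylinder and
cone walls are exact grid lines; each quad is split into two triangles with
the diagonal direction alternating checkerwise. Elements are finest
(`min_element_size`) at the pore wall and the membrane faces and coarsen
geometrically (`mesh_growth_ratio`) toward the far boundaries. Three named
profiles are used throughout: `fine` (0.5 nm / 1.3), `coarse` (1 nm / 1.4,
the documented profile for the packaged reproductions, about 600 liquid
nodes for the canonical geometry), and `test` (2 nm / 1.6, direction-only
checks). Axisymmetric areas, volumes and surface integrals are exact for
the linear geometry (the integrand $2\pi r$ is linear per element), which is
why the charged-surface integrals match the closed-form cylinder and cone
areas to rounding error.

**Poisson.** Piecewise-linear finite elements over liquid and membrane with
the $2\pi r$ weight; surface charges enter as natural interface line
integrals. The stiffness matrix is factorized once (sparse Cholesky) and
reused for every right-hand side of the time integration. The axis needs no
boundary condition: the axisymmetric weight vanishes there.

**Transport.** Concentrations live on the liquid mesh nodes, piecewise
constant on the Voronoi (circumcentre) dual boxes, and fluxes flow along
triangle edges with Scharfetter-Gummel exponential fitting,
$J_{ij} = D\,w_{ij}\,[B(-u_{ij})c_i - B(u_{ij})c_j]$ with
$u_{ij} = z(V_i - V_j)/V_T$ and $B(x) = x/(e^x - 1)$, where the conductance
$w_{ij}$ is the revolved Voronoi facet area of the edge divided by the edge
length (in the plane this reduces to the classical P1 cotangent weights),
assembled over liquid triangles only. The scheme is exact for the two-point drift-diffusion
problem — fluxes vanish identically at Boltzmann concentration ratios — and
positivity-preserving under the explicit step bound. Zero-flux boundaries
need no special treatment (membrane triangles contribute no conductance);
the end-node layer is pinned to the bulk concentrations.

The node-centred ("box") placement, rather than triangle-centred cells, is
a deliberate compatibility choice: voltage, charge density (lumped nodal
load using the same box volumes) and fluxes share one discrete
Voronoi complex — the Poisson stiffness uses exactly the same revolved
facet conductances with $\varepsilon$ in place of $D B(\mp u)$, and the
fixed surface charge is apportioned to the interface nodes by the same dual
facets. Two cheaper alternatives fail in instructive ways. With
triangle-centred concentrations a staggered charge mode lies nearly in the
null space of the nodal charge load — the Poisson solve cannot see it, the
drift cannot damp it, and the dual-time-step iteration destabilizes at the
standard Poisson cadence. With node-centred concentrations but
median-dual masses or triangle-averaged radii in the stiffness, the mass
and stiffness seen by a purely axial field disagree between node classes
and between radial columns, so the discrete screening (Debye) response
converges to the wrong double layer at any resolution — a 15% error in the
equilibrium wall concentrations that no refinement removes. On the shared
Voronoi complex both pathologies vanish: z-only fields satisfy the 1D
equations at every radial column, the discrete dielectric relaxation
mirrors the continuum rate $\varepsilon/\sigma$, and the standard time
steps are stable.

## Time integration and steady state

Two time steps are used. The Poisson equation is re-solved every
$\delta t_P = \tau_{RC}/40$, where $\tau_{RC}$ is computed from the realized
domain ($R$ of the solution column in series with the membrane capacitance)
rather than hard-coded, so non-default geometries get a correct cadence.
Between refreshes the concentrations advance by explicit finite-volume steps
$\delta t_{NP} = \min(\delta t_P, \frac{1}{5}\Delta x^2_{\min}/D_{\max})$
with $\Delta x_{\min}$ the smallest edge of the realized mesh; each cycle
additionally clamps the step to 90% of the positivity bound
$\min_i(\mathrm{vol}_i / \sum_j a_{ij})$ of the current operator, which
matters near strongly charged walls where the drift coefficients exceed
their diffusive values. A recorded time simulation runs 20 RC constants
(0.2 µs for the canonical domain).

**Steady-state acceleration.** True steady state is unreachable by direct
time stepping: after the membrane capacitor charges, convergence is limited
by co-diffusion of the salt with the intermediate coefficient
$D_{int} = 2D_K D_{Cl}/(D_K + D_{Cl})$, which needs
$(250\,\mathrm{nm})^2/D_{int} \approx 30$ µs to traverse the reservoirs —
hundreds of thousands of Poisson steps. The accelerator alternates:
(1) time-simulate `steady_rc_multiples` (default 2) RC constants;
(2) check whether each species' current through every plane parallel to the
membrane is uniform to 0.5% of the total current (or of the estimated
current at 0.1 V through the pore-plus-access resistance when no bias is
applied); (3) if not, solve the *frozen-field* steady Nernst-Planck
equation per species, average the resulting concentration changes pointwise
over the two species, damp by 0.5, and add the result to **both** species.
For a 1:$-1$ electrolyte this common-mode shift leaves the charge density —
and therefore the field — exactly unchanged, while teleporting the slow
co-diffusion mode toward its steady profile. The differential (charge-
carrying) mode, which relaxes on the fast RC scale, is handled by the time
chunks in between.

Two details of this loop were genuinely open design choices. First, the
"average change" is applied pointwise (a spatially varying common-mode
field): a single volume-averaged scalar, the other reading, cannot correct
the spatially structured salt deficit and was measured to contract the
uniformity metric by only $\approx$1.7% per outer iteration, versus a
handful of iterations for the pointwise form. Second, the shift is damped
by 0.5 and clamped from below at $-\min(c_K, c_{Cl})$ per node (a clamp on
the common mode, so it too preserves the field): the undamped shift
overshoots where strong double layers re-shape the field between
iterations and the outer loop oscillates. With these choices the uncharged
scenarios converge in 2–5 outer iterations and the charged ones in 10–45.

**Equilibrium initialization.** Charged scenarios start from the
equilibrium double layer at 0 V. Solving it by time integration is
painfully stiff: the unscreened fixed charge initially puts tens of volts
on the wall. The equilibrium is instead obtained by a damped Newton solve
of the nonlinear Poisson-Boltzmann system (Boltzmann concentrations of the
running potential, Jacobian augmented by the lumped screening response,
Newton steps clamped to 1 V, exponents clamped to ±60 during early
iterations), which converges in a few dozen Poisson-sized solves; the
regular steady-state loop then polishes to the documented criterion. The
resulting double layer reproduces the closed-form Gouy-Chapman profile of a
flat charged wall to a few percent on a 0.1 nm mesh and balances the fixed
surface charge to better than 1%.

## Observables

Plane currents are the conservation-exact sums of $F z_i$ times the SG edge
fluxes crossing each axial plane between mesh rows; they are the
convergence criterion and the reported current. The common/differential
flux decomposition $\mathbf{j}_c = (\mathbf{j}_K + \mathbf{j}_{Cl})/2$,
$\mathbf{j}_d = (\mathbf{j}_K - \mathbf{j}_{Cl})/2$ reconstructs the
species fluxes exactly. Electrochemical potentials
$E_{ec,i} = z_i e V + k_B T\ln(c_i/c_{B,i})$ are evaluated per node. The
bias-induced membrane polarization charge is reported as
$\sigma_{pol} = -\varepsilon_0\varepsilon_{r,m}E_{\perp,membrane}$ (normal
oriented into the membrane): this is zero at equilibrium and equals the
series-capacitor value $\varepsilon_0\varepsilon_{r,m}\Delta V_m/L_m$ under
bias. The raw one-sided displacement jump minus $\sigma_S$ is *not* used as
the observable because displacement continuity makes it vanish identically
at an uncharged interface; the membrane-side displacement is the quantity
with a single-number far-field meaning, and its area-weighted average over
the outer half of the face radius is what `face_polarization()` reports.
I-V sweeps record, per bias, the current 0.2 µs after the voltage step and
the accelerated steady-state current, each bias starting from the shared
0 V equilibrium state; chord conductance $G = I/V$, differential
conductance $g = \partial I/\partial V$ (central differences) and the
rectification ratio $G(+V)/G(-V)$ are derived from the sweep.

## What the scenarios emulate — and what they do not

The presets form the canonical simulation study: an uncharged cylinder
(near-ohmic, slightly super-linear); a uniformly charged pore
(counter-ion-selective, concentration polarization, steady current a few
percent below the 0.2 µs current at 0.25 V); a charged pore in an uncharged
membrane (limiting conductance: $g$ decreases with $|V|$ toward a
constant); an asymmetrically charged pore (ion current rectification
without a kink); conical pores (rectification set by which opening
depletes); and a thin-membrane, high-charge, 100 mM case whose
voltage-induced polarization charges produce an overlimiting conductance.

These are continuum scenarios with ideal electrolytes. Passing tests shows
the solver reproduces the continuum PNP physics at desk-scale resolution —
it does not validate the continuum description itself (at 10 mM there are
only $\approx$19 ions in the uncharged pore and the mean ion spacing is the
Debye length), nor fluid-dynamic effects: electro-osmosis and microvortices
are outside the model, so simulated currents can underestimate measured
ones. Voltage-step transients are likewise not comparable to real
recordings, which are dominated by chip parasitics and amplifier response.
Percentage-level statements (the 2%, 4% and 3 mC/m$^2$ figures) are
asserted on the documented coarse profile; absolute currents on that
profile carry a few-percent discretization bias that largely cancels in
the difference ratios reported.

## Numerical choices and degenerate inputs

* Linear solves: sparse Cholesky (Poisson, cached; Newton Jacobians) and
  sparse LU (steady transport, rows balanced by the flux-coefficient scale).
* Explicit-step safety: concentrations below $-10^{-6}c_B$ abort with a
  stability error; smaller negatives are clipped to zero.
* Zero bias uses the estimated reference current at 0.1 V
  ($I_{ref} = V_{ref}/(R_{pore} + R_{access})$, Hall access resistance per
  opening, mean diameter for cones) to normalize the uniformity metric.
* Degenerate inputs rejected at construction: non-electroneutral bulk,
  zero pore diameter, cone angles $\ge 90^\circ$, growth ratios $\le 1$,
  non-1:1 electrolytes for the Gouy-Chapman oracle.
* Determinism: the solver has no random state; identical inputs give
  byte-identical outputs.

## Known limitations

* The asymmetric charge map places charge on the left face plus the left
  half of the pore wall; the exact extent in the source figures is not
  recoverable from text, and rectification ratios depend on it.
* Hall's access-resistance formula is generalized to cones by using each
  opening's own diameter and the mean diameter for the internal pore
  resistance; this only affects the zero-bias normalization scale.
* The uniform-charge conical scenario is the one case where the desk-scale
  solver does not reproduce the expected (positive-favored) direction. The spatial
  concentration-polarization pattern agrees (at positive bias: depletion
  outside the small opening, enrichment inside the pore), and the two
  companion rectifiers come out as expected (asymmetric cylinder strongly
  positive-favored; pore-only cone negative-favored). But the uniform cone's
  net direction is a 1–3% balance between the in-pore double-layer
  conduction gain and the tip-side depletion penalty, and at every
  resolution and bias we can afford (ratios 0.97–1.00 from the 2 nm to the
  0.5 nm profile, ±0.125 to ±1 V) the depletion penalty wins, where the
  reference behaviour has the in-pore gain winning. The in-pore double layer —
  tip radius 2.5 nm against a 3 nm Debye length, resolved by only 3–6
  radial intervals here — is the weakest-resolved structure in the model,
  and this check should be treated as unresolved at desk scale rather than
  as a property of the continuum model.
* High-aspect far-field elements trade radial resolution for speed; the
  few-percent absolute-current bias this causes is shared by all runs on a
  profile and cancels in the reported ratios.
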