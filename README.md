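# pnpore

Axisymmetric time-dependent and steady-state **Poisson–Nernst–Planck (PNP)**
simulation of ion currents through single nanopores in dielectric membranes,
for people studying ion current rectification, limiting and overlimiting
conductances in solid-state nanopores (and for anyone who needs a compact,
fully scriptable continuum electrodiffusion solver in R).

## The model

The solver couples, in cylindrical coordinates $(r,z)$,

$$\nabla\cdot(\varepsilon\nabla V) = -F\sum_i z_i c_i,\qquad
\mathbf j_i = -D_i\Big(\nabla c_i + c_i\,\frac{z_i e}{k_BT}\,\nabla V\Big),\qquad
\partial_t c_i = -\nabla\cdot\mathbf j_i,$$

for K⁺ and Cl⁻ around a cylindrical or conical pore through a Si₃N₄
membrane. The Poisson equation is solved **through the membrane** with fixed
surface charges as interface sources — no wall Neumann condition
$V_\perp=\sigma_S/\varepsilon$ and no Donnan boundary at the pore mouths —
so screening by ions on the membrane outside the pore is part of the
solution. Voltages and bulk concentrations are imposed only at the far
reservoir ends.

Numerics: piecewise-linear finite elements for the voltage;
Scharfetter–Gummel box-scheme finite volumes (node-centred, on the same
graph) for the concentrations; a dual time step (Poisson refresh at a
fraction of the membrane RC time $\tau = RC \approx 10^{-8}$ s, transport at
a fraction of the diffusive limit $\Delta x^2/D$); and a steady-state
accelerator that alternates short time simulations with frozen-field steady
Nernst–Planck solves and field-preserving common-mode concentration shifts,
stopping when each species' current through every plane parallel to the
membrane is uniform to 0.5 % of the total current. The methods vignette
(`vignettes/pnp-methods.Rmd`) derives and motivates all of this.

## Worked example

Closed-form sanity scales for the canonical system (10 nm pore, 20 nm
membrane, 10 mM KCl):

```r
library(pnpore)
oracle_table()
#>                         quantity        value units
#>                  thermal voltage 2.569258e+01    mV
#>                     Debye length 3.040119e+00    nm
#>                      ion spacing 4.362543e+00    nm
#>                     conductivity 1.494640e-01   S/m
#>                            D_int 1.989196e-09 m^2/s
#>    co-diffusion time (reservoir) 3.141973e+01    us
#>              solution resistance 1.703741e+01  Mohm
#>             membrane capacitance 6.519434e-01    fF
#>                 RC time constant 1.110742e-08     s
#>                reference current 4.214434e+01    pA
#>              cone large diameter 1.000000e+01    nm
```

A small I–V sweep of the uncharged cylindrical pore (the `test` mesh profile
keeps this to about a minute; `coarse` is the documented profile for
quantitative numbers):

```r
scen <- preset("uncharged_cyl", profile = "test")
sweep <- run_iv_sweep(scen, bias = c(-0.25, 0.25))
sweep$iv
#>       V        I_time      I_steady             K            Cl converged iterations
#> 1 -0.25 -1.096673e-10 -1.098246e-10 -5.383036e-11 -5.599425e-11         1          5
#> 2  0.25  1.096674e-10  1.098246e-10  5.383036e-11  5.599425e-11         1          5
```

Reading this: at ±0.25 V the pore carries about 110 pA; the accelerated
steady-state current exceeds the current recorded 0.2 µs after the voltage
step by ~0.15 %, the K⁺:Cl⁻ split follows the
diffusion-coefficient ratio, the I–V is antisymmetric to machine precision,
and each bias converged in 5 outer iterations of the acceleration loop.
`steady_state_solve()` guarantees, at convergence, per-species plane
currents uniform to 0.5 %.

Charged scenarios work the same way: `preset("a_uniform")` (pore wall and
both faces at −50 mC/m²), `preset("b_pore_only")` (limiting conductance),
`preset("c_asymmetric")` (ion current rectification),
`preset("cone_uniform")` / `preset("cone_pore_only")` (20° cones), and
`preset("overlimiting_thin")` (10 nm pore, 5 nm membrane, 100 mM KCl,
−100 mC/m²: overlimiting conductance from voltage-induced polarization
charges). Fields can be exported to VTK (`export_state_vtk()`), sweeps to
CSV (`report_sweep()`), and a measured I–V table can be overlaid without
rescaling (`overlay_measured()`).

A thin command-line front end sits in `inst/cli/pnpore.R`:

```sh
Rscript inst/cli/pnpore.R validate
Rscript inst/cli/pnpore.R sweep --scenario c_asymmetric --out out/
Rscript inst/cli/pnpore.R run --scenario a_uniform --bias 0.25 --out out/
Rscript inst/cli/pnpore.R mesh --scenario cone_uniform --out mesh.vtk
```

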