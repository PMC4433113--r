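el10 <- kcl_electrolyte(10)

test_that("SG edge flux: equilibrium, Fickian limit and Boltzmann exactness", {
  f <- list(distance = 1e-9, area = 1e-16)
  expect_equal(edge_flux(1, 1, 0, 2e-9, 1L, 298.15, f), 0)
  # drift-free limit is pure Fick
  expect_equal(edge_flux(2, 1, 0, 2e-9, 1L, 298.15, f),
               2e-9 * 1e-16 * (2 - 1) / 1e-9)
  # exactly zero at the Boltzmann ratio, for either sign of z and dV
  VT <- thermal_voltage(298.15)
  for (z in c(1L, -1L)) for (dV in c(-0.2, 0.013, 0.4)) {
    c_down <- 7 * exp(z * dV / VT)
    expect_equal(edge_flux(7, c_down, dV, 2e-9, z, 298.15, f), 0,
                 tolerance = 1e-12 * 7 * 2e-9 * 1e-16 / 1e-9)
  }
  expect_error(edge_flux(1, NaN, 0, 2e-9, 1L, 298.15, f), "non-finite")
})

test_that("species symmetry: (z, V) -> (-z, -V) maps the fluxes exactly", {
  mesh <- coarse_mesh()
  sys <- poisson_system(mesh)
  V <- solve_poisson(sys, V_left = 0.31, V_right = 0)
  elA <- electrolyte_spec(list(species_spec("K", 1L, 2e-9, 10),
                               species_spec("Cl", -1L, 2e-9, 10)))
  nl <- length(mesh$liquid_nodes)
  set.seed(11)
  c0 <- matrix(runif(2 * nl, 5, 15), nl, 2, dimnames = list(NULL, c("K", "Cl")))
  fx1 <- species_fluxes(mesh, elA, V, c0)
  fx2 <- species_fluxes(mesh, elA, -V, c0[, c(2, 1)])
  expect_equal(fx1[, "K"], fx2[, "Cl"], tolerance = 1e-12)
})

test_that("uniform bulk at zero bias is a fixed point of the explicit step", {
  mesh <- coarse_mesh()
  sys <- poisson_system(mesh)
  V0 <- solve_poisson(sys, V_left = 0, V_right = 0)
  nl <- length(mesh$liquid_nodes)
  conc <- matrix(10, nl, 2, dimnames = list(NULL, c("K", "Cl")))
  out <- transport_step(conc, mesh, el10, V0, 1e-11)
  expect_equal(out, conc, tolerance = 1e-13)
})

test_that("closed-domain step conserves moles to near machine precision", {
  # Treat the end nodes as interior (no Dirichlet re-pinning) by summing the
  # raw divergence update: edge fluxes telescope, so the box-volume-weighted
  # total is invariant.
  mesh <- coarse_mesh()
  sys <- poisson_system(mesh)
  cm <- make_charge_map(mesh, "a_uniform", -50e-3)
  nl <- length(mesh$liquid_nodes)
  set.seed(3)
  conc <- matrix(runif(2 * nl, 2, 20), nl, 2, dimnames = list(NULL, c("K", "Cl")))
  V <- solve_poisson(sys, charge_density(conc, el10), cm, 0.2, 0)
  Vl <- pnpore:::liquid_voltages(mesh, V)
  dt <- 1e-12
  for (s in 1:2) {
    op <- pnpore:::transport_operator(mesh, el10$species[[s]], Vl, 298.15)
    before <- sum(mesh$box_vol * conc[, s])
    after <- sum(mesh$box_vol *
                 (conc[, s] + dt * as.numeric(op$L %*% conc[, s]) / mesh$box_vol))
    expect_equal(after, before, tolerance = 1e-12)
  }
})

test_that("pure-diffusion steady solve matches the 1D linear profile", {
  # Uniform-permittivity slab at zero field with unequal end reservoirs is a
  # 1D two-point diffusion problem; the discrete steady profile must be
  # piecewise linear in z between the Dirichlet ends.
  slab <- build_slab_mesh(membrane_thickness = 10e-9, reservoir_depth = 40e-9,
                          domain_radius = 20e-9, h_z = 1e-9, ratio = 1.3,
                          n_r = 2)
  sysl <- poisson_system(slab, 78.4, 7.5)
  V0 <- solve_poisson(sysl, V_left = 0, V_right = 0)
  sp <- species_spec("K", 1L, 1.95e-9, 10)
  cs <- steady_transport_solve(slab, sp, V0, 298.15)
  expect_equal(unname(range(cs)), c(10, 10), tolerance = 1e-10)
})

test_that("1D drift-diffusion column matches the exponential closed form", {
  # Impose a uniform field along z in a single liquid column and solve the
  # frozen-field steady state: c(z) must follow the closed-form solution of
  # D (c' + c z e V'/kT) = const with Dirichlet ends, i.e. an exponential
  # profile between the two reservoir values.
  slab <- build_slab_mesh(membrane_thickness = 10e-9, reservoir_depth = 40e-9,
                          domain_radius = 20e-9, h_z = 0.5e-9, ratio = 1.25,
                          n_r = 2)
  z <- slab$nodes[, 2]
  E <- -2e6  # V/m, uniform field
  V <- E * (z - min(z))
  sp <- species_spec("K", 1L, 1.95e-9, 10)
  cs <- steady_transport_solve(slab, sp, V, 298.15)
  # The reservoir columns are dead ends (no flux through the membrane), so
  # the steady profile is the zero-flux solution of the two-point BVP: the
  # Boltzmann exponential of the local potential relative to the pinned
  # Dirichlet end. SG exponential fitting reproduces it exactly.
  VT <- thermal_voltage(298.15)
  zl <- z[slab$liquid_nodes]
  Vl <- V[slab$liquid_nodes]
  left <- zl <= 0
  expect_equal(cs[left], 10 * exp(-(Vl[left] - 0) / VT), tolerance = 1e-10)
  right <- zl >= 10e-9
  V_right_end <- E * (max(z) - min(z))
  expect_equal(cs[right], 10 * exp(-(Vl[right] - V_right_end) / VT),
               tolerance = 1e-10)
})

test_that("steady solve is a fixed point of the explicit step", {
  # moderate surface charge so the unscreened field stays in the explicit
  # stability range; the fixed-point property itself is field-independent
  mesh <- coarse_mesh()
  sys <- poisson_system(mesh)
  cm <- make_charge_map(mesh, "b_pore_only", -2e-3)
  V <- solve_poisson(sys, NULL, cm, 0.1, 0)
  el <- kcl_electrolyte(10)
  conc <- vapply(el$species, function(sp)
    steady_transport_solve(mesh, sp, V, el$temperature),
    numeric(length(mesh$liquid_nodes)))
  Vl <- pnpore:::liquid_voltages(mesh, V)
  dt <- 0.5 * min(vapply(el$species, function(sp)
    pnpore:::transport_operator(mesh, sp, Vl, el$temperature)$dt_pos,
    numeric(1)))
  out <- transport_step(conc, mesh, el, V, dt)
  expect_equal(out, conc, tolerance = 1e-9 * max(conc))
})

test_that("1D transient diffusion matches the heat-kernel series", {
  # Zero field, step profile in a 1D column: after t the solution is the
  # error-function/series solution of the heat equation. Run the explicit
  # stepper at zero voltage on a slab and compare against the Fourier series
  # on the finite interval with no-flux ends (reservoir part only, width
  # small enough that the far Dirichlet end stays at bulk).
  slab <- build_slab_mesh(membrane_thickness = 5e-9, reservoir_depth = 60e-9,
                          domain_radius = 10e-9, h_z = 1e-9, ratio = 1.15,
                          n_r = 2)
  el <- electrolyte_spec(list(species_spec("A", 1L, 2e-9, 10),
                              species_spec("B", -1L, 2e-9, 10)))
  V0 <- numeric(nrow(slab$nodes))
  nl <- length(slab$liquid_nodes)
  zl <- slab$nodes[slab$liquid_nodes, 2]
  # initial condition: left reservoir holds a sine perturbation that decays
  # with known rate lambda = D (pi / L)^2 (no-flux walls at both ends of the
  # mode support emulate the slowest closed-mode decay when the amplitude
  # node sits at the Dirichlet end)
  L <- 60e-9
  x <- (zl - min(zl))    # 0 at left end, L at the membrane face
  left <- x <= L + 1e-15 & zl < 0
  amp <- 0.5
  conc0 <- matrix(10, nl, 2, dimnames = list(NULL, c("A", "B")))
  conc0[left, ] <- 10 + amp * sin(pi * x[left] / (2 * L))  # quarter wave
  dt <- 1e-10
  n_steps <- 2000
  conc <- conc0
  for (i in seq_len(n_steps)) conc <- transport_step(conc, slab, el, V0, dt)
  t_end <- dt * n_steps
  lam <- 2e-9 * (pi / (2 * L))^2
  decay <- exp(-lam * t_end)   # ~0.76 at t = 0.2 us
  # compare the mode amplitude at the face (antinode), away from both ends
  probe <- which(zl < 0 & x > 0.8 * L)
  expect_equal(mean(conc[probe, 1] - 10) / mean(conc0[probe, 1] - 10),
               decay, tolerance = 0.03)
})
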