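el10 <- kcl_electrolyte(10)

test_that("plane currents: equilibrium zero, ohmic column, exact totals", {
  sim <- test_sim()
  eq <- initialize_equilibrium(sim)
  pc <- plane_current(sim, eq, 10e-9)
  expect_lt(abs(pc["I_total"]), 1e-3 * sim$I_ref)
  # total is the species sum at every plane, exactly
  st <- initial_state(sim, 0.5, 0)
  prof <- current_profile(sim, st)
  expect_equal(prof$I_total, unname(rowSums(prof$I)))
  # uniform bulk column with an imposed uniform field: I = sigma E A per
  # species fraction sigma_i = F^2 z_i^2 c D_i / RT, checked in a reservoir
  # plane far from the pore where the geometry is a full cylinder
  slab <- build_slab_mesh(membrane_thickness = 10e-9, reservoir_depth = 50e-9,
                          domain_radius = 100e-9, h_z = 2e-9, ratio = 1.3,
                          n_r = 4)
  E <- 1e6
  V <- -E * slab$nodes[, 2]
  nl <- length(slab$liquid_nodes)
  conc <- matrix(10, nl, 2, dimnames = list(NULL, c("K", "Cl")))
  sims <- list(mesh = slab, config = simulation_config())
  fx <- species_fluxes(slab, el10, V, conc)
  prof2 <- pnpore:::profile_from_fluxes(slab, el10, fx)
  k <- physical_constants()
  RT <- k$k_B * k$N_A * 298.15
  A <- pi * (100e-9)^2
  for (s in c("K", "Cl")) {
    sigma_s <- k$F^2 * 1 * 10 * el10$species[[s]]$D / RT
    expect_equal(mean(prof2$I[prof2$z < 0, s]), sigma_s * E * A,
                 tolerance = 0.01)
  }
})

test_that("mode decomposition reconstructs and degenerates correctly", {
  set.seed(5)
  jK <- rnorm(40); jCl <- rnorm(40)
  m <- mode_decomposition(cbind(jK, jCl))
  expect_equal(m$j_c + m$j_d, jK)
  expect_equal(m$j_c - m$j_d, jCl)
  same <- mode_decomposition(cbind(jK, jK))
  expect_equal(same$j_d, rep(0, 40))
  opp <- mode_decomposition(cbind(jK, -jK))
  expect_equal(opp$j_c, rep(0, 40))
  expect_error(mode_decomposition(cbind(jK, jK, jK)), "two species")
})

test_that("electrochemical potential vanishes in bulk and at equilibrium", {
  sim <- test_sim(charges = charge_spec("a_uniform", -50e-3))
  eq <- initialize_equilibrium(sim)
  for (s in c("K", "Cl")) {
    Eec <- electrochemical_potential(sim, eq, s)
    # Boltzmann cancellation: zero through the double layer too
    expect_lt(max(abs(Eec), na.rm = TRUE) / physical_constants()$e, 2e-3)  # < 2 meV
  }
  expect_error(electrochemical_potential(sim, eq, "Na"), "unknown species")
})

test_that("polarization charge: zero at equilibrium, capacitor value at bias", {
  # no-pore slab under bias: at equilibrium (blocked membrane) the membrane
  # field supports the full double-layer-screened drop, sigma_pol =
  # eps0 eps_m dV_m / L_m with dV_m from the series-capacitor division of
  # the final screened state (all of the applied bias minus the double
  # layer drops)
  k <- physical_constants()
  mesh <- dl_slab_mesh()
  cfg <- simulation_config(controls = test_controls())
  sim <- structure(list(config = cfg, mesh = mesh,
                        charge_map = make_charge_map(mesh, "uncharged"),
                        system = poisson_system(mesh, 78.4, 7.5),
                        plan = time_stepping_plan(cfg, mesh),
                        vol = mesh$box_vol,
                        I_ref = estimate_reference_current(cfg)),
                   class = "pnp_simulation")
  eq <- initial_state(sim, 0, 0)
  pol0 <- polarization_charge_density(sim, eq)
  expect_equal(max(abs(pol0$sigma_pol)), 0, tolerance = 1e-15)
  # relax under 0.2 V: blocked slab reaches equilibrium; nearly the whole
  # bias then sits across the membrane
  out <- run_time_simulation(sim, initial_state(sim, 0.2, 0),
                             duration = 10 * sim$plan$tau_RC,
                             V_left = 0.2, V_right = 0)
  polV <- polarization_charge_density(sim, out$state)
  sig_expect <- k$eps0 * 7.5 * 0.2 / 10e-9   # full drop across 10 nm slab
  expect_equal(mean(abs(polV$sigma_pol)), sig_expect, tolerance = 0.1)
})

test_that("iv_curve computes conductances and rectification", {
  # ohmic line: g = G = G0 everywhere, ratio 1
  V <- seq(-0.5, 0.5, 0.25)
  G0 <- 2e-9
  curve <- iv_curve(V, G0 * V)
  expect_equal(curve$g, rep(G0, 5))
  expect_equal(curve$G[curve$V != 0], rep(G0, 4))
  expect_equal(curve$rectification[curve$V > 0], rep(1, 2))
  # rectifying synthetic curve
  I <- ifelse(V > 0, 2 * V, V) * 1e-9
  r <- iv_curve(V, I)
  expect_true(all(r$rectification[r$V > 0] == 2))
  expect_error(iv_curve(c(0.1, 0.1), c(1, 2) * 1e-9), "duplicate")
  expect_error(iv_curve(0.1, 1e-9), "at least 2")
})

test_that("ion counts: ~19 ions in the uncharged pore at 10 mM, linear in c", {
  mesh <- coarse_mesh()
  nl <- length(mesh$liquid_nodes)
  conc <- matrix(10, nl, 2)
  n_ions <- ions_in_volume(mesh, conc)
  expect_equal(n_ions, 19, tolerance = 0.02)
  expect_lt(n_ions, 20)
  expect_equal(ions_in_volume(mesh, 2 * conc), 2 * n_ions)
  expect_equal(ions_in_volume(mesh, 0 * conc), 0)
})
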