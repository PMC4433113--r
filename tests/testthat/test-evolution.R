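test_that("time-stepping plan obeys the dual-step relations", {
  cfg <- simulation_config(controls = test_controls())
  mesh <- build_mesh(cfg$geometry, cfg$controls)
  plan <- time_stepping_plan(cfg, mesh)
  rc <- membrane_RC(cfg$geometry, cfg$electrolyte, cfg$eps_r_membrane)
  expect_equal(plan$tau_RC, rc$tau)
  expect_equal(plan$dt_P, rc$tau / 40)
  expect_lte(plan$dt_NP, plan$dt_P)
  expect_equal(plan$dt_NP, min(plan$dt_P, 0.2 * mesh$h_min^2 / 2.03e-9))
  expect_gte(plan$inner_steps * plan$dt_NP, plan$dt_P)
  expect_equal(plan$duration, 20 * rc$tau)
})

test_that("convergence metric is the normalized worst-species spread", {
  prof <- list(z = 1:5,
               I = cbind(K = c(1, 1.004, 1.001, 1, 1.002) * 1e-10,
                         Cl = c(1, 1.002, 1.001, 1, 1.001) * 1e-10))
  prof$I_total <- rowSums(prof$I)
  scale <- abs(mean(prof$I_total))
  expect_equal(convergence_metric(prof, scale), 0.004e-10 / scale)
  # perfectly uniform profile
  prof0 <- list(z = 1:3, I = cbind(K = rep(1e-10, 3), Cl = rep(2e-10, 3)))
  expect_equal(convergence_metric(prof0, 1e-10), 0)
  expect_error(convergence_metric(list(I = matrix(numeric(0), 0, 2)), 1),
               "empty")
  expect_error(convergence_metric(prof0, 0), "scale")
})

test_that("uncharged equilibrium is the uniform bulk with zero current", {
  sim <- test_sim()
  eq <- initialize_equilibrium(sim)
  expect_equal(max(abs(eq$conc - 10)), 0, tolerance = 1e-9)
  prof <- current_profile(sim, eq)
  expect_lt(max(abs(prof$I_total)), 0.005 * sim$I_ref)
})

test_that("equilibrium double layer matches Gouy-Chapman within 5%", {
  # Flat charged membrane faces (slab fixture, fine 0.25 nm wall spacing):
  # compare the solver's equilibrium counter-ion profile against the
  # closed-form Gouy-Chapman solution along the left face.
  mesh <- dl_slab_mesh()
  el <- kcl_electrolyte(10)
  cfg <- simulation_config(controls = test_controls())
  sim <- structure(list(config = cfg, mesh = mesh,
                        charge_map = make_charge_map(mesh, "a_uniform", -50e-3),
                        system = poisson_system(mesh, 78.4, 7.5),
                        plan = time_stepping_plan(cfg, mesh),
                        vol = mesh$box_vol,
                        I_ref = estimate_reference_current(cfg)),
                   class = "pnp_simulation")
  eq <- initialize_equilibrium(sim)
  # nodes on the axis column in the left reservoir, within 2 Debye lengths
  nl_idx <- mesh$liquid_nodes
  r <- mesh$nodes[nl_idx, 1]; z <- mesh$nodes[nl_idx, 2]
  sel <- which(r == 0 & z <= 0 & z > -6e-9)
  x <- -z[sel]                       # distance from the left face
  gc <- gouy_chapman_profile(-50e-3, el, x = x)
  expect_equal(eq$conc[sel, "K"], unname(gc$concentration[, "K"]),
               tolerance = 0.05)
  expect_equal(eq$conc[sel, "Cl"], unname(gc$concentration[, "Cl"]),
               tolerance = 0.05)
  # screening: the integrated double-layer charge balances the fixed charge
  rho <- charge_density(eq$conc, el)
  Q_dl <- sum(rho * mesh$box_vol)
  Q_s <- total_surface_charge(mesh, sim$charge_map)
  expect_equal(-Q_dl / Q_s, 1, tolerance = 0.02)
})

test_that("zero-bias time evolution from equilibrium is stationary", {
  sim <- test_sim(charges = charge_spec("b_pore_only", -50e-3))
  eq <- initialize_equilibrium(sim)
  out <- run_time_simulation(sim, eq, duration = 2 * sim$plan$tau_RC,
                             V_left = 0, V_right = 0)
  drift <- max(abs(out$state$conc - eq$conc)) / max(eq$conc)
  expect_lt(drift, 1e-3)
})

test_that("common-mode shift step leaves the Poisson solution unchanged", {
  sim <- test_sim(charges = charge_spec("a_uniform", -50e-3))
  eq <- initialize_equilibrium(sim)
  el <- sim$config$electrolyte
  V1 <- solve_poisson(sim$system, charge_density(eq$conc, el),
                      sim$charge_map, 0.25, 0)
  shifted <- eq$conc + 1.7   # common-mode shift on both species
  V2 <- solve_poisson(sim$system, charge_density(shifted, el),
                      sim$charge_map, 0.25, 0)
  expect_equal(V1, V2, tolerance = 1e-12)
})

test_that("steady state is path-independent and plane currents uniform", {
  sim <- test_sim()
  eq <- initialize_equilibrium(sim)
  # path 1: straight to 0.4 V
  s1 <- steady_state_solve(sim, eq, V_left = 0.4, V_right = 0)
  # path 2: via an intermediate bias
  mid <- steady_state_solve(sim, eq, V_left = 0.2, V_right = 0)
  s2 <- steady_state_solve(sim, mid$state, V_left = 0.4, V_right = 0)
  I1 <- mean(s1$report$profile$I_total)
  I2 <- mean(s2$report$profile$I_total)
  expect_equal(I1, I2, tolerance = 2 * sim$config$controls$uniformity_tolerance)
  # the 0.5% uniformity criterion holds on every converged run
  for (rep in list(s1$report, s2$report)) {
    expect_true(rep$converged)
    expect_lte(rep$metric, 0.005)
  }
})
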