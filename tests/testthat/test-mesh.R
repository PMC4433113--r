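test_that("cone large diameter follows d + 2 L tan(angle/2)", {
  expect_equal(cone_large_diameter(10e-9, 20e-9, 20) * 1e9, 17, tolerance = 0.01)
  expect_equal(cone_large_diameter(10e-9, 20e-9, 0), 10e-9)
  expect_equal(cone_large_diameter(10e-9, 20e-9, 45),
               10e-9 + 2 * 20e-9 * tan(22.5 * pi / 180))
  expect_error(cone_large_diameter(10e-9, 20e-9, 90), "angle")
})

test_that("mesh partitions the domain exactly and is fully tagged", {
  mesh <- coarse_mesh()
  g <- mesh$geometry
  A_domain <- g$domain_radius * (2 * g$reservoir_depth + g$membrane_thickness)
  expect_equal(sum(mesh$area), A_domain, tolerance = 1e-12)
  expect_setequal(unique(mesh$region), c("liquid", "membrane"))
  expect_setequal(unique(mesh$boundary$tag),
                  c("left_end", "right_end", "outer_cylinder", "axis"))
  expect_true(all(mesh$nodes[, 1] >= 0))
  # membrane occupies exactly the r > wall, 0 < z < L_m block
  mem <- mesh$region == "membrane"
  expect_true(all(mesh$zbar[mem] > 0 & mesh$zbar[mem] < g$membrane_thickness))
  expect_true(all(mesh$rbar[mem] > g$pore_diameter / 2))
  # dual boxes partition the liquid volume
  expect_equal(sum(mesh$box_vol), sum(mesh$volume[mesh$region == "liquid"]),
               tolerance = 1e-12)
  # transport conductances are non-negative (M-matrix requirement)
  expect_true(all(mesh$nedge$w >= 0))
  expect_gt(min(mesh$quality), 0.01)
})

test_that("cylinder and cone walls lie on the prescribed lines", {
  mesh <- coarse_mesh()
  wall <- mesh$interface[mesh$interface$part == "pore_wall", ]
  expect_true(all(abs(wall$r_mid - 5e-9) < 1e-15))

  cone <- build_mesh(geometry_spec(opening_angle = 20,
                                   large_opening_side = "right"),
                     coarse_controls())
  wallc <- cone$interface[cone$interface$part == "pore_wall", ]
  expect_equal(wallc$r_mid, 5e-9 + wallc$z_mid * tan(10 * pi / 180),
               tolerance = 1e-9)
})

test_that("charged-interface integrals match the analytic surface areas", {
  mesh <- coarse_mesh()
  g <- mesh$geometry
  rw <- g$pore_diameter / 2
  A_face <- pi * g$domain_radius^2 - pi * rw^2
  A_wall <- 2 * pi * rw * g$membrane_thickness
  sig <- -50e-3
  cm_a <- make_charge_map(mesh, "a_uniform", sig)
  expect_equal(total_surface_charge(mesh, cm_a), sig * (2 * A_face + A_wall),
               tolerance = 1e-10)
  cm_b <- make_charge_map(mesh, "b_pore_only", sig)
  expect_equal(total_surface_charge(mesh, cm_b), sig * A_wall, tolerance = 1e-10)
  cm_0 <- make_charge_map(mesh, "uncharged")
  expect_equal(total_surface_charge(mesh, cm_0), 0)
  # conical wall: pi (r1 + r2) * slant height
  cone <- build_mesh(geometry_spec(opening_angle = 20), coarse_controls())
  r1 <- 5e-9
  r2 <- cone_large_diameter(10e-9, 20e-9, 20) / 2
  slant <- sqrt((r2 - r1)^2 + (20e-9)^2)
  cm_c <- make_charge_map(cone, "b_pore_only", sig)
  expect_equal(total_surface_charge(cone, cm_c), sig * pi * (r1 + r2) * slant,
               tolerance = 1e-10)
})

test_that("asymmetric map charges the left face plus the left half wall", {
  mesh <- coarse_mesh()
  cm <- make_charge_map(mesh, "c_asymmetric", -50e-3)
  itf <- mesh$interface
  expect_true(all(cm[itf$part == "face_left"] == -50e-3))
  expect_true(all(cm[itf$part == "face_right"] == 0))
  wall <- itf$part == "pore_wall"
  expect_true(all(cm[wall & itf$z_mid < 10e-9] == -50e-3))
  expect_true(all(cm[wall & itf$z_mid > 10e-9] == 0))
  expect_error(make_charge_map(mesh, "no_such_config", 0), "unknown charge")
})

test_that("refinement yields a Cauchy sequence of currents (order >= 1)", {
  # Frozen-field ohmic proxy of the 0.5 V uncharged scenario: the voltage of
  # the uniform initial state is held, each species is solved to its
  # frozen-field steady profile, and the plane current is read off. This
  # isolates the spatial discretization (no time stepping), so successive
  # refinements must approach a limit with shrinking increments.
  I_of <- function(h, ratio) {
    cfg <- simulation_config(controls = numerical_controls(
      min_element_size = h, mesh_growth_ratio = ratio))
    sim <- pnp_simulation(cfg)
    st <- initial_state(sim, 0.5, 0)
    st$conc <- vapply(cfg$electrolyte$species, function(sp)
      steady_transport_solve(sim$mesh, sp, st$V, 298.15),
      numeric(length(sim$mesh$liquid_nodes)))
    mean(current_profile(sim, st)$I_total)
  }
  I <- c(I_of(2e-9, 1.6), I_of(1e-9, 1.4), I_of(0.5e-9, 1.3), I_of(0.25e-9, 1.2))
  d <- abs(diff(I))
  expect_true(all(diff(d) < 0))          # increments shrink monotonically
  expect_lt(d[3] / d[1], 0.5)            # at least first-order decay overall
})
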