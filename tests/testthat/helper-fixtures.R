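# Shared fixtures, built in code. Meshes are cached per session because the
# graded grids are deterministic and several test files reuse them.

coarse_controls <- function() {
  p <- mesh_profile("coarse")
  numerical_controls(min_element_size = p$min_element_size,
                     mesh_growth_ratio = p$mesh_growth_ratio)
}

test_controls <- function() {
  p <- mesh_profile("test")
  numerical_controls(min_element_size = p$min_element_size,
                     mesh_growth_ratio = p$mesh_growth_ratio)
}

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

coarse_mesh <- function() {
  cached("coarse_mesh", function() build_mesh(geometry_spec(), coarse_controls()))
}

test_sim <- function(charges = charge_spec("uncharged"), geometry = geometry_spec(),
                     electrolyte = kcl_electrolyte(10)) {
  pnp_simulation(simulation_config(geometry = geometry, electrolyte = electrolyte,
                                   charges = charges, controls = test_controls()))
}

# Slab fixture with reservoirs fine enough to resolve the double layer.
dl_slab_mesh <- function() {
  cached("dl_slab", function() {
    build_slab_mesh(membrane_thickness = 10e-9, reservoir_depth = 60e-9,
                    domain_radius = 30e-9, h_z = 0.1e-9, ratio = 1.35, n_r = 2)
  })
}
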