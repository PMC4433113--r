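# Configuration records. Everything downstream of the constructors is SI;
# the YAML reader/writer is the single place where nm/mV/mM/mC-per-m2 are
# converted.

#' Define an ion species
#'
#' @param name Species label, e.g. `"K"` or `"Cl"`.
#' @param z Integer charge number (non-zero).
#' @param D Diffusion coefficient in m^2/s (> 0).
#' @param c_B Bulk concentration in mol/m^3 (>= 0). Note 1 mM = 1 mol/m^3.
#' @return A `pnp_species` list.
#' @export
species_spec <- function(name, z, D, c_B) {
  if (!is.character(name) || nchar(name) == 0) stop("species name required", call. = FALSE)
  if (z != round(z) || z == 0) stop("charge number z must be a non-zero integer", call. = FALSE)
  if (!(D > 0)) stop("diffusion coefficient must be > 0", call. = FALSE)
  if (c_B < 0) stop("bulk concentration must be >= 0", call. = FALSE)
  structure(list(name = name, z = as.integer(z), D = D, c_B = c_B),
            class = "pnp_species")
}

#' Define the electrolyte
#'
#' @param species List of [species_spec()] objects. The bulk must be
#'   electroneutral: `sum(z_i * c_Bi) == 0`.
#' @param temperature Absolute temperature in kelvin (default 298.15).
#' @return A `pnp_electrolyte` list.
#' @export
electrolyte_spec <- function(species, temperature = 298.15) {
  if (!length(species)) stop("at least one species required", call. = FALSE)
  if (!(temperature > 0)) stop("temperature must be > 0 K", call. = FALSE)
  zc <- vapply(species, function(s) s$z * s$c_B, numeric(1))
  if (abs(sum(zc)) > 1e-12 * max(abs(zc), 1e-300)) {
    stop("bulk electroneutrality violated: sum z_i * c_Bi = ", sum(zc),
         " mol/m^3", call. = FALSE)
  }
  names(species) <- vapply(species, `[[`, character(1), "name")
  structure(list(species = species, temperature = temperature),
            class = "pnp_electrolyte")
}

#' Standard KCl electrolyte
#'
#' Potassium chloride with D(K+) = 1.95e-9 m^2/s and D(Cl-) = 2.03e-9 m^2/s.
#'
#' @param c_B Bulk concentration in mol/m^3 (= mM); default 10.
#' @param temperature Kelvin; default 298.15.
#' @return A `pnp_electrolyte`.
#' @export
kcl_electrolyte <- function(c_B = 10, temperature = 298.15) {
  electrolyte_spec(list(
    species_spec("K", 1L, 1.95e-9, c_B),
    species_spec("Cl", -1L, 2.03e-9, c_B)
  ), temperature = temperature)
}

#' Pore and membrane geometry
#'
#' Axisymmetric domain: two cylindrical reservoirs separated by a membrane
#' pierced by a cylindrical or conical pore on the axis. The coordinate
#' convention is z increasing left to right with z = 0 at the left membrane
#' face; "left" is the `V_left` reservoir.
#'
#' @param membrane_thickness Membrane thickness L_m in m (default 20 nm).
#' @param pore_diameter Small-opening pore diameter d in m (default 10 nm).
#' @param opening_angle Full cone opening angle in degrees; 0 is a cylinder.
#' @param large_opening_side `"left"` or `"right"`: which membrane face holds
#'   the large opening of a conical pore.
#' @param reservoir_depth Axial extent of each reservoir in m (default 250 nm).
#' @param domain_radius Radius of the simulated cylinder in m (default 250 nm).
#' @return A `pnp_geometry` list.
#' @export
geometry_spec <- function(membrane_thickness = 20e-9,
                          pore_diameter = 10e-9,
                          opening_angle = 0,
                          large_opening_side = c("right", "left"),
                          reservoir_depth = 250e-9,
                          domain_radius = 250e-9) {
  large_opening_side <- match.arg(large_opening_side)
  if (!(pore_diameter > 0)) stop("pore diameter must be > 0", call. = FALSE)
  if (!(membrane_thickness > 0)) stop("membrane thickness must be > 0", call. = FALSE)
  if (opening_angle < 0 || opening_angle >= 90) {
    stop("opening angle must be in [0, 90) degrees", call. = FALSE)
  }
  if (!(reservoir_depth > 0) || !(domain_radius > 0)) {
    stop("reservoir depth and domain radius must be > 0", call. = FALSE)
  }
  d_large <- cone_large_diameter(pore_diameter, membrane_thickness, opening_angle)
  if (d_large / 2 >= domain_radius) {
    stop("large pore opening exceeds the domain radius", call. = FALSE)
  }
  structure(list(
    membrane_thickness = membrane_thickness,
    pore_diameter = pore_diameter,
    opening_angle = opening_angle,
    large_opening_side = large_opening_side,
    reservoir_depth = reservoir_depth,
    domain_radius = domain_radius
  ), class = "pnp_geometry")
}

#' Numerical controls
#'
#' @param poisson_step_fraction Fraction of the RC time constant used as the
#'   Poisson refresh step (default 1/40).
#' @param transport_step_fraction Fraction of the diffusive stability limit
#'   dx^2/D used as the transport step (default 1/5).
#' @param rc_multiples Duration of a recorded time simulation in RC time
#'   constants (default 20, i.e. 0.2 us for the canonical domain).
#' @param steady_rc_multiples RC multiples simulated per outer iteration of
#'   the steady-state acceleration loop (default 2).
#' @param uniformity_tolerance Plane-current uniformity stopping tolerance as
#'   a fraction of the total current (default 0.005, i.e. 0.5%).
#' @param reference_voltage Voltage (V) whose estimated current normalizes the
#'   uniformity metric for zero-bias runs (default 0.1).
#' @param min_element_size Target smallest element size at charged surfaces,
#'   in m (default 0.5 nm).
#' @param mesh_growth_ratio Geometric coarsening ratio away from the pore and
#'   the membrane faces (default 1.3, must be > 1).
#' @param linear_solver_tolerance Relative residual bound for linear solves.
#' @param max_outer_iterations Cap on steady-state outer iterations.
#' @return A `pnp_controls` list.
#' @export
numerical_controls <- function(poisson_step_fraction = 1 / 40,
                               transport_step_fraction = 1 / 5,
                               rc_multiples = 20,
                               steady_rc_multiples = 2,
                               uniformity_tolerance = 0.005,
                               reference_voltage = 0.1,
                               min_element_size = 0.5e-9,
                               mesh_growth_ratio = 1.3,
                               linear_solver_tolerance = 1e-9,
                               max_outer_iterations = 60) {
  if (!(poisson_step_fraction > 0 && poisson_step_fraction < 1)) {
    stop("poisson_step_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!(transport_step_fraction > 0 && transport_step_fraction <= 1)) {
    stop("transport_step_fraction must be in (0, 1]", call. = FALSE)
  }
  if (!(uniformity_tolerance > 0)) stop("uniformity_tolerance must be > 0", call. = FALSE)
  if (!(mesh_growth_ratio > 1)) stop("mesh_growth_ratio must be > 1", call. = FALSE)
  if (!(min_element_size > 0)) stop("min_element_size must be > 0", call. = FALSE)
  structure(list(
    poisson_step_fraction = poisson_step_fraction,
    transport_step_fraction = transport_step_fraction,
    rc_multiples = rc_multiples,
    steady_rc_multiples = steady_rc_multiples,
    uniformity_tolerance = uniformity_tolerance,
    reference_voltage = reference_voltage,
    min_element_size = min_element_size,
    mesh_growth_ratio = mesh_growth_ratio,
    linear_solver_tolerance = linear_solver_tolerance,
    max_outer_iterations = max_outer_iterations
  ), class = "pnp_controls")
}

#' Named mesh resolution profiles
#'
#' `"fine"` resolves the double layer with several sub-nanometre elements,
#' `"coarse"` is the documented profile for desk-scale runs and the packaged
#' reproduction scripts, `"test"` is an aggressively coarsened profile for
#' direction-only checks.
#'
#' @param profile One of `"fine"`, `"coarse"`, `"test"`.
#' @return A list with `min_element_size` (m) and `mesh_growth_ratio`.
#' @export
mesh_profile <- function(profile = c("coarse", "fine", "test")) {
  profile <- match.arg(profile)
  switch(profile,
    fine = list(min_element_size = 0.5e-9, mesh_growth_ratio = 1.3),
    coarse = list(min_element_size = 1.0e-9, mesh_growth_ratio = 1.4),
    test = list(min_element_size = 2.0e-9, mesh_growth_ratio = 1.6)
  )
}

#' Fixed surface-charge specification
#'
#' Describes which water/membrane interface segments carry fixed charge.
#' Resolved against a concrete mesh by [make_charge_map()].
#'
#' @param configuration One of `"uncharged"`, `"a_uniform"` (pore wall and
#'   both membrane faces), `"b_pore_only"` (pore wall only), `"c_asymmetric"`
#'   (left membrane face and the left half of the pore wall), or `"custom"`.
#' @param sigma Surface charge density in C/m^2 (e.g. -50e-3 for -50 mC/m^2).
#' @param segments For `"custom"`: list of lists with fields `part`
#'   (`"pore_wall"`, `"face_left"`, `"face_right"`), optional `z_min`/`z_max`
#'   (m) and `sigma` (C/m^2).
#' @return A `pnp_charge_spec` list.
#' @export
charge_spec <- function(configuration = c("uncharged", "a_uniform", "b_pore_only",
                                          "c_asymmetric", "custom"),
                        sigma = 0, segments = NULL) {
  configuration <- match.arg(configuration)
  if (configuration == "custom" && is.null(segments)) {
    stop("custom charge configuration needs a 'segments' list", call. = FALSE)
  }
  structure(list(configuration = configuration, sigma = sigma,
                 segments = segments),
            class = "pnp_charge_spec")
}

#' Assemble a full simulation configuration
#'
#' @param geometry A [geometry_spec()].
#' @param electrolyte A [electrolyte_spec()] or [kcl_electrolyte()].
#' @param charges A [charge_spec()].
#' @param V_left,V_right Reservoir-end voltages in volts.
#' @param controls A [numerical_controls()].
#' @param eps_r_water,eps_r_membrane Relative permittivities of the liquid and
#'   the membrane. The defaults (78.4 and 7.5) describe water and Si3N4; the
#'   membrane value reproduces a 0.65 fF membrane capacitance for the default
#'   20 nm membrane over the 250 nm-radius domain.
#' @return A `pnp_config` list.
#' @export
simulation_config <- function(geometry = geometry_spec(),
                              electrolyte = kcl_electrolyte(),
                              charges = charge_spec("uncharged"),
                              V_left = 0, V_right = 0,
                              controls = numerical_controls(),
                              eps_r_water = 78.4,
                              eps_r_membrane = 7.5) {
  stopifnot(inherits(geometry, "pnp_geometry"),
            inherits(electrolyte, "pnp_electrolyte"),
            inherits(charges, "pnp_charge_spec"),
            inherits(controls, "pnp_controls"))
  if (!(eps_r_water > eps_r_membrane && eps_r_membrane > 1)) {
    stop("expected eps_r_water > eps_r_membrane > 1 for a water/dielectric system",
         call. = FALSE)
  }
  if (!is.finite(V_left) || !is.finite(V_right)) {
    stop("bias voltages must be finite", call. = FALSE)
  }
  structure(list(
    geometry = geometry, electrolyte = electrolyte, charges = charges,
    V_left = V_left, V_right = V_right, controls = controls,
    eps_r_water = eps_r_water, eps_r_membrane = eps_r_membrane
  ), class = "pnp_config")
}

# ---- YAML front end ---------------------------------------------------------

pick <- function(lst, key, default) if (!is.null(lst[[key]])) lst[[key]] else default

#' Read a scenario configuration file
#'
#' The file is declarative YAML with sections `geometry`, `electrolyte`,
#' `charges`, `bias`, `numerics` and `permittivity`, in convenience units
#' (nm, mM, mC/m^2, volts, kelvin). A top-level `scenario:` key names a
#' [preset()] whose fields are used as defaults and overridden key by key.
#'
#' @param path Path to the YAML file.
#' @return A validated `pnp_config`.
#' @seealso [write_config()], [preset()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  config_from_list(raw)
}

#' @rdname load_config
#' @param raw A list with the same structure as the YAML document.
#' @export
config_from_list <- function(raw) {
  base <- if (!is.null(raw$scenario)) preset(raw$scenario)$config else simulation_config()

  g <- raw$geometry
  geometry <- geometry_spec(
    membrane_thickness = pick(g, "membrane_thickness_nm",
                              base$geometry$membrane_thickness * 1e9) * 1e-9,
    pore_diameter = pick(g, "pore_diameter_nm",
                         base$geometry$pore_diameter * 1e9) * 1e-9,
    opening_angle = pick(g, "opening_angle_deg", base$geometry$opening_angle),
    large_opening_side = pick(g, "large_opening_side",
                              base$geometry$large_opening_side),
    reservoir_depth = pick(g, "reservoir_depth_nm",
                           base$geometry$reservoir_depth * 1e9) * 1e-9,
    domain_radius = pick(g, "domain_radius_nm",
                         base$geometry$domain_radius * 1e9) * 1e-9
  )

  el <- raw$electrolyte
  if (!is.null(el$species)) {
    species <- lapply(el$species, function(s) {
      for (k in c("name", "z", "D")) {
        if (is.null(s[[k]])) stop("species entry missing key '", k, "'", call. = FALSE)
      }
      if (is.null(s$c_mM)) stop("species entry missing key 'c_mM'", call. = FALSE)
      species_spec(s$name, s$z, s$D, s$c_mM)  # 1 mM = 1 mol/m^3
    })
  } else {
    species <- base$electrolyte$species
    if (!is.null(el$c_mM)) {
      species <- lapply(species, function(s) species_spec(s$name, s$z, s$D, el$c_mM))
    }
  }
  electrolyte <- electrolyte_spec(species,
    temperature = pick(el, "temperature_K", base$electrolyte$temperature))

  ch <- raw$charges
  segments <- pick(ch, "segments", base$charges$segments)
  if (!is.null(segments)) {
    segments <- lapply(segments, function(sg) {
      sg$sigma <- if (!is.null(sg$sigma_mC_m2)) sg$sigma_mC_m2 * 1e-3 else sg$sigma
      sg$z_min <- if (!is.null(sg$z_min_nm)) sg$z_min_nm * 1e-9 else sg$z_min
      sg$z_max <- if (!is.null(sg$z_max_nm)) sg$z_max_nm * 1e-9 else sg$z_max
      sg[c("part", "z_min", "z_max", "sigma")]
    })
  }
  charges <- charge_spec(
    configuration = pick(ch, "configuration", base$charges$configuration),
    sigma = pick(ch, "sigma_mC_m2", base$charges$sigma * 1e3) * 1e-3,
    segments = segments
  )

  b <- raw$bias
  nu <- raw$numerics
  prof <- if (!is.null(nu$mesh_profile)) mesh_profile(nu$mesh_profile) else NULL
  controls <- numerical_controls(
    poisson_step_fraction = pick(nu, "poisson_step_fraction",
                                 base$controls$poisson_step_fraction),
    transport_step_fraction = pick(nu, "transport_step_fraction",
                                   base$controls$transport_step_fraction),
    rc_multiples = pick(nu, "rc_multiples", base$controls$rc_multiples),
    steady_rc_multiples = pick(nu, "steady_rc_multiples",
                               base$controls$steady_rc_multiples),
    uniformity_tolerance = pick(nu, "uniformity_tolerance",
                                base$controls$uniformity_tolerance),
    reference_voltage = pick(nu, "reference_voltage", base$controls$reference_voltage),
    min_element_size = pick(nu, "min_element_size_nm",
      (if (is.null(prof)) base$controls$min_element_size else prof$min_element_size) * 1e9) * 1e-9,
    mesh_growth_ratio = pick(nu, "mesh_growth_ratio",
      if (is.null(prof)) base$controls$mesh_growth_ratio else prof$mesh_growth_ratio),
    linear_solver_tolerance = pick(nu, "linear_solver_tolerance",
                                   base$controls$linear_solver_tolerance),
    max_outer_iterations = pick(nu, "max_outer_iterations",
                                base$controls$max_outer_iterations)
  )

  pe <- raw$permittivity
  simulation_config(
    geometry = geometry, electrolyte = electrolyte, charges = charges,
    V_left = pick(b, "V_left", base$V_left),
    V_right = pick(b, "V_right", base$V_right),
    controls = controls,
    eps_r_water = pick(pe, "water", base$eps_r_water),
    eps_r_membrane = pick(pe, "membrane", base$eps_r_membrane)
  )
}

#' Write a configuration back to YAML
#'
#' Inverse of [load_config()]: `load_config(write_config(cfg, f))` compares
#' equal to `cfg`.
#'
#' @param config A `pnp_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pnp_config"))
  g <- config$geometry
  ct <- config$controls
  doc <- list(
    geometry = list(
      membrane_thickness_nm = g$membrane_thickness * 1e9,
      pore_diameter_nm = g$pore_diameter * 1e9,
      opening_angle_deg = g$opening_angle,
      large_opening_side = g$large_opening_side,
      reservoir_depth_nm = g$reservoir_depth * 1e9,
      domain_radius_nm = g$domain_radius * 1e9
    ),
    electrolyte = list(
      temperature_K = config$electrolyte$temperature,
      species = lapply(unname(config$electrolyte$species), function(s) {
        list(name = s$name, z = s$z, D = s$D, c_mM = s$c_B)
      })
    ),
    charges = list(
      configuration = config$charges$configuration,
      sigma_mC_m2 = config$charges$sigma * 1e3
    ),
    bias = list(V_left = config$V_left, V_right = config$V_right),
    numerics = list(
      poisson_step_fraction = ct$poisson_step_fraction,
      transport_step_fraction = ct$transport_step_fraction,
      rc_multiples = ct$rc_multiples,
      steady_rc_multiples = ct$steady_rc_multiples,
      uniformity_tolerance = ct$uniformity_tolerance,
      reference_voltage = ct$reference_voltage,
      min_element_size_nm = ct$min_element_size * 1e9,
      mesh_growth_ratio = ct$mesh_growth_ratio,
      linear_solver_tolerance = ct$linear_solver_tolerance,
      max_outer_iterations = ct$max_outer_iterations
    ),
    permittivity = list(water = config$eps_r_water, membrane = config$eps_r_membrane)
  )
  if (!is.null(config$charges$segments)) {
    doc$charges$segments <- lapply(config$charges$segments, function(sg) {
      out <- list(part = sg$part, sigma_mC_m2 = sg$sigma * 1e3)
      if (!is.null(sg$z_min)) out$z_min_nm <- sg$z_min * 1e9
      if (!is.null(sg$z_max)) out$z_max_nm <- sg$z_max * 1e9
      out
    })
  }
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @export
print.pnp_config <- function(x, ...) {
  g <- x$geometry
  cat("<pnp_config>\n")
  cat(sprintf("  pore d = %.3g nm, L_m = %.3g nm, cone angle = %g deg (%s)\n",
              g$pore_diameter * 1e9, g$membrane_thickness * 1e9,
              g$opening_angle,
              if (g$opening_angle > 0) paste("large opening", g$large_opening_side)
              else "cylinder"))
  cat(sprintf("  domain: radius %.3g nm, reservoirs %.3g nm\n",
              g$domain_radius * 1e9, g$reservoir_depth * 1e9))
  sp <- x$electrolyte$species
  cat(sprintf("  electrolyte: %s at T = %.5g K\n",
              paste(vapply(sp, function(s)
                sprintf("%s(z=%+d, %.3g mM)", s$name, s$z, s$c_B), character(1)),
                collapse = " + "),
              x$electrolyte$temperature))
  cat(sprintf("  charges: %s (sigma = %.3g mC/m^2)\n",
              x$charges$configuration, x$charges$sigma * 1e3))
  cat(sprintf("  bias: V_L = %g V, V_R = %g V\n", x$V_left, x$V_right))
  invisible(x)
}
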