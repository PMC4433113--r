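# Closed-form electrochemical reference quantities. These are pure functions
# used both as solver oracles in the test suite and to set physical scales
# (RC time constant, reference current) inside the solver itself.

#' Debye screening length
#'
#' kappa^-1 = sqrt(eps0 eps_r k_B T / sum_i (z_i e)^2 c_Bi N_A). About 3 nm in
#' 10 mM KCl at room temperature.
#'
#' @param electrolyte A [electrolyte_spec()].
#' @param eps_r_water Relative permittivity of the liquid.
#' @return Length in metres.
#' @export
debye_length <- function(electrolyte, eps_r_water = 78.4) {
  k <- physical_constants()
  s <- electrolyte$species
  denom <- sum(vapply(s, function(sp) (sp$z * k$e)^2 * sp$c_B * k$N_A, numeric(1)))
  if (denom <= 0) stop("zero ionic strength", call. = FALSE)
  sqrt(k$eps0 * eps_r_water * k$k_B * electrolyte$temperature / denom)
}

#' Intermediate (ambipolar) diffusion coefficient
#'
#' The co-diffusion of a 1:1 salt relaxes with the harmonic-mean-type
#' coefficient D_int = 2 D_K D_Cl / (D_K + D_Cl), the rate that limits
#' convergence of the common-mode flux toward steady state.
#'
#' @param D_K,D_Cl Species diffusion coefficients in m^2/s.
#' @return Coefficient in m^2/s.
#' @export
intermediate_diffusion <- function(D_K, D_Cl) {
  if (!(D_K > 0 && D_Cl > 0)) stop("diffusion coefficients must be > 0", call. = FALSE)
  2 * D_K * D_Cl / (D_K + D_Cl)
}

#' Co-diffusion relaxation time over a length L
#'
#' L^2 / D_int: about 30 us for the 250 nm simulation reservoirs, about an
#' hour for millimetre-sized compartments -- the reason true steady state is
#' never reached in practice.
#'
#' @param L Length in metres.
#' @param D_int Ambipolar diffusion coefficient in m^2/s.
#' @return Time in seconds.
#' @export
codiffusion_time <- function(L, D_int) {
  if (!(L > 0 && D_int > 0)) stop("inputs must be > 0", call. = FALSE)
  L^2 / D_int
}

#' Nernst-Einstein bulk conductivity
#'
#' sigma = (F^2 / (R T)) * sum_i z_i^2 c_Bi D_i, with R = k_B N_A. Uses the
#' model's own diffusion coefficients, so solver currents and analytic
#' resistances are mutually consistent.
#'
#' @inheritParams debye_length
#' @return Conductivity in S/m (about 0.149 S/m for 10 mM KCl at 298.15 K).
#' @export
conductivity <- function(electrolyte) {
  k <- physical_constants()
  RT <- k$k_B * k$N_A * electrolyte$temperature
  sum(vapply(electrolyte$species,
             function(s) k$F^2 * s$z^2 * s$c_B * s$D / RT, numeric(1)))
}

#' Solution resistance, membrane capacitance and RC time constant
#'
#' The simulated column of electrolyte (both reservoirs in series) has
#' R = 2 L_res / (sigma pi R_dom^2); the membrane is a parallel-plate
#' capacitor C = eps0 eps_m pi R_dom^2 / L_m (the pore area is negligible).
#' Their product sets the Poisson refresh cadence of the time integrator.
#'
#' @param geometry A [geometry_spec()].
#' @param electrolyte A [electrolyte_spec()].
#' @param eps_r_membrane Relative permittivity of the membrane.
#' @return List with `R` (ohm), `C` (farad), `tau` (s).
#' @export
membrane_RC <- function(geometry, electrolyte, eps_r_membrane = 7.5) {
  k <- physical_constants()
  sig <- conductivity(electrolyte)
  if (sig <= 0) stop("zero electrolyte conductivity", call. = FALSE)
  A <- pi * geometry$domain_radius^2
  R <- 2 * geometry$reservoir_depth / (sig * A)
  C <- k$eps0 * eps_r_membrane * A / geometry$membrane_thickness
  list(R = R, C = C, tau = R * C)
}

#' RC time constant
#'
#' @param R Resistance in ohm.
#' @param C Capacitance in farad.
#' @return R * C in seconds.
#' @export
rc_time_constant <- function(R, C) {
  if (R < 0 || C < 0) stop("R and C must be >= 0", call. = FALSE)
  R * C
}

#' Mean distance between ions
#'
#' (sum_i c_Bi N_A)^(-1/3) counting all species: about 4 nm in 10 mM KCl,
#' which is why this concentration sits at the edge of validity of the
#' continuum description.
#'
#' @inheritParams debye_length
#' @return Length in metres.
#' @export
ion_spacing <- function(electrolyte) {
  n <- sum(vapply(electrolyte$species, function(s) s$c_B * physical_constants()$N_A,
                  numeric(1)))
  if (n <= 0) stop("total ion density must be > 0", call. = FALSE)
  n^(-1 / 3)
}

#' Gouy-Chapman double layer at a flat charged plane
#'
#' Closed-form equilibrium diffuse layer for a symmetric 1:1 electrolyte:
#' the surface potential follows from the Grahame equation
#' sigma = sqrt(8 eps k_B T n_inf) sinh(e psi0 / 2 k_B T), the potential
#' decays as psi(x) = (2kT/e) ln[(1 + g exp(-kx))/(1 - g exp(-kx))] with
#' g = tanh(e psi0 / 4 k_B T), and concentrations are Boltzmann factors of
#' psi. Used as the oracle for the solver's equilibrium double layer.
#'
#' @param sigma Fixed surface charge density in C/m^2.
#' @param electrolyte A symmetric 1:1 [electrolyte_spec()].
#' @param eps_r_water Relative permittivity of the liquid.
#' @param x Distances from the wall (m) at which to evaluate the profiles.
#' @return List with `psi0` (surface potential, V), `x`, `psi` (V), and
#'   `concentration`: matrix (length(x) x species) in mol/m^3.
#' @export
gouy_chapman_profile <- function(sigma, electrolyte, eps_r_water = 78.4,
                                 x = seq(0, 20e-9, length.out = 201)) {
  s <- electrolyte$species
  zs <- vapply(s, `[[`, integer(1), "z")
  cs <- vapply(s, `[[`, numeric(1), "c_B")
  if (length(s) != 2 || !all(sort(zs) == c(-1L, 1L)) || cs[1] != cs[2]) {
    stop("Gouy-Chapman profile supports only a symmetric 1:1 electrolyte",
         call. = FALSE)
  }
  k <- physical_constants()
  T <- electrolyte$temperature
  VT <- thermal_voltage(T)
  n_inf <- unname(cs[1]) * k$N_A
  eps <- k$eps0 * eps_r_water
  kap <- 1 / debye_length(electrolyte, eps_r_water)
  psi0 <- 2 * VT * asinh(sigma / sqrt(8 * eps * k$k_B * T * n_inf))
  g <- tanh(psi0 / (4 * VT))
  gx <- g * exp(-kap * x)
  psi <- 2 * VT * log((1 + gx) / (1 - gx))
  conc <- vapply(s, function(sp) sp$c_B * exp(-sp$z * psi / VT),
                 numeric(length(x)))
  conc <- matrix(conc, nrow = length(x),
                 dimnames = list(NULL, vapply(s, `[[`, character(1), "name")))
  list(psi0 = psi0, x = x, psi = psi, concentration = conc)
}

#' Grahame equation: surface charge from surface potential
#'
#' Inverse of the surface-potential step of [gouy_chapman_profile()].
#'
#' @param psi0 Surface potential in volts.
#' @inheritParams gouy_chapman_profile
#' @return Surface charge density in C/m^2.
#' @export
grahame_charge <- function(psi0, electrolyte, eps_r_water = 78.4) {
  k <- physical_constants()
  T <- electrolyte$temperature
  n_inf <- electrolyte$species[[1]]$c_B * k$N_A
  unname(sqrt(8 * k$eps0 * eps_r_water * k$k_B * T * n_inf) *
         sinh(psi0 / (2 * thermal_voltage(T))))
}

#' Estimated pore-plus-access reference current
#'
#' The uniformity criterion of a zero-bias steady-state run is normalized by
#' the current expected at a reference voltage (default 0.1 V) through the
#' series combination of the internal pore resistance
#' R_pore = 4 L_m / (sigma pi d^2) (mean diameter for conical pores) and the
#' Hall access resistance of both openings, R_access = 1/(2 sigma d_left) +
#' 1/(2 sigma d_right).
#'
#' @param config A `pnp_config`.
#' @return Current in amperes.
#' @export
estimate_reference_current <- function(config) {
  g <- config$geometry
  sig <- conductivity(config$electrolyte)
  if (sig <= 0) stop("zero electrolyte conductivity", call. = FALSE)
  d_small <- g$pore_diameter
  d_large <- cone_large_diameter(d_small, g$membrane_thickness, g$opening_angle)
  d_mean <- (d_small + d_large) / 2
  R_pore <- 4 * g$membrane_thickness / (sig * pi * d_mean^2)
  R_access <- 1 / (2 * sig * d_small) + 1 / (2 * sig * d_large)
  config$controls$reference_voltage / (R_pore + R_access)
}

#' Print the oracle table
#'
#' Evaluates every closed-form reference quantity for a configuration and
#' returns them as a data frame (used by the `validate` CLI subcommand).
#'
#' @param config A `pnp_config`; default is the canonical uncharged pore.
#' @return A data frame with columns `quantity`, `value`, `units`.
#' @export
oracle_table <- function(config = simulation_config()) {
  el <- config$electrolyte
  Ds <- vapply(el$species, `[[`, numeric(1), "D")
  D_int <- intermediate_diffusion(Ds[1], Ds[2])
  rc <- membrane_RC(config$geometry, el, config$eps_r_membrane)
  data.frame(
    quantity = c("thermal voltage", "Debye length", "ion spacing",
                 "conductivity", "D_int", "co-diffusion time (reservoir)",
                 "solution resistance", "membrane capacitance",
                 "RC time constant", "reference current",
                 "cone large diameter"),
    value = c(thermal_voltage(el$temperature) * 1e3,
              debye_length(el, config$eps_r_water) * 1e9,
              ion_spacing(el) * 1e9,
              conductivity(el),
              D_int,
              codiffusion_time(config$geometry$reservoir_depth, D_int) * 1e6,
              rc$R / 1e6, rc$C * 1e15, rc$tau,
              estimate_reference_current(config) * 1e12,
              cone_large_diameter(config$geometry$pore_diameter,
                                  config$geometry$membrane_thickness,
                                  config$geometry$opening_angle) * 1e9),
    units = c("mV", "nm", "nm", "S/m", "m^2/s", "us", "Mohm", "fF", "s",
              "pA", "nm"),
    stringsAsFactors = FALSE
  )
}
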