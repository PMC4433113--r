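#' Physical constants (SI, CODATA 2018 exact values)
#'
#' Returns the fundamental constants used throughout the solver. All internal
#' computation is in SI units (m, s, V, mol, C, K); conversion from the
#' convenience units accepted by configuration files (nm, mV, mM, mC/m^2)
#' happens exactly once, at configuration load.
#'
#' @return A list with components `F` (Faraday constant, C/mol), `e`
#'   (elementary charge, C), `k_B` (Boltzmann constant, J/K), `N_A`
#'   (Avogadro constant, 1/mol) and `eps0` (vacuum permittivity, F/m).
#' @examples
#' k <- physical_constants()
#' k$F / (k$e * k$N_A)  # 1 by definition
#' @export
physical_constants <- function() {
  e <- 1.602176634e-19
  N_A <- 6.02214076e23
  list(
    F = e * N_A,
    e = e,
    k_B = 1.380649e-23,
    N_A = N_A,
    eps0 = 8.8541878128e-12
  )
}

#' Thermal voltage k_B T / e
#'
#' The voltage scale of electrodiffusion: the drift term of the Nernst-Planck
#' flux is c z e/(k_B T) times the voltage gradient, so concentration ratios at
#' equilibrium are `exp(-z dV / thermal_voltage(T))`.
#'
#' @param T Absolute temperature in kelvin (> 0).
#' @return Thermal voltage in volts (about 25.7 mV at 298.15 K).
#' @export
thermal_voltage <- function(T) {
  if (!is.numeric(T) || any(T < 0)) {
    stop("thermal_voltage: temperature must be >= 0 K", call. = FALSE)
  }
  k <- physical_constants()
  k$k_B * T / k$e
}
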