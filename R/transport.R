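# Ion transport with the Scharfetter-Gummel box scheme: concentrations live
# on the liquid mesh nodes (piecewise constant on the median-dual boxes) and
# fluxes flow along triangle edges with the P1 cotangent conductances of the
# axisymmetric Laplacian. Voltage and charge density therefore share one
# graph with the Poisson solve, which keeps the discrete dielectric
# relaxation of the dual-time-step iteration faithful to the continuum. The
# exponential fitting is exact for the two-point 1D drift-diffusion problem:
# fluxes vanish identically at thermal-equilibrium (Boltzmann) concentration
# ratios and the explicit update is positivity-preserving under the step
# bound. Membrane and outer boundaries carry no flux (membrane triangles
# contribute no edge weight); the nodes on the reservoir ends are pinned to
# the bulk concentrations.

# Bernoulli function B(x) = x / (exp(x) - 1), the SG weight.
bernoulli <- function(x) {
  out <- x / expm1(x)
  out[x == 0] <- 1
  big <- x < -700
  out[big] <- -x[big]
  out
}

#' Scharfetter-Gummel flux through one facet
#'
#' Numerical flux (mol/s) between two adjacent control volumes for one
#' species, given the voltage drop between them. Reduces to Fickian
#' diffusion for `dV = 0` and vanishes exactly when the concentration ratio
#' is the Boltzmann factor of the voltage drop.
#'
#' @param c_up,c_down Concentrations (mol/m^3) in the two control volumes.
#' @param dV Voltage of the `c_up` side minus voltage of the `c_down` side
#'   (V).
#' @param D Diffusion coefficient (m^2/s).
#' @param z Charge number.
#' @param T Temperature (K).
#' @param facet List with `distance` (m) and `area` (m^2); their ratio is
#'   the geometric conductance of the connection.
#' @return Flux in mol/s, positive from up to down.
#' @export
edge_flux <- function(c_up, c_down, dV, D, z, T, facet) {
  if (!all(is.finite(c(c_up, c_down, dV)))) {
    stop("edge_flux: non-finite input", call. = FALSE)
  }
  stopifnot(facet$distance > 0, facet$area > 0)
  u <- z * dV / thermal_voltage(T)
  g <- D * facet$area / facet$distance
  g * (bernoulli(-u) * c_up - bernoulli(u) * c_down)
}

# Voltages at the liquid nodes.
liquid_voltages <- function(mesh, V) V[mesh$liquid_nodes]

# Per-species SG edge coefficients for a frozen field: flux p->q on edge e
# is a[e] c_p - b[e] c_q (mol/s).
sg_coefficients <- function(mesh, species, Vl, T) {
  ne <- mesh$nedge
  u <- species$z * (Vl[ne$p] - Vl[ne$q]) / thermal_voltage(T)
  g <- species$D * ne$w
  list(a = g * bernoulli(-u), b = g * bernoulli(u))
}

# Divergence operator for explicit stepping: dc/dt = (L c) / box_vol.
# dt_pos is the positivity bound of the explicit update.
transport_operator <- function(mesh, species, Vl, T) {
  ne <- mesh$nedge
  co <- sg_coefficients(mesh, species, Vl, T)
  nl <- length(mesh$liquid_nodes)
  L <- Matrix::sparseMatrix(
    i = c(ne$p, ne$p, ne$q, ne$q),
    j = c(ne$p, ne$q, ne$q, ne$p),
    x = c(-co$a, co$b, -co$b, co$a),
    dims = c(nl, nl)
  )
  outflow <- -Matrix::diag(L)
  pos <- outflow > 0
  dt_pos <- if (any(pos)) min(mesh$box_vol[pos] / outflow[pos]) else Inf
  list(L = L, dt_pos = dt_pos, coef = co)
}

#' One explicit transport step
#'
#' Advances all species by `dt` with the voltage field frozen:
#' c <- c + dt * (net edge fluxes) / box volume, then re-pins the reservoir
#' end nodes to the bulk concentrations.
#'
#' @param conc Matrix (liquid nodes x species), mol/m^3.
#' @param mesh A `pnp_mesh`.
#' @param electrolyte A [electrolyte_spec()].
#' @param V Nodal voltage vector (all mesh nodes).
#' @param dt Time step (s); must respect the diffusive stability bound.
#' @param negative_tolerance Concentrations below `-negative_tolerance`
#'   abort with a stability error; smaller negatives are clipped to zero.
#' @return Updated concentration matrix.
#' @export
transport_step <- function(conc, mesh, electrolyte, V, dt,
                           negative_tolerance = NULL) {
  Vl <- liquid_voltages(mesh, V)
  T <- electrolyte$temperature
  out <- conc
  for (s in seq_along(electrolyte$species)) {
    sp <- electrolyte$species[[s]]
    op <- transport_operator(mesh, sp, Vl, T)
    cs <- conc[, s] + dt * as.numeric(op$L %*% conc[, s]) / mesh$box_vol
    cs <- clip_negatives(cs, sp, negative_tolerance)
    cs[mesh$dirichlet_nodes] <- sp$c_B
    out[, s] <- cs
  }
  out
}

clip_negatives <- function(cs, sp, negative_tolerance = NULL) {
  if (is.null(negative_tolerance)) negative_tolerance <- 1e-6 * max(sp$c_B, 1)
  if (any(cs < -negative_tolerance)) {
    stop(sprintf(
      "transport instability: %s concentration reached %.3g mol/m^3; use a smaller time step",
      sp$name, min(cs)), call. = FALSE)
  }
  pmax(cs, 0)
}

#' Frozen-field steady-state Nernst-Planck solve for one species
#'
#' Solves div j = 0 with the SG edge coefficients of a fixed voltage field,
#' bulk Dirichlet concentrations at the reservoir ends, and zero flux
#' elsewhere. The result is a fixed point of [transport_step()] for the
#' same field.
#'
#' @param mesh A `pnp_mesh`.
#' @param species A [species_spec()].
#' @param V Nodal voltage vector.
#' @param T Temperature (K).
#' @return Concentration vector over liquid nodes (mol/m^3).
#' @export
steady_transport_solve <- function(mesh, species, V, T = 298.15) {
  ne <- mesh$nedge
  Vl <- liquid_voltages(mesh, V)
  co <- sg_coefficients(mesh, species, Vl, T)
  nl <- length(mesh$liquid_nodes)
  dir <- mesh$dirichlet_nodes
  keep_p <- !(ne$p %in% dir)
  keep_q <- !(ne$q %in% dir)
  gbar <- max(co$a, co$b)  # scale of the flux coefficients, for row balance
  ii <- c(ne$p[keep_p], ne$p[keep_p], ne$q[keep_q], ne$q[keep_q], dir)
  jj <- c(ne$p[keep_p], ne$q[keep_p], ne$q[keep_q], ne$p[keep_q], dir)
  xx <- c(co$a[keep_p], -co$b[keep_p], co$b[keep_q], -co$a[keep_q],
          rep(gbar, length(dir)))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nl, nl))
  rhs <- numeric(nl)
  rhs[dir] <- gbar * species$c_B
  cs <- as.numeric(Matrix::solve(M, rhs))
  if (anyNA(cs) || any(!is.finite(cs))) {
    stop("steady transport solve failed (singular system)", call. = FALSE)
  }
  cs
}

#' Per-edge species fluxes for a state
#'
#' @param mesh A `pnp_mesh`.
#' @param electrolyte A [electrolyte_spec()].
#' @param V Nodal voltage vector.
#' @param conc Concentration matrix (liquid nodes x species).
#' @return Matrix (transport edges x species) of SG fluxes in mol/s,
#'   oriented p to q as in `mesh$nedge` (antisymmetric under orientation
#'   flip by construction).
#' @export
species_fluxes <- function(mesh, electrolyte, V, conc) {
  Vl <- liquid_voltages(mesh, V)
  ne <- mesh$nedge
  T <- electrolyte$temperature
  out <- matrix(0, nrow(ne), length(electrolyte$species),
                dimnames = list(NULL, names(electrolyte$species)))
  for (s in seq_along(electrolyte$species)) {
    co <- sg_coefficients(mesh, electrolyte$species[[s]], Vl, T)
    out[, s] <- co$a * conc[ne$p, s] - co$b * conc[ne$q, s]
  }
  out
}
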