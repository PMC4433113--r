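# Derived quantities: plane currents (the convergence and reporting
# surface), common/differential-mode fluxes, electrochemical potentials,
# polarization charges, I-V curves and ion counts.

#' Per-species currents through planes parallel to the membrane
#'
#' For every axial plane between consecutive mesh rows, the current of each
#' species is the sum of F z_i times the SG facet fluxes crossing the plane
#' (finite-volume conservation makes this exact for any cut). At steady
#' state the per-species profiles are z-uniform to within the stopping
#' tolerance; during a transient they are not, while the total remains
#' nearly uniform once the membrane capacitor has charged.
#'
#' @param sim A [pnp_simulation()] (or any list with `mesh` and `config`).
#' @param state A `pnp_state`.
#' @return List: `z` (plane positions, m), `I` (planes x species, A),
#'   `I_total` (A).
#' @export
current_profile <- function(sim, state) {
  mesh <- sim$mesh
  el <- sim$config$electrolyte
  fx <- species_fluxes(mesh, el, state$V, state$conc)
  profile_from_fluxes(mesh, el, fx)
}

profile_from_fluxes <- function(mesh, el, fx) {
  ne <- mesh$nedge
  crossing <- ne$cross > 0L
  k <- physical_constants()
  zs <- vapply(el$species, `[[`, integer(1), "z")
  signed <- fx[crossing, , drop = FALSE] * ne$sgn[crossing]
  rs <- rowsum(signed, group = ne$cross[crossing], reorder = TRUE)
  idx <- as.integer(rownames(rs))
  n_planes <- length(mesh$plane_z)
  I <- matrix(0, n_planes, ncol(fx), dimnames = list(NULL, colnames(fx)))
  I[idx, ] <- rs
  has <- logical(n_planes)
  has[idx] <- TRUE
  I <- sweep(I[has, , drop = FALSE], 2, k$F * zs, `*`)
  list(z = mesh$plane_z[has], I = I, I_total = rowSums(I))
}

#' Current through one axial plane
#'
#' @param sim A [pnp_simulation()].
#' @param state A `pnp_state`.
#' @param z Axial position (m); the nearest liquid-crossing plane is used.
#' @return Named vector: per-species currents and `I_total` (A).
#' @export
plane_current <- function(sim, state, z) {
  prof <- current_profile(sim, state)
  if (!length(prof$z)) stop("no plane intersects the liquid region", call. = FALSE)
  span <- diff(range(prof$z))
  i <- which.min(abs(prof$z - z))
  if (abs(prof$z[i] - z) > 0.05 * span + 1e-12) {
    # requested plane lies inside the membrane at all radii (no liquid cut)
    if (!any(abs(prof$z - z) < 0.5 * span)) {
      stop("plane does not intersect the liquid region", call. = FALSE)
    }
  }
  c(prof$I[i, ], I_total = sum(prof$I[i, ]))
}

#' Common- and differential-mode flux decomposition
#'
#' j_c = (j_K + j_Cl)/2 carries no charge (co-diffusion of the salt);
#' j_d = (j_K - j_Cl)/2 carries half the charge flux. The species fluxes are
#' reconstructed exactly as j_K = j_c + j_d, j_Cl = j_c - j_d.
#'
#' @param fluxes Matrix (facets x 2) of per-species facet fluxes with the
#'   cation in column 1 (as returned by [species_fluxes()]).
#' @return List with `j_c` and `j_d` (mol/s per facet).
#' @export
mode_decomposition <- function(fluxes) {
  if (ncol(fluxes) != 2) stop("mode decomposition needs exactly two species",
                              call. = FALSE)
  list(j_c = (fluxes[, 1] + fluxes[, 2]) / 2,
       j_d = (fluxes[, 1] - fluxes[, 2]) / 2)
}

#' Electrochemical potential field
#'
#' E_ec,i = z_i e V + k_B T ln(c_i / c_Bi) per liquid cell (joule per ion).
#' Zero in the bulk and, at equilibrium, zero throughout the double layer
#' (the Boltzmann factor cancels the electrostatic term). Cells with zero
#' concentration are masked as NA.
#'
#' @param sim A [pnp_simulation()].
#' @param state A `pnp_state`.
#' @param species Species name (e.g. `"K"`).
#' @return Numeric vector over liquid cells (J).
#' @export
electrochemical_potential <- function(sim, state, species) {
  sp <- sim$config$electrolyte$species[[species]]
  if (is.null(sp)) stop("unknown species '", species, "'", call. = FALSE)
  k <- physical_constants()
  T <- sim$config$electrolyte$temperature
  Vl <- liquid_voltages(sim$mesh, state$V)
  cs <- state$conc[, sp$name]
  out <- rep(NA_real_, length(cs))
  ok <- cs > 0
  out[ok] <- sp$z * k$e * Vl[ok] + k$k_B * T * log(cs[ok] / sp$c_B)
  out
}

#' Bias-induced polarization charge on the membrane surface
#'
#' The applied voltage polarizes the dielectric membrane; the induced
#' surface charge seen by the electrolyte is the membrane-side displacement,
#' sigma_pol = -eps0 eps_m E_perp,membrane (normal oriented liquid to
#' membrane). It vanishes at equilibrium and equals the series-capacitor
#' value eps0 eps_m dV_m / L_m under bias; far from the pore at 1 V across a
#' 20 nm Si3N4 membrane it is about 3 mC/m^2.
#'
#' @param sim A [pnp_simulation()].
#' @param state A `pnp_state`.
#' @return Data frame: the interface table plus `sigma_pol` (C/m^2).
#' @export
polarization_charge_density <- function(sim, state) {
  k <- physical_constants()
  nf <- interface_normal_fields(sim$system, state$V)
  nf$sigma_pol <- -k$eps0 * sim$config$eps_r_membrane * nf$E_membrane
  nf
}

#' Far-from-pore face polarization charge
#'
#' Area-weighted average of `sigma_pol` over the outer half of the radial
#' extent of one membrane face, where the single-number far-field statements
#' apply.
#'
#' @param sim A [pnp_simulation()].
#' @param state A `pnp_state`.
#' @param side `"left"` or `"right"` membrane face.
#' @param outer_fraction Use edges with r_mid above this fraction of the
#'   domain radius (default 0.5).
#' @return Average sigma_pol in C/m^2.
#' @export
face_polarization <- function(sim, state, side = c("left", "right"),
                              outer_fraction = 0.5) {
  side <- match.arg(side)
  pol <- polarization_charge_density(sim, state)
  part <- if (side == "left") "face_left" else "face_right"
  sel <- pol$part == part &
    pol$r_mid >= outer_fraction * sim$config$geometry$domain_radius
  if (!any(sel)) stop("no face edges in the selected radial band", call. = FALSE)
  w <- 2 * pi * pol$r_mid[sel] * pol$length[sel]
  sum(w * pol$sigma_pol[sel]) / sum(w)
}

#' Assemble an I-V curve
#'
#' @param V Bias voltages (V), unique.
#' @param I Currents (A) at those biases.
#' @return Data frame sorted by V with chord conductance `G = I/V` (NA at
#'   V = 0), differential conductance `g` by central differences (one-sided
#'   at the ends), and `rectification` = G(+V)/G(-V) on positive-V rows that
#'   have a matching -V row.
#' @export
iv_curve <- function(V, I) {
  if (anyDuplicated(V)) stop("duplicate bias points", call. = FALSE)
  if (length(V) < 2) stop("an I-V curve needs at least 2 bias points", call. = FALSE)
  o <- order(V)
  V <- V[o]; I <- I[o]
  G <- ifelse(V != 0, I / V, NA_real_)
  n <- length(V)
  g <- numeric(n)
  if (n >= 3) {
    g[2:(n - 1)] <- (I[3:n] - I[1:(n - 2)]) / (V[3:n] - V[1:(n - 2)])
  }
  g[1] <- (I[2] - I[1]) / (V[2] - V[1])
  g[n] <- (I[n] - I[n - 1]) / (V[n] - V[n - 1])
  rect <- rep(NA_real_, n)
  for (i in which(V > 0)) {
    j <- which(abs(V + V[i]) < 1e-12 * max(abs(V)))
    if (length(j) == 1 && !is.na(G[j]) && G[j] != 0) rect[i] <- G[i] / G[j]
  }
  data.frame(V = V, I = I, G = G, g = g, rectification = rect)
}

#' Number of ions in a region
#'
#' N = N_A sum_i integral c_i dV with axisymmetric volume weights.
#'
#' The concentration field is piecewise linear over the liquid triangles
#' (nodal values), so the integral over a set of triangles is exact:
#' int c 2 pi r dA = 2 pi A sum_i c_i (2 r_i + r_j + r_k) / 12 per triangle.
#'
#' @param mesh A `pnp_mesh`.
#' @param conc Concentration matrix (liquid nodes x species), mol/m^3.
#' @param triangles Triangle indices of the region; default the pore
#'   interior (liquid triangles with centroid inside the membrane z-range).
#' @return Expected ion count (dimensionless).
#' @export
ions_in_volume <- function(mesh, conc, triangles = pore_triangles(mesh)) {
  k <- physical_constants()
  tri <- mesh$tri[triangles, , drop = FALSE]
  if (any(mesh$region[triangles] != "liquid")) {
    stop("region must consist of liquid triangles", call. = FALSE)
  }
  r <- mesh$nodes[, 1]
  A <- mesh$area[triangles]
  rsum <- r[tri[, 1]] + r[tri[, 2]] + r[tri[, 3]]
  total <- 0
  for (s in seq_len(ncol(conc))) {
    cn <- numeric(nrow(mesh$nodes))
    cn[mesh$liquid_nodes] <- conc[, s]
    w <- cn[tri[, 1]] * (rsum + r[tri[, 1]]) +
         cn[tri[, 2]] * (rsum + r[tri[, 2]]) +
         cn[tri[, 3]] * (rsum + r[tri[, 3]])
    total <- total + sum(2 * pi * A * w / 12)
  }
  k$N_A * total
}

#' Liquid triangles inside the pore
#'
#' @param mesh A `pnp_mesh`.
#' @return Triangle indices whose centroid lies within the membrane z-range
#'   and the liquid region.
#' @export
pore_triangles <- function(mesh) {
  which(mesh$region == "liquid" & mesh$zbar > 0 &
        mesh$zbar < mesh$geometry$membrane_thickness)
}
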