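# Piecewise-linear finite-element Poisson solve in cylindrical coordinates.
# The weak form carries the axisymmetric weight 2*pi*r; the membrane interior
# is part of the solve (permittivity eps0*eps_m there, zero mobile charge),
# and fixed surface charges enter as natural interface line terms
# int sigma w 2 pi r ds. No wall Neumann condition is imposed: screening by
# ions on the membrane outside the pore emerges from the solution. Dirichlet
# voltages act on the far reservoir ends; the outer cylinder and the axis are
# natural (zero normal displacement; the 2*pi*r weight vanishes on the axis).

#' Assemble the Poisson system for a mesh
#'
#' Builds and factorizes the stiffness matrix once; the factorization is
#' reused for every right-hand side during time stepping (the matrix depends
#' only on mesh and permittivities).
#'
#' @param mesh A `pnp_mesh`.
#' @param eps_r_water,eps_r_membrane Relative permittivities.
#' @return A `pnp_poisson` object (stiffness, Cholesky factor, load maps).
#' @export
poisson_system <- function(mesh, eps_r_water = 78.4, eps_r_membrane = 7.5) {
  k <- physical_constants()
  n <- nrow(mesh$nodes)
  tri <- mesh$tri
  r <- mesh$nodes[, 1]; z <- mesh$nodes[, 2]
  i1 <- tri[, 1]; i2 <- tri[, 2]; i3 <- tri[, 3]
  # P1 gradient coefficients (kept for element fields): grad w_m = (b,c)/(2A)
  b1 <- z[i2] - z[i3]; b2 <- z[i3] - z[i1]; b3 <- z[i1] - z[i2]
  c1 <- r[i3] - r[i2]; c2 <- r[i1] - r[i3]; c3 <- r[i2] - r[i1]
  bb <- cbind(b1, b2, b3); cc <- cbind(c1, c2, c3)

  # Stiffness as the axisymmetric Voronoi-box Laplacian: per triangle edge,
  # conductance = eps_T * (revolved Voronoi facet area) / (edge length)
  # (identical to P1 FEM in the plane; the facet-radius weighting keeps the
  # operator exactly compatible with the nodal box masses of the transport
  # scheme, so z-only fields obey the 1D equations at every radial column).
  eps <- ifelse(mesh$region == "membrane", eps_r_membrane, eps_r_water) * k$eps0
  vor <- mesh$vor
  we <- eps[vor$tri] * vor$w
  K <- Matrix::sparseMatrix(
    i = c(vor$i, vor$j, vor$i, vor$j),
    j = c(vor$i, vor$j, vor$j, vor$i),
    x = c(we, we, -we, -we),
    dims = c(n, n)
  )

  dirichlet <- sort(unique(c(mesh$left_nodes, mesh$right_nodes)))
  free <- setdiff(seq_len(n), dirichlet)
  K_ff <- K[free, free, drop = FALSE]
  K_fd <- K[free, dirichlet, drop = FALSE]
  # mildly obtuse triangles on mapped conical grids can leave a few small
  # positive off-diagonals; fall back to LU if the Cholesky balks
  factor <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(K_ff), LDL = FALSE),
                     error = function(e) Matrix::lu(K_ff))

  # Volume charge load: lumped nodal load box_vol_i * rho_i over the liquid
  # nodes (the box volumes of the transport scheme), so that charge density
  # and voltage share one discrete graph. Interface nodes carry only the
  # liquid part of their box, confining mobile charge to the electrolyte.
  T_load <- Matrix::sparseMatrix(i = mesh$liquid_nodes,
                                 j = seq_along(mesh$liquid_nodes),
                                 x = mesh$box_vol,
                                 dims = c(n, length(mesh$liquid_nodes)))

  # Surface charge load: each interface edge is split at its midpoint and
  # each half 's revolved area int sigma 2 pi r ds goes to its end node --
  # the box-consistent apportioning (the halves are exactly the nodes' dual
  # facets on the interface), so surface charge per unit area is uniform
  # across the boxes and z-only fields stay exactly one-dimensional.
  itf <- mesh$interface
  if (nrow(itf)) {
    r1 <- r[itf$n1]; r2 <- r[itf$n2]
    Si <- c(itf$n1, itf$n2)
    Sj <- rep(seq_len(nrow(itf)), 2L)
    Sx <- c(pi * itf$length * (3 * r1 + r2) / 4,
            pi * itf$length * (r1 + 3 * r2) / 4)
    S_load <- Matrix::sparseMatrix(i = Si, j = Sj, x = Sx, dims = c(n, nrow(itf)))
  } else {
    S_load <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                   dims = c(n, 0L))
  }

  structure(list(
    mesh = mesh, K = K, K_fd = K_fd, factor = factor, free = free,
    dirichlet = dirichlet,
    T_load = T_load, S_load = S_load,
    eps_r_water = eps_r_water, eps_r_membrane = eps_r_membrane,
    grad_b = bb, grad_c = cc
  ), class = "pnp_poisson")
}

#' Solve the Poisson equation
#'
#' div(eps grad V) = -F sum_i z_i c_i with fixed surface charges on the
#' liquid/membrane interface and Dirichlet voltages at the reservoir ends.
#'
#' @param system A [poisson_system()].
#' @param rho Per-liquid-node mobile charge density F sum z_i c_i in C/m^3
#'   (zero if `NULL`).
#' @param charge_map A `pnp_charge_map` (or `NULL` for no fixed charge).
#' @param V_left,V_right Dirichlet voltages (V).
#' @return Nodal voltage vector (volts), one value per mesh node.
#' @export
solve_poisson <- function(system, rho = NULL, charge_map = NULL,
                          V_left = 0, V_right = 0) {
  mesh <- system$mesh
  n <- nrow(mesh$nodes)
  b <- numeric(n)
  if (!is.null(rho)) {
    stopifnot(length(rho) == length(mesh$liquid_nodes))
    b <- b + as.numeric(system$T_load %*% rho)
  }
  if (!is.null(charge_map)) {
    stopifnot(length(charge_map) == nrow(mesh$interface))
    b <- b + as.numeric(system$S_load %*% as.numeric(charge_map))
  }
  V <- numeric(n)
  V[mesh$left_nodes] <- V_left
  V[mesh$right_nodes] <- V_right
  rhs <- b[system$free] -
    as.numeric(system$K_fd %*% V[system$dirichlet])
  V[system$free] <- if (methods::is(system$factor, "CHMfactor")) {
    as.numeric(Matrix::solve(system$factor, rhs, system = "A"))
  } else {
    as.numeric(Matrix::solve(system$factor, rhs))
  }
  V
}

#' Mobile charge density per liquid cell
#'
#' rho = F sum_i z_i c_i, in C/m^3.
#'
#' @param conc Matrix (liquid nodes x species) of concentrations in mol/m^3.
#' @param electrolyte A [electrolyte_spec()].
#' @return Numeric vector, one value per liquid node.
#' @export
charge_density <- function(conc, electrolyte) {
  zs <- vapply(electrolyte$species, `[[`, integer(1), "z")
  physical_constants()$F * as.numeric(conc %*% zs)
}

#' Per-triangle electric field
#'
#' Constant-per-element E = -grad V of the piecewise-linear voltage.
#'
#' @param system A [poisson_system()].
#' @param V Nodal voltage vector.
#' @return Matrix (triangles x 2): columns `Er`, `Ez` in V/m.
#' @export
field_gradients <- function(system, V) {
  tri <- system$mesh$tri
  A2 <- 2 * system$mesh$area
  Vr <- (V[tri[, 1]] * system$grad_b[, 1] + V[tri[, 2]] * system$grad_b[, 2] +
         V[tri[, 3]] * system$grad_b[, 3]) / A2
  Vz <- (V[tri[, 1]] * system$grad_c[, 1] + V[tri[, 2]] * system$grad_c[, 2] +
         V[tri[, 3]] * system$grad_c[, 3]) / A2
  cbind(Er = -Vr, Ez = -Vz)
}

#' One-sided normal electric fields on the interface
#'
#' For each liquid/membrane interface edge, the normal components of the
#' element fields on both sides, with the normal oriented liquid to membrane.
#'
#' @param system A [poisson_system()].
#' @param V Nodal voltage vector.
#' @return Data frame with `E_liquid`, `E_membrane` (V/m), plus the interface
#'   geometry columns of `mesh$interface`.
#' @export
interface_normal_fields <- function(system, V) {
  itf <- system$mesh$interface
  E <- field_gradients(system, V)
  data.frame(
    itf,
    E_liquid = E[itf$liquid_tri, 1] * itf$nr + E[itf$liquid_tri, 2] * itf$nz,
    E_membrane = E[itf$membrane_tri, 1] * itf$nr + E[itf$membrane_tri, 2] * itf$nz
  )
}
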