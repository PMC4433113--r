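# Axisymmetric (r, z) meshing. The domain is a cylinder of radius R_dom:
# two electrolyte reservoirs separated by a dielectric membrane pierced by a
# cylindrical or conical pore on the axis. The grid is boundary-fitted and
# logically rectangular: radial node positions are fractions of the local
# wall radius r_w(z) inside the pore and of [r_w(z), R_dom] outside, so the
# pore wall is always an exact grid line; every quad is split into two
# triangles along the same diagonal. Conformity and region/interface tags
# then follow from the grid indexing alone.

#' Large-opening diameter of a conical pore
#'
#' d_large = d + 2 L_m tan(angle/2). With the canonical geometry (d = 10 nm,
#' L_m = 20 nm, 20 degrees) this is about 17 nm.
#'
#' @param d Small-opening diameter in m.
#' @param L_m Membrane thickness in m.
#' @param opening_angle Full opening angle in degrees (0 = cylinder; < 90).
#' @return Large-opening diameter in m.
#' @export
cone_large_diameter <- function(d, L_m, opening_angle) {
  if (!(d > 0 && L_m > 0)) stop("d and L_m must be > 0", call. = FALSE)
  if (opening_angle < 0 || opening_angle >= 90) {
    stop("opening angle must be in [0, 90) degrees", call. = FALSE)
  }
  d + 2 * L_m * tan(opening_angle / 2 * pi / 180)
}

# Graded interval widths summing exactly to `length`: geometric growth from
# h0 at the fine end, rescaled to fit. `symmetric` grades fine at both ends.
graded_intervals <- function(length, h0, ratio, symmetric = FALSE) {
  stopifnot(length > 0, h0 > 0, ratio > 1)
  if (symmetric) {
    half <- graded_intervals(length / 2, h0, ratio)
    return(c(half, rev(half)))
  }
  if (h0 >= length) return(length)
  w <- h0
  while (sum(w) < length) w <- c(w, w[length(w)] * ratio)
  w * (length / sum(w))
}

# Pore wall radius as a function of z (clamped to the faces outside the
# membrane); vectorized over z.
wall_radius <- function(geometry, z) {
  g <- geometry
  zc <- pmin(pmax(z, 0), g$membrane_thickness)
  slope <- tan(g$opening_angle / 2 * pi / 180)
  if (g$large_opening_side == "right") {
    g$pore_diameter / 2 + zc * slope
  } else {
    g$pore_diameter / 2 + (g$membrane_thickness - zc) * slope
  }
}

# Shared back end: given the node grid (Nc columns x Nz z-levels), quad
# region labels (Nc-1 x Nz-1, "liquid"/"membrane"), build the full tagged
# mesh structure.
mesh_from_grid <- function(r_nodes, z_levels, quad_region, geometry, i_wall) {
  Nc <- ncol(r_nodes)
  Nz <- length(z_levels)
  node_id <- function(i, j) (j - 1L) * Nc + i
  nodes <- cbind(r = as.vector(t(r_nodes)),
                 z = rep(z_levels, each = Nc))

  qi <- rep(seq_len(Nc - 1L), times = Nz - 1L)   # quad column
  qj <- rep(seq_len(Nz - 1L), each = Nc - 1L)    # quad row
  n00 <- node_id(qi, qj); n10 <- node_id(qi + 1L, qj)
  n01 <- node_id(qi, qj + 1L); n11 <- node_id(qi + 1L, qj + 1L)
  # Alternate the split diagonal checkerwise (union-jack pattern): a uniform
  # diagonal direction supports a column-alternating charge mode that the
  # nodal Poisson solve barely sees, which destabilizes the coupled
  # field/transport iteration on high-aspect cells.
  alt <- (qi + qj) %% 2L == 1L
  # alt: diagonal n00-n11 -> (n00,n10,n11) + (n00,n11,n01)
  # else: diagonal n10-n01 -> (n00,n10,n01) + (n10,n11,n01)
  tri <- rbind(
    cbind(n00, n10, ifelse(alt, n11, n01)),
    cbind(ifelse(alt, n00, n10), n11, n01)
  )
  # orient all triangles counter-clockwise (signed subregion integrals below
  # rely on a consistent orientation)
  sgnA <- (nodes[tri[, 2], 1] - nodes[tri[, 1], 1]) *
          (nodes[tri[, 3], 2] - nodes[tri[, 1], 2]) -
          (nodes[tri[, 3], 1] - nodes[tri[, 1], 1]) *
          (nodes[tri[, 2], 2] - nodes[tri[, 1], 2])
  flip_tri <- sgnA < 0
  tmp <- tri[flip_tri, 2]
  tri[flip_tri, 2] <- tri[flip_tri, 3]
  tri[flip_tri, 3] <- tmp
  region <- rep(as.vector(quad_region), 2L)
  row <- rep(qj, 2L); col <- rep(qi, 2L)

  r1 <- nodes[tri[, 1], 1]; r2 <- nodes[tri[, 2], 1]; r3 <- nodes[tri[, 3], 1]
  z1 <- nodes[tri[, 1], 2]; z2 <- nodes[tri[, 2], 2]; z3 <- nodes[tri[, 3], 2]
  area <- 0.5 * abs((r2 - r1) * (z3 - z1) - (r3 - r1) * (z2 - z1))
  rbar <- (r1 + r2 + r3) / 3
  zbar <- (z1 + z2 + z3) / 3
  volume <- 2 * pi * rbar * area  # exact: integrand 2*pi*r is linear

  # quality = 2 * inradius / circumradius (1 for equilateral)
  a <- sqrt((r2 - r3)^2 + (z2 - z3)^2)
  b <- sqrt((r1 - r3)^2 + (z1 - z3)^2)
  cc <- sqrt((r1 - r2)^2 + (z1 - z2)^2)
  s <- (a + b + cc) / 2
  quality <- 2 * (area / s) / (a * b * cc / (4 * area))

  m <- nrow(tri)
  e1 <- tri[, c(1, 2)]; e2 <- tri[, c(2, 3)]; e3 <- tri[, c(3, 1)]
  edges_all <- rbind(e1, e2, e3)
  owner <- rep(seq_len(m), 3L)
  lo <- pmin(edges_all[, 1], edges_all[, 2])
  hi <- pmax(edges_all[, 1], edges_all[, 2])
  key <- lo * (Nc * Nz + 1) + hi
  ord <- order(key)
  key_s <- key[ord]; owner_s <- owner[ord]; lo_s <- lo[ord]; hi_s <- hi[ord]
  first <- !duplicated(key_s)
  idx <- cumsum(first)
  n_edges <- idx[length(idx)]
  t1 <- integer(n_edges); t2 <- integer(n_edges)
  en1 <- lo_s[first]; en2 <- hi_s[first]
  t1[idx[first]] <- owner_s[first]
  dup <- !first
  t2[idx[dup]] <- owner_s[dup]

  liquid <- which(region == "liquid")
  liq_index <- integer(m); liq_index[liquid] <- seq_along(liquid)

  interior <- t2 != 0L
  reg1 <- region[t1]
  reg2 <- rep("boundary", n_edges)
  reg2[interior] <- region[t2[interior]]

  # --- node-centred (Voronoi box scheme) discretization graph ------------
  # Both the Poisson solve and ion transport are discretized on one
  # node-centred finite-volume complex: Voronoi (circumcentre) dual boxes
  # and, per triangle edge, the conductance of the revolved Voronoi facet,
  # w = 2*pi*r_f * cot(theta_opp)/2 with r_f the facet's mean radius
  # (exact: r is linear along the facet segment). In the plane this is
  # identical to P1 finite elements; the axisymmetric facet weighting makes
  # stiffness and box masses exactly compatible, so fields that depend on z
  # only satisfy the 1D equations at every radial column -- with
  # triangle-averaged radii instead, the screening (Debye) response near
  # the axis is wrong at any resolution. Concentrations are piecewise
  # constant on the boxes; membrane triangles contribute no transport
  # conductance, which is the zero-flux wall condition.
  vor_pairs <- function(which_tri) {
    t3 <- tri[which_tri, , drop = FALSE]
    p1r <- nodes[t3[, 1], 1]; p1z <- nodes[t3[, 1], 2]
    p2r <- nodes[t3[, 2], 1]; p2z <- nodes[t3[, 2], 2]
    p3r <- nodes[t3[, 3], 1]; p3z <- nodes[t3[, 3], 2]
    # circumcentre (local coordinates about corner 1 for robustness)
    bx <- p2r - p1r; bz <- p2z - p1z
    cx <- p3r - p1r; cz <- p3z - p1z
    dd <- 2 * (bx * cz - bz * cx)       # 4 * signed area, > 0 for CCW
    b2 <- bx^2 + bz^2; c2 <- cx^2 + cz^2
    ccr <- p1r + (b2 * cz - c2 * bz) / dd
    ccz <- p1z + (c2 * bx - b2 * cx) / dd
    cot_at <- function(ar, az, br, bz2, cr, cz2) {
      # cotangent of the angle at (ar, az); positive cross for CCW input
      ux <- br - ar; uz <- bz2 - az; vx <- cr - ar; vz <- cz2 - az
      (ux * vx + uz * vz) / abs(ux * vz - uz * vx)
    }
    cot1 <- cot_at(p1r, p1z, p2r, p2z, p3r, p3z)
    cot2 <- cot_at(p2r, p2z, p3r, p3z, p1r, p1z)
    cot3 <- cot_at(p3r, p3z, p1r, p1z, p2r, p2z)
    rf12 <- ((p1r + p2r) / 2 + ccr) / 2
    rf23 <- ((p2r + p3r) / 2 + ccr) / 2
    rf31 <- ((p3r + p1r) / 2 + ccr) / 2
    list(i = c(t3[, 1], t3[, 2], t3[, 3]),
         j = c(t3[, 2], t3[, 3], t3[, 1]),
         w = c(pi * rf12 * cot3, pi * rf23 * cot1, pi * rf31 * cot2),
         ccr = ccr, ccz = ccz)
  }
  vp_all <- vor_pairs(seq_len(m))
  vp_all$tri <- rep(seq_len(m), 3)
  in_liq <- vp_all$tri %in% liquid
  vp_liq <- list(i = vp_all$i[in_liq], j = vp_all$j[in_liq],
                 w = vp_all$w[in_liq])
  ltri <- tri[liquid, , drop = FALSE]
  lr1 <- nodes[ltri[, 1], 1]; lr2 <- nodes[ltri[, 2], 1]; lr3 <- nodes[ltri[, 3], 1]
  lz1 <- nodes[ltri[, 1], 2]; lz2 <- nodes[ltri[, 2], 2]; lz3 <- nodes[ltri[, 3], 2]

  plo <- pmin(vp_liq$i, vp_liq$j); phi <- pmax(vp_liq$i, vp_liq$j)
  pkey <- plo * (Nc * Nz + 1) + phi
  agg <- rowsum(vp_liq$w, pkey, reorder = TRUE)
  ekey <- as.numeric(rownames(agg))
  e_i <- as.integer(ekey %/% (Nc * Nz + 1))
  e_j <- as.integer(ekey %% (Nc * Nz + 1))
  e_w <- pmax(as.numeric(agg), 0)  # near-right-angled grid: >= 0 up to roundoff

  liquid_nodes <- sort(unique(as.integer(ltri)))
  node_liq <- integer(nrow(nodes)); node_liq[liquid_nodes] <- seq_along(liquid_nodes)
  node_level <- rep(seq_len(Nz), each = Nc)
  lev_i <- node_level[e_i]; lev_j <- node_level[e_j]
  e_len <- sqrt((nodes[e_i, 1] - nodes[e_j, 1])^2 +
                (nodes[e_i, 2] - nodes[e_j, 2])^2)
  nedge <- data.frame(
    p = node_liq[e_i], q = node_liq[e_j], w = e_w, length = e_len,
    r_mid = (nodes[e_i, 1] + nodes[e_j, 1]) / 2,
    cross = ifelse(lev_i == lev_j, 0L, pmin(lev_i, lev_j)),
    sgn = sign(lev_j - lev_i)
  )

  # Voronoi-dual box volumes: for each (liquid triangle, corner), the signed
  # quad (node, adjacent edge midpoints, circumcentre). The circumcentre
  # dual is the one compatible with the cotangent edge conductances (on the
  # right triangles of this grid the diagonal weights vanish and the scheme
  # is the classical 5-point box method); a median/barycentric dual would
  # give node masses alternating 2:1 between the union-jack node classes
  # against identical stiffness rows, i.e. a screening length that is wrong
  # at any resolution. int 2 pi r dA is exact (r linear over the quad);
  # signed integrals keep the partition exact for mildly obtuse triangles
  # on mapped (conical) grids.
  quad_vol <- function(P1r, P1z, P2r, P2z, P3r, P3z, P4r, P4z) {
    xs <- cbind(P1r, P2r, P3r, P4r); zs <- cbind(P1z, P2z, P3z, P4z)
    xn <- cbind(P2r, P3r, P4r, P1r); zn <- cbind(P2z, P3z, P4z, P1z)
    crossp <- xs * zn - xn * zs
    2 * pi * rowSums((xs + xn) * crossp) / 6  # signed, CCW positive
  }
  # circumcentre relative to corner 1 (local coordinates for robustness)
  bx <- lr2 - lr1; bz <- lz2 - lz1
  cxr <- lr3 - lr1; czr <- lz3 - lz1
  dd <- 2 * (bx * czr - bz * cxr)   # = 4 * signed area > 0 (CCW)
  b2 <- bx^2 + bz^2; c2 <- cxr^2 + czr^2
  ccx <- lr1 + (b2 * czr - c2 * bz) / dd
  ccz <- lz1 + (c2 * bx - b2 * cxr) / dd
  m12r <- (lr1 + lr2) / 2; m12z <- (lz1 + lz2) / 2
  m23r <- (lr2 + lr3) / 2; m23z <- (lz2 + lz3) / 2
  m31r <- (lr3 + lr1) / 2; m31z <- (lz3 + lz1) / 2
  v1 <- quad_vol(lr1, lz1, m12r, m12z, ccx, ccz, m31r, m31z)
  v2 <- quad_vol(lr2, lz2, m23r, m23z, ccx, ccz, m12r, m12z)
  v3 <- quad_vol(lr3, lz3, m31r, m31z, ccx, ccz, m23r, m23z)
  box_vol <- as.numeric(rowsum(c(v1, v2, v3), node_liq[as.integer(ltri)],
                               reorder = TRUE))
  if (any(box_vol <= 0)) {
    stop("non-positive Voronoi box volume: mesh too distorted", call. = FALSE)
  }

  dirichlet_nodes <- node_liq[liquid_nodes[node_level[liquid_nodes] %in% c(1L, Nz)]]

  # --- interface edges (liquid/membrane) ---
  is_int <- interior & reg1 != reg2 & reg2 != "boundary"
  ip_liq <- ifelse(reg1[is_int] == "liquid", t1[is_int], t2[is_int])
  ip_mem <- ifelse(reg1[is_int] == "liquid", t2[is_int], t1[is_int])
  iarr <- nodes[en1[is_int], , drop = FALSE]
  ibrr <- nodes[en2[is_int], , drop = FALSE]
  ilen <- sqrt(rowSums((iarr - ibrr)^2))
  irmid <- (iarr[, 1] + ibrr[, 1]) / 2
  izmid <- (iarr[, 2] + ibrr[, 2]) / 2
  itr <- (ibrr[, 1] - iarr[, 1]) / ilen; itz <- (ibrr[, 2] - iarr[, 2]) / ilen
  inr <- itz; inz <- -itr
  dflip <- inr * (rbar[ip_mem] - rbar[ip_liq]) + inz * (zbar[ip_mem] - zbar[ip_liq]) < 0
  inr[dflip] <- -inr[dflip]; inz[dflip] <- -inz[dflip]
  ztol <- 1e-15 + 1e-9 * abs(geometry$membrane_thickness)
  face_left <- abs(iarr[, 2]) < ztol & abs(ibrr[, 2]) < ztol
  face_right <- abs(iarr[, 2] - geometry$membrane_thickness) < ztol &
                abs(ibrr[, 2] - geometry$membrane_thickness) < ztol
  part <- ifelse(face_left, "face_left",
                 ifelse(face_right, "face_right", "pore_wall"))
  interface <- data.frame(n1 = en1[is_int], n2 = en2[is_int],
                          liquid_tri = ip_liq, membrane_tri = ip_mem,
                          part = part, length = ilen, r_mid = irmid,
                          z_mid = izmid, nr = inr, nz = inz,
                          stringsAsFactors = FALSE)

  # --- boundary edges ---
  is_bnd <- !interior
  bn1 <- en1[is_bnd]; bn2 <- en2[is_bnd]
  bz1 <- nodes[bn1, 2]; bz2 <- nodes[bn2, 2]
  br1 <- nodes[bn1, 1]; br2 <- nodes[bn2, 1]
  zmin <- z_levels[1]; zmax <- z_levels[Nz]
  R_dom <- geometry$domain_radius
  btol_z <- 1e-9 * (zmax - zmin); btol_r <- 1e-9 * R_dom
  tag <- rep("outer_cylinder", length(bn1))
  tag[abs(bz1 - zmin) < btol_z & abs(bz2 - zmin) < btol_z] <- "left_end"
  tag[abs(bz1 - zmax) < btol_z & abs(bz2 - zmax) < btol_z] <- "right_end"
  tag[br1 < btol_r & br2 < btol_r] <- "axis"
  boundary <- data.frame(n1 = bn1, n2 = bn2, tag = tag, stringsAsFactors = FALSE)

  node_z <- nodes[, 2]
  left_nodes <- which(abs(node_z - zmin) < btol_z)
  right_nodes <- which(abs(node_z - zmax) < btol_z)

  structure(list(
    nodes = nodes, tri = tri, region = region,
    area = area, rbar = rbar, zbar = zbar, volume = volume,
    quality = quality, row = row, col = col,
    liquid = liquid, liq_index = liq_index,
    liquid_nodes = liquid_nodes, node_liq = node_liq,
    node_level = node_level, nedge = nedge, box_vol = box_vol,
    vor = vp_all,
    dirichlet_nodes = dirichlet_nodes,
    interface = interface, boundary = boundary,
    left_nodes = left_nodes, right_nodes = right_nodes,
    plane_z = (z_levels[-Nz] + z_levels[-1]) / 2,  # plane k cuts rows k|k+1
    z_levels = z_levels, i_wall = i_wall,
    h_min = min(nedge$length),
    geometry = geometry
  ), class = "pnp_mesh")
}

#' Build the axisymmetric nanopore mesh
#'
#' Graded conforming triangulation of the two-reservoir + membrane + pore
#' domain. The finest elements (about `controls$min_element_size`) sit along
#' the pore wall and the membrane faces; element size grows geometrically by
#' `controls$mesh_growth_ratio` toward the far boundaries. Region labels
#' (`liquid`/`membrane`), liquid/membrane interface edges and outer boundary
#' tags (`left_end`, `right_end`, `outer_cylinder`, `axis`) are populated.
#'
#' @param geometry A [geometry_spec()].
#' @param controls A [numerical_controls()] (only the mesh fields are used).
#' @param quality_floor Minimum accepted triangle quality
#'   (2 inradius / circumradius); the graded anisotropic far field is
#'   intentionally below isotropic quality, so the default floor is low.
#' @return A `pnp_mesh` object.
#' @export
build_mesh <- function(geometry, controls = numerical_controls(),
                       quality_floor = 0.01) {
  g <- geometry
  h0 <- controls$min_element_size
  ratio <- controls$mesh_growth_ratio

  r_small <- g$pore_diameter / 2
  r_large <- cone_large_diameter(g$pore_diameter, g$membrane_thickness,
                                 g$opening_angle) / 2

  w_in <- rev(graded_intervals(r_small, h0, ratio))      # fine at the wall
  f_in <- cumsum(c(0, w_in)) / r_small                   # fractions of [0, r_w]
  w_out <- graded_intervals(g$domain_radius - r_large, h0, ratio)
  f_out <- cumsum(w_out) / sum(w_out)                    # fractions of [r_w, R]

  z_left <- -rev(cumsum(graded_intervals(g$reservoir_depth, h0, ratio)))
  z_mem <- cumsum(c(0, graded_intervals(g$membrane_thickness, h0, ratio,
                                        symmetric = TRUE)))
  z_right <- g$membrane_thickness +
    cumsum(graded_intervals(g$reservoir_depth, h0, ratio))
  z_levels <- c(z_left, z_mem, z_right)

  i_wall <- length(f_in)                                 # node column on the wall
  Nc <- i_wall + length(f_out)
  Nz <- length(z_levels)

  rw <- wall_radius(g, z_levels)
  r_nodes <- matrix(0, nrow = Nz, ncol = Nc)
  for (j in seq_len(Nz)) {
    r_nodes[j, seq_len(i_wall)] <- f_in * rw[j]
    r_nodes[j, (i_wall + 1L):Nc] <- rw[j] + f_out * (g$domain_radius - rw[j])
  }

  j_f0 <- which(abs(z_levels) < 1e-18 + 1e-9 * g$membrane_thickness)[1]
  j_f1 <- which(abs(z_levels - g$membrane_thickness) <
                1e-18 + 1e-9 * g$membrane_thickness)[1]
  quad_region <- matrix("liquid", nrow = Nc - 1L, ncol = Nz - 1L)
  quad_region[i_wall:(Nc - 1L), j_f0:(j_f1 - 1L)] <- "membrane"

  mesh <- mesh_from_grid(r_nodes, z_levels, quad_region, g, i_wall)
  if (min(mesh$quality) < quality_floor) {
    stop(sprintf("mesh quality %.3g below floor %.3g", min(mesh$quality),
                 quality_floor), call. = FALSE)
  }
  mesh
}

#' Build a flat-membrane (no pore) slab mesh
#'
#' A membrane slab spanning the full radius with a reservoir on each side:
#' the parallel-plate fixture used for capacitor checks and for flat-wall
#' double-layer (Gouy-Chapman) comparisons. The two reservoirs are not
#' connected; at zero bias each equilibrates independently.
#'
#' @param membrane_thickness,reservoir_depth,domain_radius Geometry in m.
#' @param h_z Finest axial element size at the membrane faces, in m.
#' @param ratio Geometric growth ratio away from the faces.
#' @param n_r Number of (uniform) radial columns.
#' @return A `pnp_mesh` with `face_left`/`face_right` interface edges and no
#'   pore wall.
#' @export
build_slab_mesh <- function(membrane_thickness = 20e-9,
                            reservoir_depth = 100e-9,
                            domain_radius = 50e-9,
                            h_z = 0.25e-9, ratio = 1.3, n_r = 3) {
  g <- geometry_spec(membrane_thickness = membrane_thickness,
                     pore_diameter = domain_radius / 100, # placeholder, unused
                     reservoir_depth = reservoir_depth,
                     domain_radius = domain_radius)
  z_left <- -rev(cumsum(graded_intervals(reservoir_depth, h_z, ratio)))
  z_mem <- cumsum(c(0, graded_intervals(membrane_thickness, h_z, ratio,
                                        symmetric = TRUE)))
  z_right <- membrane_thickness +
    cumsum(graded_intervals(reservoir_depth, h_z, ratio))
  z_levels <- c(z_left, z_mem, z_right)
  Nz <- length(z_levels)
  r_cols <- seq(0, domain_radius, length.out = n_r + 1L)
  r_nodes <- matrix(rep(r_cols, each = Nz), nrow = Nz)

  j_f0 <- which(abs(z_levels) < 1e-9 * membrane_thickness + 1e-18)[1]
  j_f1 <- which(abs(z_levels - membrane_thickness) <
                1e-9 * membrane_thickness + 1e-18)[1]
  quad_region <- matrix("liquid", nrow = n_r, ncol = Nz - 1L)
  quad_region[, j_f0:(j_f1 - 1L)] <- "membrane"
  mesh_from_grid(r_nodes, z_levels, quad_region, g, i_wall = NA_integer_)
}

#' Resolve a surface-charge specification against a mesh
#'
#' @param mesh A `pnp_mesh`.
#' @param configuration Configuration name (see [charge_spec()]) or a
#'   `pnp_charge_spec`.
#' @param sigma Surface charge density in C/m^2 for the named configurations.
#' @return Numeric vector: sigma per interface edge (C/m^2), class
#'   `pnp_charge_map`. Unlisted interface edges carry 0.
#' @export
make_charge_map <- function(mesh, configuration = "uncharged", sigma = 0) {
  if (inherits(configuration, "pnp_charge_spec")) {
    spec <- configuration
    configuration <- spec$configuration
    if (missing(sigma)) sigma <- spec$sigma
    segments <- spec$segments
  } else {
    segments <- NULL
  }
  itf <- mesh$interface
  if (!nrow(itf)) stop("mesh has no interface edges", call. = FALSE)
  out <- numeric(nrow(itf))
  L_m <- mesh$geometry$membrane_thickness
  half <- L_m / 2
  if (configuration == "uncharged") {
    # all zero
  } else if (configuration == "a_uniform") {
    out[] <- sigma
  } else if (configuration == "b_pore_only") {
    out[itf$part == "pore_wall"] <- sigma
  } else if (configuration == "c_asymmetric") {
    out[itf$part == "face_left"] <- sigma
    out[itf$part == "pore_wall" & itf$z_mid < half] <- sigma
  } else if (configuration == "custom") {
    if (is.null(segments)) stop("custom configuration needs segments", call. = FALSE)
    for (sg in segments) {
      sel <- itf$part == sg$part
      if (!is.null(sg$z_min)) sel <- sel & itf$z_mid >= sg$z_min
      if (!is.null(sg$z_max)) sel <- sel & itf$z_mid <= sg$z_max
      out[sel] <- sg$sigma
    }
  } else {
    stop("unknown charge configuration '", configuration,
         "'; valid: uncharged, a_uniform, b_pore_only, c_asymmetric, custom",
         call. = FALSE)
  }
  structure(out, class = "pnp_charge_map")
}

#' Total fixed charge carried by a charge map
#'
#' Surface integral sum(sigma * 2 pi r_mid * edge length) over the charged
#' interface edges; matches the analytic lateral-surface formulas for
#' cylinder and cone exactly (the integrand is linear in r along each edge).
#'
#' @param mesh A `pnp_mesh`.
#' @param charge_map A `pnp_charge_map`.
#' @return Charge in coulomb.
#' @export
total_surface_charge <- function(mesh, charge_map) {
  sum(charge_map * 2 * pi * mesh$interface$r_mid * mesh$interface$length)
}

#' @export
print.pnp_mesh <- function(x, ...) {
  cat("<pnp_mesh>\n")
  cat(sprintf("  %d nodes, %d triangles (%d liquid, %d membrane)\n",
              nrow(x$nodes), length(x$region), length(x$liquid),
              sum(x$region == "membrane")))
  cat(sprintf("  %d liquid nodes, %d transport edges, %d interface edges, min quality %.3f\n",
              length(x$liquid_nodes), nrow(x$nedge), nrow(x$interface),
              min(x$quality)))
  cat(sprintf("  min edge length %.3g nm\n", x$h_min * 1e9))
  invisible(x)
}
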