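# The two core algorithms. Time-dependent PNP: the Poisson equation is
# refreshed every dt_P (a fraction of the membrane RC time constant) and the
# concentrations are advanced between refreshes by explicit finite-volume
# steps of dt_NP (a fraction of the diffusive stability limit dx^2/D of the
# realized mesh). Steady state: alternate a short time simulation with
# frozen-field steady Nernst-Planck solves whose volume-averaged
# concentration change, averaged over the two species, is added to BOTH
# species -- a common-mode shift that leaves the charge density and hence
# the electric field untouched -- until the per-species currents through
# planes parallel to the membrane are spatially uniform to within the
# tolerance (0.5% of the total current, or of the estimated current at the
# reference voltage when no bias is applied).

#' Set up a simulation
#'
#' Builds the mesh, resolves the surface-charge map, assembles and
#' factorizes the Poisson system, and computes the time-stepping plan.
#'
#' @param config A `pnp_config`.
#' @return A `pnp_simulation` object.
#' @export
pnp_simulation <- function(config) {
  stopifnot(inherits(config, "pnp_config"))
  mesh <- build_mesh(config$geometry, config$controls)
  charge_map <- make_charge_map(mesh, config$charges)
  system <- poisson_system(mesh, config$eps_r_water, config$eps_r_membrane)
  plan <- time_stepping_plan(config, mesh)
  structure(list(
    config = config, mesh = mesh, charge_map = charge_map,
    system = system, plan = plan,
    vol = mesh$box_vol,
    I_ref = estimate_reference_current(config)
  ), class = "pnp_simulation")
}

#' Dual time-step plan
#'
#' dt_P = f_P * tau_RC (Poisson refresh), dt_NP = min(dt_P, f_NP *
#' dx_min^2 / D_max) with dx_min the smallest facet-normal cell-centre
#' distance of the realized mesh and D_max the diffusion coefficient of the
#' most mobile species; inner_steps = ceil(dt_P / dt_NP).
#'
#' @param config A `pnp_config`.
#' @param mesh The realized `pnp_mesh`.
#' @return List with `tau_RC`, `dt_P`, `dt_NP`, `inner_steps`, `duration`.
#' @export
time_stepping_plan <- function(config, mesh) {
  ct <- config$controls
  rc <- membrane_RC(config$geometry, config$electrolyte, config$eps_r_membrane)
  D_max <- max(vapply(config$electrolyte$species, `[[`, numeric(1), "D"))
  dt_P <- ct$poisson_step_fraction * rc$tau
  dt_NP <- min(dt_P, ct$transport_step_fraction * mesh$h_min^2 / D_max)
  inner <- ceiling(dt_P / dt_NP)
  list(tau_RC = rc$tau, dt_P = dt_P, dt_NP = dt_NP,
       inner_steps = inner, duration = ct$rc_multiples * rc$tau,
       R = rc$R, C = rc$C)
}

#' Initial (bulk) state
#'
#' Uniform bulk concentrations with the consistent Poisson solution at the
#' given bias.
#'
#' @param sim A [pnp_simulation()].
#' @param V_left,V_right Bias voltages; default the configured ones.
#' @return A `pnp_state`: list with `time`, `V` (nodal volts), `conc`
#'   (liquid nodes x species, mol/m^3).
#' @export
initial_state <- function(sim, V_left = sim$config$V_left,
                          V_right = sim$config$V_right) {
  el <- sim$config$electrolyte
  nl <- length(sim$mesh$liquid_nodes)
  conc <- vapply(el$species, function(s) rep(s$c_B, nl), numeric(nl))
  dimnames(conc) <- list(NULL, names(el$species))
  V <- solve_poisson(sim$system, charge_density(conc, el), sim$charge_map,
                     V_left, V_right)
  structure(list(time = 0, V = V, conc = conc), class = "pnp_state")
}

# One Poisson refresh followed by the inner explicit transport steps.
# Returns the updated state; ops are rebuilt from the fresh voltage.
poisson_transport_cycle <- function(sim, state, V_left, V_right) {
  el <- sim$config$electrolyte
  mesh <- sim$mesh
  V <- solve_poisson(sim$system, charge_density(state$conc, el),
                     sim$charge_map, V_left, V_right)
  Vl <- liquid_voltages(mesh, V)
  T <- el$temperature
  ops <- lapply(el$species, function(sp) transport_operator(mesh, sp, Vl, T))
  dt <- min(sim$plan$dt_NP, 0.9 * min(vapply(ops, `[[`, numeric(1), "dt_pos")))
  n_inner <- ceiling(sim$plan$dt_P / dt)
  dt <- sim$plan$dt_P / n_inner
  conc <- state$conc
  vol <- sim$vol
  dir <- mesh$dirichlet_nodes
  for (k in seq_len(n_inner)) {
    for (s in seq_along(ops)) {
      cs <- conc[, s] + dt * as.numeric(ops[[s]]$L %*% conc[, s]) / vol
      cs <- clip_negatives(cs, el$species[[s]])
      cs[dir] <- el$species[[s]]$c_B
      conc[, s] <- cs
    }
  }
  structure(list(time = state$time + sim$plan$dt_P, V = V, conc = conc,
                 ops = ops), class = "pnp_state")
}

#' Run a time-dependent PNP simulation
#'
#' Alternates Poisson solves and explicit transport for the requested
#' duration, starting from `state`.
#'
#' @param sim A [pnp_simulation()].
#' @param state Starting `pnp_state` (see [initial_state()]).
#' @param duration Simulated time (s); default the configured
#'   `rc_multiples` RC constants (0.2 us for the canonical domain).
#' @param V_left,V_right Bias voltages; default the configured ones.
#' @param record_every Record a trajectory row every this many Poisson steps
#'   (0 = record only the final point).
#' @return List with `state` (final), and `trajectory`: data frame of
#'   `time` (s), per-species mid-plane currents and `I_total` (A).
#' @export
run_time_simulation <- function(sim, state, duration = sim$plan$duration,
                                V_left = sim$config$V_left,
                                V_right = sim$config$V_right,
                                record_every = 0) {
  n_steps <- max(1L, round(duration / sim$plan$dt_P))
  rows <- list()
  for (step in seq_len(n_steps)) {
    state <- poisson_transport_cycle(sim, state, V_left, V_right)
    if (record_every > 0 && (step %% record_every == 0L || step == n_steps)) {
      I <- midplane_current(sim, state)
      rows[[length(rows) + 1L]] <- c(time = state$time, I)
    }
  }
  trajectory <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows))
  } else {
    mid <- midplane_current(sim, state)
    as.data.frame(t(c(time = state$time, mid)))
  }
  list(state = state, trajectory = trajectory)
}

# Total and per-species current at the plane nearest the membrane centre.
midplane_current <- function(sim, state) {
  prof <- current_profile(sim, state)
  mid <- which.min(abs(prof$z - sim$config$geometry$membrane_thickness / 2))
  I <- prof$I[mid, ]
  c(I, I_total = sum(I))
}

#' Plane-current uniformity metric
#'
#' Maximum over species of the spread (max - min over planes) of the plane
#' current, divided by the normalization scale: the mean total current
#' magnitude under bias, or the estimated reference current at zero bias.
#'
#' @param profile A current profile from [current_profile()].
#' @param scale Normalization current (A).
#' @return Dimensionless metric; converged when below the uniformity
#'   tolerance.
#' @export
convergence_metric <- function(profile, scale) {
  if (!nrow(profile$I)) stop("empty current profile", call. = FALSE)
  if (!(scale > 0)) stop("normalization scale must be > 0", call. = FALSE)
  spread <- apply(profile$I, 2, function(x) max(x) - min(x))
  max(spread) / scale
}

#' Accelerated steady-state solve
#'
#' Outer loop: (1) time-simulate `steady_rc_multiples` RC constants; (2) test
#' plane-current uniformity; (3) if not converged, solve the frozen-field
#' steady Nernst-Planck equation per species, form the volume-weighted mean
#' concentration change per species, average the two species' means into one
#' common-mode shift, and add it to both species (leaving the field
#' unchanged); repeat.
#'
#' @param sim A [pnp_simulation()].
#' @param state Starting `pnp_state`.
#' @param V_left,V_right Bias voltages; default the configured ones.
#' @param shift_damping Fraction of the common-mode shift applied per outer
#'   iteration (1 = undamped; the default 0.5 is robust for strongly
#'   charged walls).
#' @param verbose Print the per-iteration uniformity metric.
#' @return List with `state`, and `report`: list with `converged`,
#'   `iterations`, `metric`, `scale`, `spread` (per species, A), and the
#'   final `profile`.
#' @export
steady_state_solve <- function(sim, state,
                               V_left = sim$config$V_left,
                               V_right = sim$config$V_right,
                               shift_damping = 0.5,
                               verbose = FALSE) {
  ct <- sim$config$controls
  el <- sim$config$electrolyte
  chunk <- ct$steady_rc_multiples * sim$plan$tau_RC
  vol <- sim$vol
  history <- numeric(0)
  for (iter in seq_len(ct$max_outer_iterations)) {
    state <- run_time_simulation(sim, state, duration = chunk,
                                 V_left = V_left, V_right = V_right)$state
    prof <- current_profile(sim, state)
    scale <- if (abs(V_left - V_right) > 0) {
      abs(mean(rowSums(prof$I)))
    } else {
      sim$I_ref
    }
    scale <- max(scale, .Machine$double.xmin)
    metric <- convergence_metric(prof, scale)
    history <- c(history, metric)
    if (verbose) {
      message(sprintf("outer %3d: uniformity %.4g (tol %.3g)", iter, metric,
                      ct$uniformity_tolerance))
    }
    if (metric <= ct$uniformity_tolerance) {
      spread <- apply(prof$I, 2, function(x) max(x) - min(x))
      report <- list(converged = TRUE, iterations = iter, metric = metric,
                     scale = scale, spread = spread, history = history,
                     profile = prof)
      return(list(state = state, report = report))
    }
    # Frozen-field steady solves and common-mode shift: the change to the
    # steady solution, averaged pointwise over the two species, is added to
    # both species. For a 1:-1 electrolyte this leaves the charge density
    # (hence the field) exactly unchanged while jumping the slow co-diffusion
    # (common) mode toward its frozen-field steady profile. The shift is
    # damped (the frozen-field target overshoots where strong double layers
    # re-shape the field between iterations) and clamped from below so that
    # no species goes negative -- the clamp acts on the common mode, so the
    # field stays untouched.
    delta <- shift_damping * rowMeans(vapply(el$species, function(sp) {
      steady_transport_solve(sim$mesh, sp, state$V, el$temperature) -
        state$conc[, sp$name]
    }, numeric(length(vol))))
    delta <- pmax(delta, -apply(state$conc, 1, min))
    for (s in seq_along(el$species)) {
      cs <- state$conc[, s] + delta
      cs[sim$mesh$dirichlet_nodes] <- el$species[[s]]$c_B
      state$conc[, s] <- cs
    }
  }
  stop(sprintf(
    "steady state not reached in %d outer iterations (last uniformity %.3g, tol %.3g)",
    ct$max_outer_iterations, history[length(history)], ct$uniformity_tolerance),
    call. = FALSE)
}

#' Equilibrate the double layer at zero bias
#'
#' Builds the equilibrium double layers around all charged surfaces at
#' V_left = V_right = 0 and then runs the steady-state acceleration to the
#' documented uniformity criterion. The uniform bulk start is first pulled
#' onto the nonlinear equilibrium by a damped Poisson-Boltzmann fixed point
#' (concentrations set to clamped Boltzmann factors of the current
#' potential, potential relaxed under damping): the unscreened fixed
#' surface charge initially produces wall potentials of many volts, which
#' the time integrator would need thousands of steps to screen, while the
#' damped fixed point collapses them in a few dozen Poisson solves. For an
#' uncharged configuration the bulk state is already stationary.
#'
#' @param sim A [pnp_simulation()].
#' @param damping Fixed-point damping factor on the potential update.
#' @param tol Convergence tolerance on the potential update (V).
#' @param max_iter Iteration cap for the fixed point.
#' @return A `pnp_state` at equilibrium (time reset to 0).
#' @export
initialize_equilibrium <- function(sim, tol = 1e-9, max_iter = 60) {
  el <- sim$config$electrolyte
  state <- initial_state(sim, V_left = 0, V_right = 0)
  if (any(sim$charge_map != 0)) {
    pb <- equilibrium_poisson_boltzmann(sim, tol = tol, max_iter = max_iter)
    state$V <- pb$V
    state$conc <- pb$conc
  }
  res <- steady_state_solve(sim, state, V_left = 0, V_right = 0)
  st <- res$state
  st$time <- 0
  st
}

# Damped Newton solve of the nonlinear equilibrium (Poisson-Boltzmann)
# problem at zero bias: concentrations are Boltzmann factors of the
# potential, so the Poisson residual R(V) = K V - b_sigma - load(rho(V)) is
# solved with Jacobian K + diag(box_vol * F sum z^2 c_i(V) / VT). Newton
# steps are clamped to 1 V; exponents are clamped to +-60 so early iterates
# cannot overflow. Converges in a handful of iterations where a plain
# damped fixed point oscillates (the screening response is far too stiff).
equilibrium_poisson_boltzmann <- function(sim, tol = 1e-9, max_iter = 60) {
  el <- sim$config$electrolyte
  sys <- sim$system
  mesh <- sim$mesh
  k <- physical_constants()
  VT <- thermal_voltage(el$temperature)
  n <- nrow(mesh$nodes)
  free <- sys$free
  b_sigma <- as.numeric(sys$S_load %*% as.numeric(sim$charge_map))
  V <- numeric(n)
  nl <- length(mesh$liquid_nodes)
  zs <- vapply(el$species, `[[`, integer(1), "z")
  cBs <- vapply(el$species, `[[`, numeric(1), "c_B")
  conc <- NULL
  for (it in seq_len(max_iter)) {
    Vl <- V[mesh$liquid_nodes]
    conc <- vapply(seq_along(el$species), function(s) {
      cBs[s] * exp(pmin(pmax(-zs[s] * Vl / VT, -60), 60))
    }, numeric(nl))
    rho <- k$F * as.numeric(conc %*% zs)
    drho <- (k$F / VT) * as.numeric(conc %*% zs^2)   # -d(rho)/dV >= 0
    R <- as.numeric(sys$K %*% V) - b_sigma -
      as.numeric(sys$T_load %*% rho)
    Jd <- numeric(n)
    Jd[mesh$liquid_nodes] <- mesh$box_vol * drho
    J <- sys$K[free, free, drop = FALSE] + Matrix::Diagonal(x = Jd[free])
    dV <- as.numeric(Matrix::solve(J, -R[free]))
    dV <- pmin(pmax(dV, -1), 1)
    V[free] <- V[free] + dV
    if (max(abs(dV)) < tol) break
  }
  dimnames(conc) <- list(NULL, names(el$species))
  conc[mesh$dirichlet_nodes, ] <- matrix(cBs, length(mesh$dirichlet_nodes),
                                         length(el$species), byrow = TRUE)
  list(V = V, conc = conc, iterations = it)
}

#' @export
print.pnp_simulation <- function(x, ...) {
  cat("<pnp_simulation>\n")
  print(x$config)
  cat(sprintf("  mesh: %d liquid nodes, h_min = %.3g nm\n",
              length(x$mesh$liquid_nodes), x$mesh$h_min * 1e9))
  cat(sprintf("  plan: tau_RC = %.3g s, dt_P = %.3g s, dt_NP = %.3g s (%d inner)\n",
              x$plan$tau_RC, x$plan$dt_P, x$plan$dt_NP, x$plan$inner_steps))
  invisible(x)
}
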