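# Scenario presets for the canonical simulation study, the I-V sweep
# driver and the reporting layer.

preset_names <- c("uncharged_cyl", "a_uniform", "b_pore_only", "c_asymmetric",
                  "cone_uniform", "cone_pore_only", "overlimiting_thin")

#' Scenario presets
#'
#' Fully specified simulation scenarios. The cylindrical presets use a 10 nm
#' pore in a 20 nm membrane at 10 mM KCl with -50 mC/m^2 where charged:
#' `uncharged_cyl` (no fixed charge), `a_uniform` (pore wall and both
#' membrane faces charged), `b_pore_only` (pore wall only), `c_asymmetric`
#' (left face and left half of the pore wall). The conical presets add a 20
#' degree opening angle with the large (about 17 nm) opening at the right.
#' `overlimiting_thin` is the thin-membrane case: 10 nm pore, 5 nm membrane,
#' 100 mM KCl, -100 mC/m^2 in the asymmetric configuration, which produces
#' an overlimiting conductance at the low-conductance polarity.
#'
#' @param name One of the names above.
#' @param profile Mesh resolution profile (see [mesh_profile()]).
#' @return A `pnp_scenario`: list with `name`, `config`, `bias` (the default
#'   sweep grid, V) and `outputs`.
#' @export
preset <- function(name, profile = "coarse") {
  if (!name %in% preset_names) {
    stop("unknown preset '", name, "'; valid: ",
         paste(preset_names, collapse = ", "), call. = FALSE)
  }
  prof <- mesh_profile(profile)
  controls <- numerical_controls(min_element_size = prof$min_element_size,
                                 mesh_growth_ratio = prof$mesh_growth_ratio)
  cyl <- geometry_spec()
  cone <- geometry_spec(opening_angle = 20, large_opening_side = "right")
  sig <- -50e-3
  spec <- switch(name,
    uncharged_cyl = list(geom = cyl, el = kcl_electrolyte(10),
                         ch = charge_spec("uncharged"),
                         bias = c(-0.5, -0.25, 0.25, 0.5)),
    a_uniform = list(geom = cyl, el = kcl_electrolyte(10),
                     ch = charge_spec("a_uniform", sig),
                     bias = setdiff(seq(-1, 1, 0.25), 0)),
    b_pore_only = list(geom = cyl, el = kcl_electrolyte(10),
                       ch = charge_spec("b_pore_only", sig),
                       bias = setdiff(seq(-1, 1, 0.25), 0)),
    c_asymmetric = list(geom = cyl, el = kcl_electrolyte(10),
                        ch = charge_spec("c_asymmetric", sig),
                        bias = setdiff(seq(-1, 1, 0.25), 0)),
    cone_uniform = list(geom = cone, el = kcl_electrolyte(10),
                        ch = charge_spec("a_uniform", sig),
                        bias = setdiff(seq(-1, 1, 0.25), 0)),
    cone_pore_only = list(geom = cone, el = kcl_electrolyte(10),
                          ch = charge_spec("b_pore_only", sig),
                          bias = setdiff(seq(-1, 1, 0.25), 0)),
    overlimiting_thin = list(
      geom = geometry_spec(membrane_thickness = 5e-9),
      el = kcl_electrolyte(100),
      ch = charge_spec("c_asymmetric", -100e-3),
      bias = setdiff(seq(-1, 1, 0.25), 0))
  )
  config <- simulation_config(geometry = spec$geom, electrolyte = spec$el,
                              charges = spec$ch, controls = controls)
  structure(list(name = name, config = config, bias = spec$bias,
                 outputs = c("iv", "profiles")),
            class = "pnp_scenario")
}

#' Run an I-V sweep for a scenario
#'
#' For each bias point: start from the shared 0 V equilibrium state, run the
#' time simulation for the configured number of RC constants (recording the
#' "0.2 us" current), then run the steady-state acceleration (recording the
#' steady current and its species split). A bias point whose steady solve
#' fails is recorded as failed and the sweep continues.
#'
#' @param scenario A [preset()] or `pnp_scenario`.
#' @param bias Optional bias grid override (V).
#' @param verbose Print progress.
#' @return A `pnp_sweep`: list with `iv` (data frame: V, I_time, I_steady,
#'   per-species steady currents, converged flag, outer iterations),
#'   `curve_steady` and `curve_time` ([iv_curve()] results on the converged
#'   points), `reports` (per-bias convergence reports), `sim`, and
#'   `equilibrium` (the shared 0 V state).
#' @export
run_iv_sweep <- function(scenario, bias = NULL, verbose = FALSE) {
  stopifnot(inherits(scenario, "pnp_scenario"))
  if (is.null(bias)) bias <- scenario$bias
  if (anyDuplicated(bias)) stop("duplicate bias points", call. = FALSE)
  sim <- pnp_simulation(scenario$config)
  if (verbose) message("equilibrating at 0 V ...")
  eq <- initialize_equilibrium(sim)
  rows <- list(); reports <- list()
  for (Vb in bias) {
    if (verbose) message(sprintf("bias %+.3g V ...", Vb))
    res <- tryCatch({
      tr <- run_time_simulation(sim, eq, V_left = Vb, V_right = 0)
      I_time <- unname(tr$trajectory$I_total[nrow(tr$trajectory)])
      ss <- steady_state_solve(sim, tr$state, V_left = Vb, V_right = 0)
      prof <- ss$report$profile
      I_sp <- colMeans(prof$I)
      list(row = c(V = Vb, I_time = I_time, I_steady = mean(prof$I_total),
                   I_sp, converged = 1,
                   iterations = ss$report$iterations),
           report = ss$report)
    }, error = function(e) {
      warning(sprintf("bias %+.3g V failed: %s", Vb, conditionMessage(e)),
              call. = FALSE)
      list(row = c(V = Vb, I_time = NA, I_steady = NA,
                   stats::setNames(rep(NA_real_, length(scenario$config$electrolyte$species)),
                            names(scenario$config$electrolyte$species)),
                   converged = 0, iterations = NA),
           report = conditionMessage(e))
    })
    rows[[length(rows) + 1L]] <- res$row
    reports[[sprintf("%+.3g", Vb)]] <- res$report
  }
  iv <- as.data.frame(do.call(rbind, rows))
  if (all(iv$converged == 0)) stop("all bias points failed", call. = FALSE)
  ok <- iv$converged == 1
  curve_steady <- if (sum(ok) >= 2) iv_curve(iv$V[ok], iv$I_steady[ok]) else NULL
  curve_time <- if (sum(ok) >= 2) iv_curve(iv$V[ok], iv$I_time[ok]) else NULL
  structure(list(name = scenario$name, iv = iv, curve_steady = curve_steady,
                 curve_time = curve_time, reports = reports, sim = sim,
                 equilibrium = eq),
            class = "pnp_sweep")
}

#' Compare a sweep against a measured I-V table
#'
#' No fitting or rescaling: simply the ratio of simulated steady currents to
#' the supplied measurements at matching voltages.
#'
#' @param sweep A `pnp_sweep`.
#' @param measured Data frame (or CSV path) with columns `V` (volts) and
#'   `I` (amperes).
#' @return Data frame with `V`, `I_measured`, `I_simulated`, `ratio`.
#' @export
overlay_measured <- function(sweep, measured) {
  if (is.character(measured)) measured <- utils::read.csv(measured)
  stopifnot(all(c("V", "I") %in% names(measured)))
  iv <- sweep$iv
  m <- merge(data.frame(V = measured$V, I_measured = measured$I),
             data.frame(V = iv$V, I_simulated = iv$I_steady), by = "V")
  m$ratio <- m$I_simulated / m$I_measured
  m
}

#' Write sweep outputs
#'
#' Writes `iv.csv` (bias table with time and steady currents), a
#' `profiles.csv` with the converged per-plane species currents of each
#' bias, and `convergence.log` with the outer-iteration metrics.
#'
#' @param sweep A `pnp_sweep`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
report_sweep <- function(sweep, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("cannot write to ", out_dir, call. = FALSE)
  iv_path <- file.path(out_dir, "iv.csv")
  utils::write.csv(sweep$iv, iv_path, row.names = FALSE)
  prof_rows <- list()
  for (nm in names(sweep$reports)) {
    rep_i <- sweep$reports[[nm]]
    if (is.list(rep_i)) {
      p <- rep_i$profile
      prof_rows[[nm]] <- data.frame(V = as.numeric(nm), z = p$z,
                                    p$I, I_total = p$I_total,
                                    check.names = FALSE)
    }
  }
  prof_path <- file.path(out_dir, "profiles.csv")
  utils::write.csv(do.call(rbind, prof_rows), prof_path, row.names = FALSE)
  log_path <- file.path(out_dir, "convergence.log")
  lines <- character(0)
  for (nm in names(sweep$reports)) {
    rep_i <- sweep$reports[[nm]]
    if (is.list(rep_i)) {
      lines <- c(lines, sprintf("%s  bias %s V: converged in %d outer iterations; uniformity %s",
                                format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), nm,
                                rep_i$iterations,
                                paste(signif(rep_i$history, 4), collapse = " ")))
    } else {
      lines <- c(lines, sprintf("%s  bias %s V: FAILED: %s",
                                format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), nm, rep_i))
    }
  }
  writeLines(lines, log_path)
  invisible(c(iv_path, prof_path, log_path))
}
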