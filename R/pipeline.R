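#' Simulation configuration
#'
#' Bundles everything one simulation arm needs. Three arms are supported:
#' rigid-wall CFD (\code{cfd_rigid}), FSI with a distensible pre-stressed
#' wall (\code{fsi_no_bending}), and FSI with the artery-specific bending
#' displacement added (\code{fsi_bending}).
#'
#' @param mode One of "cfd_rigid", "fsi_no_bending", "fsi_bending".
#' @param geometry An \code{artery_geometry} (the imaged diastolic
#'   configuration).
#' @param bc A \code{flow_bc}.
#' @param material Wall \code{ogden_material}.
#' @param peri Perivascular \code{linear_elastic_material}.
#' @param blood A \code{carreau_model}.
#' @param bending For \code{fsi_bending}: list with \code{diastole} and
#'   \code{systole} centrelines (or a ready \code{bending_field}).
#' @param amplitude Optional \code{amplitude_waveform}; default is the
#'   smoothed asymmetric sawtooth peaking at 0.35 T.
#' @param patch_fraction Circumferential fraction loaded by bending
#'   (default 0.3).
#' @param schedule Pre-stress \code{prestress_schedule}; default uses the
#'   minimum of the outlet pressure waveform as the diastolic pressure.
#' @param n_t Time steps per cycle (default 200).
#' @param n_r Radial grid points (default 33).
#' @param n_cycles_max Maximum coupling cycles (default 6, >= 2).
#' @param periodicity_tol Relative cycle-to-cycle change in the diameter
#'   and TAWSS fields below which the solution counts as periodic
#'   (default 1e-3).
#' @param coupling_relax Under-relaxation of the wall pressure load
#'   (default 0.5).
#' @param seed Seed (only synthetic-data generation is stochastic; solvers
#'   are deterministic).
#' @param ... Extra arguments passed to \code{\link{solve_pulsatile_flow}}
#'   (closure coefficients, theta_scheme).
#' @return Object of class \code{simulation_config}.
#' @export
simulation_config <- function(mode = c("cfd_rigid", "fsi_no_bending",
                                       "fsi_bending"),
                              geometry, bc, material = ogden_material(),
                              peri = linear_elastic_material(),
                              blood = carreau_model(), bending = NULL,
                              amplitude = NULL, patch_fraction = 0.3,
                              schedule = NULL, n_t = 200L, n_r = 33L,
                              n_cycles_max = 6L, periodicity_tol = 1e-3,
                              coupling_relax = 0.5, seed = 0, ...) {
  mode <- match.arg(mode)
  if (n_cycles_max < 2) stop("n_cycles_max must be >= 2", call. = FALSE)
  if (mode == "fsi_bending" && is.null(bending))
    stop("fsi_bending mode requires a bending block", call. = FALSE)
  if (is.null(amplitude))
    amplitude <- make_amplitude(bc$T, t_systole = 0.35 * bc$T)
  if (is.null(schedule))
    schedule <- prestress_schedule(pressure_max = min(bc$pressure$value))
  structure(list(mode = mode, geometry = geometry, bc = bc,
                 material = material, peri = peri, blood = blood,
                 bending = bending, amplitude = amplitude,
                 patch_fraction = patch_fraction, schedule = schedule,
                 n_t = as.integer(n_t), n_r = as.integer(n_r),
                 n_cycles_max = as.integer(n_cycles_max),
                 periodicity_tol = periodicity_tol,
                 coupling_relax = coupling_relax, seed = seed,
                 flow_args = list(...)),
            class = "simulation_config")
}

#' Run one simulation arm
#'
#' Executes the configured arm: backward-incremental pre-stress (FSI modes),
#' then a loosely coupled cycle loop alternating a quasi-static wall update
#' (membrane equilibrium under the current pressure field, with
#' amplitude-scaled bending displacement constraints in \code{fsi_bending}
#' mode) and a flow solve on the updated lumen, with under-relaxed pressure
#' exchange, until the diameter and TAWSS fields are cycle-periodic. Shear
#' and strain metrics are computed on the converged cycle.
#'
#' @param config A \code{simulation_config}.
#' @return Object of class \code{simulation_result}: \code{wss}
#'   (\code{wss_field}), \code{metrics} (list of \code{metric_map}s: TAWSS,
#'   tSS, OSI and, for FSI modes, the three cyclic strain components),
#'   \code{diameters} (n_axial x n_t ring-mean diameter, mm),
#'   \code{strain}, \code{prestress}, \code{converged_cycle},
#'   \code{periodicity} (history of cycle-to-cycle changes), \code{time},
#'   \code{config}.
#' @export
run_simulation <- function(config) {
  cfg <- config
  g <- cfg$geometry
  n_t <- cfg$n_t
  tt <- cfg$bc$T * (seq_len(n_t) - 1L) / n_t

  if (cfg$mode == "cfd_rigid") {
    wss <- do.call(solve_pulsatile_flow,
                   c(list(g, cfg$bc, cfg$blood, n_t = n_t, n_r = cfg$n_r,
                          n_cycles = 3L, motion = NULL), cfg$flow_args))
    diam <- matrix(2 * g$lumen_radius, g$n_axial, n_t)
    metrics <- list(TAWSS = tawss(wss), tSS = tss(wss), OSI = osi(wss))
    return(structure(list(mode = cfg$mode, wss = wss, metrics = metrics,
                          diameters = diam, strain = NULL, prestress = NULL,
                          converged_cycle = 1L, periodicity = numeric(0),
                          time = tt, config = cfg),
                     class = "simulation_result"))
  }

  prestress <- backward_incremental_prestress(g, cfg$material, cfg$schedule)
  h0 <- g$wall_thickness * 1e-3
  k_f <- if (is.null(cfg$peri)) 0 else cfg$peri$E / cfg$peri$support_thickness

  bending_on <- cfg$mode == "fsi_bending"
  field <- NULL; amp_t <- rep(0, n_t); damp_dt <- rep(0, n_t)
  pin <- matrix(FALSE, g$n_axial, g$n_circ)
  deforming <- rep(FALSE, g$n_axial); d_tilde <- NULL
  if (bending_on) {
    field <- if (inherits(cfg$bending, "bending_field")) cfg$bending else
      compute_bending_vectors(cfg$bending$diastole, cfg$bending$systole,
                              g$n_axial)
    field <- assign_to_wall(field, g, cfg$patch_fraction)
    pin <- field$patch_mask
    # rigid-translation removal: only the deforming part of the motion
    # constrains distension and shears the near-wall fluid (a pure
    # translation carries the blood with the vessel)
    d_tilde <- sweep(field$vectors, 2, field$vectors[1, ])
    deforming <- row_norms(d_tilde) > 1e-9
    sync <- synchronize(cfg$amplitude, cfg$bc$velocity, cfg$bc$pressure,
                        r_peak_times = c(0, cfg$bc$T), n_t = n_t)
    amp_t <- sync$amplitude
    ip <- c(2:n_t, 1); im <- c(n_t, 1:(n_t - 1))
    damp_dt <- (amp_t[ip] - amp_t[im]) / (2 * cfg$bc$T / n_t)
  }

  # initial wall pressure: outlet waveform at every station
  p_wall <- matrix(mmHg_to_Pa(periodic_interp(cfg$bc$pressure$time_s,
                                              cfg$bc$pressure$value, tt,
                                              cfg$bc$T)),
                   g$n_axial, n_t, byrow = TRUE)

  radius_t <- array(0, c(g$n_axial, g$n_circ, n_t))
  prev_diam <- NULL; prev_tawss <- NULL
  wss <- NULL; periodicity <- numeric(0)
  converged_cycle <- cfg$n_cycles_max

  for (cyc in seq_len(cfg$n_cycles_max)) {
    # --- wall pass: quasi-static membrane update per station and time step
    for (i in seq_len(g$n_axial)) {
      pin_i <- pin[i, ] & bending_on & deforming[i]
      r_prev <- NULL
      for (k in seq_len(n_t)) {
        p_kPa <- p_wall[i, k] / 1000
        if (!any(pin_i)) {
          lt <- inflate_station_supported(cfg$material, prestress$R0[i], h0,
                                          prestress$lambda_z, p_kPa, k_f,
                                          g$lumen_radius[i])
          radius_t[i, , k] <- lt * prestress$R0[i]
        } else {
          r0 <- if (is.null(r_prev)) NULL else r_prev
          radius_t[i, , k] <- ring_solve(cfg$material, prestress$R0[i], h0,
                                         prestress$lambda_z, p_kPa, k_f,
                                         rest_radius = g$lumen_radius[i],
                                         pin = pin_i,
                                         pin_radius = g$lumen_radius[i],
                                         r_init = r0)
          r_prev <- radius_t[i, , k]
        }
      }
    }

    # --- flow pass on the updated lumen
    r_eq <- sqrt(apply(radius_t^2, c(1, 3), mean))
    motion <- list(radius = r_eq)
    if (bending_on) {
      lat <- array(0, c(g$n_axial, n_t, 3))
      for (kk in 1:3)
        lat[, , kk] <- outer(d_tilde[, kk] * 1e-3, damp_dt)
      motion$lateral_velocity <- lat
    }
    wss <- do.call(solve_pulsatile_flow,
                   c(list(g, cfg$bc, cfg$blood, n_t = n_t, n_r = cfg$n_r,
                          n_cycles = 2L, motion = motion), cfg$flow_args))
    p_wall <- cfg$coupling_relax * wss$pressure +
      (1 - cfg$coupling_relax) * p_wall

    # --- periodicity check on diameter and TAWSS fields
    diam <- 2 * apply(radius_t, c(1, 3), mean)
    tw <- tawss(wss)$values
    if (!is.null(prev_diam)) {
      ch <- max(max(abs(diam - prev_diam)) / max(abs(diam)),
                max(abs(tw - prev_tawss)) / max(abs(tw), 1e-12))
      periodicity <- c(periodicity, ch)
      if (ch < cfg$periodicity_tol) { converged_cycle <- cyc; break }
    }
    prev_diam <- diam; prev_tawss <- tw
  }

  # --- wall states over the converged cycle (positions include bending)
  states <- vector("list", n_t)
  for (k in seq_len(n_t)) {
    offset <- if (bending_on) amp_t[k] * field$vectors else NULL
    states[[k]] <- list(radius = radius_t[, , k],
                        positions = surface_points(g,
                                                   radius = radius_t[, , k],
                                                   center_offset = offset))
  }
  diastolic <- states[[1]]
  strain <- cyclic_log_strain(states, diastolic)
  diam <- 2 * apply(radius_t, c(1, 3), mean)

  metrics <- list(TAWSS = tawss(wss), tSS = tss(wss), OSI = osi(wss),
                  strain_circ = metric_map(strain$circ, "strain_circ", "%"),
                  strain_axial = metric_map(strain$axial, "strain_axial", "%"),
                  strain_radial = metric_map(strain$radial, "strain_radial", "%"))

  structure(list(mode = cfg$mode, wss = wss, metrics = metrics,
                 diameters = diam, strain = strain, prestress = prestress,
                 converged_cycle = converged_cycle,
                 periodicity = periodicity, time = tt, config = cfg),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> mode %s, converged cycle %d\n",
              x$mode, x$converged_cycle))
  for (nm in names(x$metrics))
    cat(sprintf("  %s median %.4g %s\n", nm, x$metrics[[nm]]$summary$median,
                x$metrics[[nm]]$units))
  invisible(x)
}

#' Diastole-to-systole diameter change profile
#'
#' Percentage change of the ring-mean diameter between diastole (t = 0) and
#' systole, per axial station; local systolic compression under bending
#' shows up as negative values.
#'
#' @param result A \code{simulation_result}.
#' @param t_systole Time of systole (s); default the configured amplitude
#'   peak.
#' @param proximal_fraction If given, also return the mean over the
#'   proximal fraction of the vessel (e.g. 1/3).
#' @return List with \code{profile} (percent per station) and, if
#'   requested, \code{proximal_mean}.
#' @export
diameter_change_profile <- function(result, t_systole = NULL,
                                    proximal_fraction = NULL) {
  if (is.null(t_systole))
    t_systole <- result$config$amplitude$t_systole
  k_sys <- which.min(abs(result$time - t_systole))
  d_dia <- result$diameters[, 1]
  d_sys <- result$diameters[, k_sys]
  prof <- 100 * (d_sys - d_dia) / d_dia
  out <- list(profile = prof)
  if (!is.null(proximal_fraction)) {
    n <- length(prof)
    out$proximal_mean <- mean(prof[seq_len(max(1, round(proximal_fraction * n)))])
  }
  out
}
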