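#' Pre-stress loading schedule
#'
#' The two-phase backward-incremental loading: axial traction ramped first,
#' then the diastolic pressure, each in fixed increments.
#'
#' @param axial_load_max Peak axial traction (kPa); default 100, equivalent
#'   to a physiological axial stretch.
#' @param axial_steps Increments for the axial phase; default 10.
#' @param pressure_max Diastolic pressure (mmHg); default 80.
#' @param pressure_steps Increments for the pressure phase; default 12.
#' @return Object of class \code{prestress_schedule}.
#' @export
prestress_schedule <- function(axial_load_max = 100, axial_steps = 10,
                               pressure_max = 80, pressure_steps = 12) {
  if (axial_steps < 1 || pressure_steps < 1)
    stop("step counts must be >= 1", call. = FALSE)
  if (axial_load_max < 0 || pressure_max < 0)
    stop("loads must be >= 0", call. = FALSE)
  structure(list(axial_load_max = axial_load_max, axial_steps = axial_steps,
                 pressure_max = pressure_max, pressure_steps = pressure_steps),
            class = "prestress_schedule")
}

# Axial stretch under uniaxial Cauchy traction t (kPa), free lateral
# contraction.
axial_stretch_for_traction <- function(m, traction) {
  if (traction == 0) return(1)
  stats::uniroot(function(l) uniaxial_stress(m, l) - traction,
                 lower = 0.2, upper = 5, tol = 1e-12)$root
}

# Circumferential stretch of an axisymmetric membrane station: unloaded
# radius R0 (mm), unloaded thickness h0 (mm), fixed axial stretch lz,
# internal pressure p (kPa). Root of
#   sigma_theta(lt, lz) h0 / (lt lz) = p lt R0.
inflate_station <- function(m, R0, h0, lz, p) {
  if (p == 0 && lz == 1) return(1)
  f <- function(lt) hoop_stress(m, lt, lz) * h0 / (lt * lz) - p * lt * R0
  stats::uniroot(f, lower = 0.2, upper = 5, tol = 1e-12)$root
}

# Circumferential transmission factor of the imposed bending displacement.
# With the perivascular support loaded on its full outer circumference the
# whole ring is dragged (g = 1 everywhere). Otherwise the patch drives the
# ring through the wall's circumferential stiffness against the elastic
# foundation: k_s Lap(g) = k_f g off-patch, g = 1 on the patch, giving a
# decay with circumferential distance from the patch.
ring_transmission <- function(geometry, mask, peri_full = TRUE,
                              material = ogden_material(),
                              peri = linear_elastic_material()) {
  g <- geometry
  if (peri_full) return(matrix(1, g$n_axial, g$n_circ))
  mu0 <- initial_moduli(material)$mu0
  h0 <- g$wall_thickness * 1e-3
  k_f <- peri$E / peri$support_thickness
  out <- matrix(0, g$n_axial, g$n_circ)
  for (i in seq_len(g$n_axial)) {
    dtheta <- 2 * pi / g$n_circ
    k_s <- mu0 * h0 / (g$lumen_radius[i] * dtheta)^2
    free <- which(!mask[i, ])
    if (length(free) == 0) { out[i, ] <- 1; next }
    nb <- function(j, d) ((j - 1 + d) %% g$n_circ) + 1
    A <- matrix(0, length(free), length(free))
    b <- numeric(length(free))
    pos <- match(seq_len(g$n_circ), free)
    for (r in seq_along(free)) {
      j <- free[r]
      A[r, r] <- -2 * k_s - k_f
      for (d in c(-1, 1)) {
        jn <- nb(j, d)
        if (mask[i, jn]) b[r] <- b[r] - k_s else A[r, pos[jn]] <- A[r, pos[jn]] + k_s
      }
    }
    gi <- rep(1, g$n_circ)
    gi[free] <- solve(A, b)
    out[i, ] <- gi
  }
  out
}

#' Quasi-static equilibrium of the discretised artery wall
#'
#' Thin-walled membrane equilibrium of the tube, station ring by station
#' ring: circumferential Laplace-type balance with the Ogden tangent
#' response, an elastic-foundation reduction of the perivascular support,
#' and imposed bending displacements applied as hard constraints on the
#' inner-curvature patch nodes (which cannot distend). End planes constrain
#' axially (fixed axial stretch) while leaving radial dilation free.
#'
#' @param geometry An \code{artery_geometry}; its radius profile is the
#'   diastolic (imaged) configuration.
#' @param material An \code{ogden_material}.
#' @param peri A \code{linear_elastic_material} for the perivascular
#'   foundation, or \code{NULL} for no support.
#' @param pressure Luminal pressure per station (Pa); scalar recycled.
#' @param axial_traction Axial Cauchy traction (kPa) applied when no
#'   pre-stress reference is given; sets the axial stretch.
#' @param imposed Optional list \code{list(field = bending_field,
#'   amplitude = a)} imposing \code{a * field$vectors} on the patch nodes
#'   (the field must have been through \code{\link{assign_to_wall}}).
#' @param reference Optional pre-stress \code{wall_state} (from
#'   \code{\link{backward_incremental_prestress}}) supplying the unloaded
#'   radius and axial pre-stretch.
#' @param coupling_c Dimensionless circumferential smoothing coefficient of
#'   the ring solver (default 1).
#' @param end_condition "constrained" (axial stretch held, default) or
#'   "free".
#' @return Object of class \code{wall_state}: \code{radius}
#'   (n_axial x n_circ, mm), \code{positions} (n_axial x n_circ x 3, mm),
#'   \code{stretches} (list \code{circ} matrix, \code{axial} scalar,
#'   \code{radial} matrix), \code{log_strain} (vs the unloaded reference),
#'   \code{stress} (hoop Cauchy, kPa), \code{R0}, \code{lambda_z},
#'   \code{prestressed}.
#' @export
tube_equilibrium <- function(geometry, material, peri = linear_elastic_material(),
                             pressure = 0, axial_traction = 0, imposed = NULL,
                             reference = NULL, coupling_c = 1,
                             end_condition = c("constrained", "free")) {
  end_condition <- match.arg(end_condition)
  g <- geometry
  p_kPa <- rep(pressure, length.out = g$n_axial) / 1000    # Pa -> kPa
  h0 <- g$wall_thickness * 1e-3                            # um -> mm
  if (!is.null(reference)) {
    R0 <- reference$R0
    lz <- reference$lambda_z
  } else {
    R0 <- g$lumen_radius
    lz <- axial_stretch_for_traction(material, axial_traction)
  }
  k_f <- if (is.null(peri)) 0 else peri$E / peri$support_thickness

  pin_mask <- matrix(FALSE, g$n_axial, g$n_circ)
  amp <- 0
  if (!is.null(imposed)) {
    if (is.null(imposed$field$patch_mask))
      stop("imposed field must have been through assign_to_wall()", call. = FALSE)
    pin_mask <- imposed$field$patch_mask
    amp <- imposed$amplitude
  }

  radius <- matrix(0, g$n_axial, g$n_circ)
  for (i in seq_len(g$n_axial)) {
    if (!any(pin_mask[i, ])) {
      lt <- inflate_station_supported(material, R0[i], h0, lz, p_kPa[i],
                                      k_f, g$lumen_radius[i])
      radius[i, ] <- lt * R0[i]
    } else {
      radius[i, ] <- ring_solve(material, R0[i], h0, lz, p_kPa[i], k_f,
                                rest_radius = g$lumen_radius[i],
                                pin = pin_mask[i, ],
                                pin_radius = g$lumen_radius[i],
                                coupling_c = coupling_c)
    }
  }

  offset <- NULL
  if (!is.null(imposed)) {
    gfac <- ring_transmission(g, pin_mask,
                              peri_full = imposed$field$peri_full_circumference,
                              material = material,
                              peri = if (is.null(peri)) linear_elastic_material() else peri)
    # per-node displacement; positions use the ring-mean as centre motion and
    # per-node transmission for the node coordinates
    offset <- amp * imposed$field$vectors * rowMeans(gfac)
  }
  pos <- surface_points(g, radius = radius, center_offset = offset)

  lt_mat <- radius / R0
  lr_mat <- 1 / (lt_mat * lz)
  state <- structure(list(
    radius = radius, positions = pos,
    stretches = list(circ = lt_mat, axial = lz, radial = lr_mat),
    log_strain = list(circ = log(lt_mat), axial = log(lz) + 0 * lt_mat,
                      radial = log(lr_mat)),
    stress = matrix(hoop_stress_mat(material, lt_mat, lz), g$n_axial, g$n_circ),
    R0 = R0, lambda_z = lz, prestressed = !is.null(reference),
    geometry = g), class = "wall_state")
  state
}

hoop_stress_mat <- function(m, lt_mat, lz) {
  vals <- hoop_stress(m, as.vector(lt_mat), lz)
  matrix(vals, nrow(lt_mat), ncol(lt_mat))
}

# Axisymmetric inflation including the elastic foundation (zero foundation
# force at the rest radius).
inflate_station_supported <- function(m, R0, h0, lz, p, k_f, rest_radius) {
  if (p == 0 && lz == 1 && (k_f == 0 || rest_radius == R0)) return(1)
  f <- function(lt) {
    r <- lt * R0
    hoop_stress(m, lt, lz) * h0 / (lt * lz) - (p - k_f * (r - rest_radius)) * r
  }
  stats::uniroot(f, lower = 0.2, upper = 5, tol = 1e-12)$root
}

# Per-ring Newton solve with pinned patch nodes. Unknowns are the radii of
# the free nodes; pinned nodes sit at pin_radius. Residual (kPa) per free
# node j:
#   p - sigma_theta(r_j/R0) h_cur / r_j - k_f (r_j - rest) + Dc Lap(r)_j = 0
ring_solve <- function(m, R0, h0, lz, p, k_f, rest_radius, pin, pin_radius,
                       coupling_c = 1, tol = 1e-10, max_iter = 200,
                       r_init = NULL) {
  n <- length(pin)
  dtheta <- 2 * pi / n
  Dc <- coupling_c * initial_moduli(m)$mu0 * h0 / (R0 * dtheta)^2
  r <- if (is.null(r_init)) rep(rest_radius, n) else r_init
  r[pin] <- pin_radius
  free <- which(!pin)
  if (length(free) == 0) return(r)
  nb <- function(j, d) ((j - 1 + d) %% n) + 1
  pos <- match(seq_len(n), free)

  wall_term <- function(rj) {
    lt <- rj / R0
    hoop_stress(m, lt, lz) * h0 / (lt * lz) / rj
  }
  wall_term_d <- function(rj) {
    lt <- rj / R0
    s <- hoop_stress(m, lt, lz)
    ds <- hoop_stress_dlt(m, lt, lz)
    (ds / (lt^2 * lz) - 2 * s / (lt^3 * lz)) * h0 / R0^2
  }

  for (it in seq_len(max_iter)) {
    Fv <- numeric(length(free))
    J <- matrix(0, length(free), length(free))
    for (k in seq_along(free)) {
      j <- free[k]
      lap <- r[nb(j, -1)] - 2 * r[j] + r[nb(j, 1)]
      Fv[k] <- p - wall_term(r[j]) - k_f * (r[j] - rest_radius) + Dc * lap
      J[k, k] <- -wall_term_d(r[j]) - k_f - 2 * Dc
      for (d in c(-1, 1)) {
        jn <- nb(j, d)
        if (!pin[jn]) J[k, pos[jn]] <- J[k, pos[jn]] + Dc
      }
    }
    if (max(abs(Fv)) < tol * max(1, abs(p))) break
    step <- solve(J, -Fv)
    # damped update keeping radii positive
    sc <- 1
    while (any(r[free] + sc * step <= 0.05 * R0)) sc <- sc / 2
    r[free] <- r[free] + sc * step
    if (it == max_iter)
      stop(sprintf("ring solver did not converge; residual %.3e kPa", max(abs(Fv))),
           call. = FALSE)
  }
  r
}

#' Backward-incremental pre-stress of the imaged geometry
#'
#' The imaged (in vivo diastolic) geometry is already loaded by axial
#' stretch and diastolic pressure. The backward-incremental (BI) procedure
#' finds the unloaded reference configuration and in vivo stress state:
#' phase 1 ramps the axial traction to its peak in fixed increments (the
#' ends then stay axially constrained to maintain the axial stress); phase 2
#' ramps the pressure to the diastolic value, and after each increment the
#' computed displacement is subtracted from the reference radius so the
#' fully loaded configuration converges to the imaged geometry.
#'
#' @param geometry An \code{artery_geometry}; the in vivo (loaded)
#'   configuration.
#' @param material An \code{ogden_material}.
#' @param schedule A \code{prestress_schedule}.
#' @param tol Relative radius-recovery tolerance (default 1e-5).
#' @return A \code{wall_state} with \code{prestressed = TRUE}; its \code{R0}
#'   is the unloaded reference radius per station and \code{recovered_radius}
#'   the forward-loaded check of the fixed point.
#' @export
backward_incremental_prestress <- function(geometry, material,
                                           schedule = prestress_schedule(),
                                           tol = 1e-5) {
  g <- geometry
  h0 <- g$wall_thickness * 1e-3
  R_img <- g$lumen_radius

  # phase 1: axial traction ramp (BI on the axial stretch; the imaged length
  # is held so the reference length shrinks by 1/lz each increment)
  lz <- 1
  for (k in seq_len(schedule$axial_steps))
    lz <- axial_stretch_for_traction(
      material, schedule$axial_load_max * k / schedule$axial_steps)
  # uniaxial lateral contraction maps the reference radius to the imaged one
  R0 <- R_img * sqrt(lz)

  # phase 2: pressure ramp with ends axially constrained; BI radius update
  p_max <- mmHg_to_Pa(schedule$pressure_max) / 1000   # kPa
  if (p_max > 0) {
    inflate_all <- function(R0, p)
      vapply(seq_along(R0), function(i)
        inflate_station(material, R0[i], h0, lz, p) * R0[i], numeric(1))
    for (k in seq_len(schedule$pressure_steps)) {
      r <- inflate_all(R0, p_max * k / schedule$pressure_steps)
      R0 <- R0 - (r - R_img)
    }
    for (it in seq_len(200)) {           # polish the fixed point at full load
      r <- inflate_all(R0, p_max)
      err <- max(abs(r - R_img) / R_img)
      if (err < tol) break
      R0 <- R0 - (r - R_img)
      if (it == 200)
        stop(sprintf("BI pre-stress failed to recover the imaged geometry (err %.2e)",
                     err), call. = FALSE)
    }
    recovered <- inflate_all(R0, p_max)
  } else {
    recovered <- R0 / sqrt(lz)
  }

  lt <- R_img / R0
  lt_mat <- matrix(lt, g$n_axial, g$n_circ)
  lr_mat <- 1 / (lt_mat * lz)
  structure(list(
    radius = matrix(R_img, g$n_axial, g$n_circ),
    positions = surface_points(g),
    stretches = list(circ = lt_mat, axial = lz, radial = lr_mat),
    log_strain = list(circ = log(lt_mat), axial = log(lz) + 0 * lt_mat,
                      radial = log(lr_mat)),
    stress = hoop_stress_mat(material, lt_mat, lz),
    R0 = R0, lambda_z = lz, recovered_radius = recovered,
    prestressed = TRUE, geometry = g), class = "wall_state")
}

#' @export
print.wall_state <- function(x, ...) {
  cat(sprintf("<wall_state> %d x %d nodes, lambda_z %.3f, prestressed: %s\n",
              nrow(x$radius), ncol(x$radius), x$lambda_z, x$prestressed))
  invisible(x)
}

#' Cyclic logarithmic strain over a cardiac cycle
#'
#' Per wall node and component, the logarithmic strain relative to the
#' diastolic (pre-stressed) state at each time, summarised as the cyclic
#' value: the signed extreme (largest magnitude) over the cycle, in percent.
#' Circumferential strain uses the ring radius ratio, axial strain the
#' change of distance between axially adjacent nodes, and radial strain
#' follows from near-incompressibility of the wall.
#'
#' @param states List of \code{wall_state} objects covering one cycle.
#' @param diastolic_reference The diastolic \code{wall_state}.
#' @return List of (n_axial x n_circ) matrices \code{circ}, \code{axial},
#'   \code{radial}, in percent.
#' @export
cyclic_log_strain <- function(states, diastolic_reference) {
  ref <- diastolic_reference
  n_ax <- nrow(ref$radius); n_ci <- ncol(ref$radius)
  seg_len <- function(pos) {
    L <- array(0, c(n_ax, n_ci))
    d <- pos[2:n_ax, , , drop = FALSE] - pos[1:(n_ax - 1), , , drop = FALSE]
    L[1:(n_ax - 1), ] <- sqrt(d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2)
    L[n_ax, ] <- L[n_ax - 1, ]
    L
  }
  L_ref <- seg_len(ref$positions)
  ext <- function(cur, prev) { # keep the larger-magnitude signed value
    swap <- abs(cur) > abs(prev)
    prev[swap] <- cur[swap]
    prev
  }
  e_c <- e_a <- e_r <- matrix(0, n_ax, n_ci)
  for (st in states) {
    ec <- log(st$radius / ref$radius)
    ea <- log(seg_len(st$positions) / L_ref)
    er <- -(ec + ea)
    e_c <- ext(ec, e_c); e_a <- ext(ea, e_a); e_r <- ext(er, e_r)
  }
  list(circ = 100 * e_c, axial = 100 * e_a, radial = 100 * e_r)
}
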