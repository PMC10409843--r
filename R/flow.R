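#' Flow boundary conditions for one cardiac cycle
#'
#' @param velocity Data frame (\code{time_s}, \code{value}) of the maximum
#'   (centreline) inlet velocity (m/s); applied as a parabolic profile.
#' @param pressure Data frame (\code{time_s}, \code{value}) of the outlet
#'   pressure (mmHg).
#' @param T Cardiac period (s).
#' @return Object of class \code{flow_bc}.
#' @export
flow_boundary_conditions <- function(velocity, pressure, T) {
  stopifnot_scalar(T, "T")
  for (d in list(velocity, pressure))
    if (!all(c("time_s", "value") %in% names(d)))
      stop("waveforms need columns time_s, value", call. = FALSE)
  structure(list(velocity = velocity, pressure = pressure, T = T),
            class = "flow_bc")
}

# --- radial profile solver ---------------------------------------------------

# One implicit step (or steady solve when dt = Inf) of the axisymmetric
# axial-momentum balance on a fixed radial grid r = seq(0, R, n_r), with the
# pressure gradient G entering as a Lagrange multiplier enforcing the
# prescribed volumetric flow Q. Viscosity mu_half is evaluated at half-grid
# points. Returns list(u, G).
radial_step <- function(u_old, R, Q, model, dt, theta, mu_half) {
  n_r <- length(u_old)
  dr <- R / (n_r - 1)
  r <- seq(0, R, length.out = n_r)
  rho <- model$rho
  nu_f <- n_r - 1            # number of unknown velocities (wall node = 0)

  # implicit diffusion operator L (rows = interior nodes 1..n_r-1)
  A <- matrix(0, nu_f + 1, nu_f + 1)
  b <- numeric(nu_f + 1)
  rhalf <- r[-1] - dr / 2                     # r_{j-1/2}, j = 2..n_r
  lap_coeff <- function(j) {
    # coefficients (c_m, c_c, c_p) of Lap(u)_j
    if (j == 1) {
      c(0, -4 * mu_half[1] / dr^2, 4 * mu_half[1] / dr^2)
    } else {
      cm <- rhalf[j - 1] * mu_half[j - 1] / (r[j] * dr^2)
      cp <- rhalf[j] * mu_half[j] / (r[j] * dr^2)
      c(cm, -(cm + cp), cp)
    }
  }
  explicit <- numeric(nu_f)
  for (j in seq_len(nu_f)) {
    cf <- lap_coeff(j)
    um <- if (j > 1) u_old[j - 1] else 0
    up <- if (j < n_r) u_old[j + 1] else 0
    explicit[j] <- cf[1] * um + cf[2] * u_old[j] + cf[3] * up
  }
  steady <- !is.finite(dt)
  for (j in seq_len(nu_f)) {
    cf <- lap_coeff(j)
    tfac <- if (steady) 0 else rho / dt
    A[j, j] <- tfac - theta * cf[2]
    if (j > 1) A[j, j - 1] <- -theta * cf[1]
    if (j < nu_f) A[j, j + 1] <- -theta * cf[3]
    A[j, nu_f + 1] <- -1                     # -G
    b[j] <- (if (steady) 0 else rho / dt * u_old[j]) +
      (1 - theta) * explicit[j]
  }
  # flow constraint: 2 pi * trapz(r u) = Q  (wall velocity is zero)
  w <- rep(dr, n_r); w[c(1, n_r)] <- dr / 2
  A[nu_f + 1, seq_len(nu_f)] <- 2 * pi * (w * r)[seq_len(nu_f)]
  b[nu_f + 1] <- Q
  # row equilibration: the viscous rows and the flow-constraint row differ by
  # many orders of magnitude
  sc <- apply(abs(A), 1, max)
  sol <- solve(A / sc, b / sc)
  list(u = c(sol[seq_len(nu_f)], 0), G = sol[nu_f + 1])
}

shear_rates_half <- function(u, dr) abs(diff(u)) / dr

# Spectral derivative of a periodic signal sampled uniformly over one period,
# low-passed at a fraction of the Nyquist band. The wall-storage term dA/dt
# is a derivative of a smooth periodic signal; differentiating it spectrally
# keeps the coupling loop from amplifying grid-frequency noise.
periodic_deriv <- function(x, T, keep_frac = 0.25) {
  n <- length(x)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  if (n %% 2 == 0) k[n %/% 2 + 1] <- 0          # drop the unpaired Nyquist mode
  fac <- 2i * pi * k / T
  fac[abs(k) > keep_frac * n / 2] <- 0
  Re(stats::fft(stats::fft(x) * fac, inverse = TRUE)) / n
}

wall_shear <- function(u, dr, model) {
  n <- length(u)
  dudr <- (3 * u[n] - 4 * u[n - 1] + u[n - 2]) / (2 * dr)
  g <- abs(dudr)
  mu_w <- carreau_viscosity(model, g)
  # traction on the wall along the inward normal: positive for forward flow
  list(tau = -mu_w * dudr, mu_w = mu_w, gamma_w = g)
}

# Steady generalized-Poiseuille profile at flow Q in a tube of radius R;
# Picard iteration on the Carreau viscosity.
steady_profile <- function(R, Q, model, n_r = 33, tol = 1e-10, max_iter = 60) {
  dr <- R / (n_r - 1)
  u <- 2 * Q / (pi * R^2) * (1 - (seq(0, R, length.out = n_r) / R)^2)
  mu_half <- carreau_viscosity(model, shear_rates_half(u, dr))
  for (it in seq_len(max_iter)) {
    sol <- radial_step(u, R, Q, model, dt = Inf, theta = 1, mu_half = mu_half)
    du <- max(abs(sol$u - u)) / max(abs(sol$u), 1e-12)
    u <- sol$u
    mu_half <- carreau_viscosity(model, shear_rates_half(u, dr))
    if (du < tol) break
  }
  list(u = u, G = sol$G)
}

# --- pulsatile solver --------------------------------------------------------

#' Reduced-order pulsatile flow and wall shear stress
#'
#' Radially resolved quasi-1D solution of laminar incompressible Carreau
#' flow in a (possibly moving and distending) tapered curved tube. Per
#' axial station the unsteady axisymmetric momentum balance is integrated
#' implicitly on a radial grid with the Carreau viscosity iterated to
#' self-consistency; the station flow follows from mass conservation
#' including the wall-motion storage term; pressure is integrated backward
#' from the outlet. The base axisymmetric wall shear is modulated
#' azimuthally by a curvature (Dean) closure and by bending-velocity-induced
#' transverse shear, yielding the time-resolved wall-shear-stress vector on
#' the lumen grid. An inlet extension of 1.5 inlet diameters is prepended
#' for flow development and excluded from all outputs.
#'
#' @param geometry An \code{artery_geometry}.
#' @param bc A \code{flow_bc}.
#' @param model A \code{carreau_model}.
#' @param n_t Time steps per cycle (default 200).
#' @param n_r Radial grid points (default 33).
#' @param n_cycles Cycles integrated; the last is returned (default 3).
#' @param motion Optional wall motion: list with \code{radius}
#'   (n_axial x n_t equivalent lumen radius, mm) and optionally
#'   \code{lateral_velocity} (n_axial x n_t x 3 wall velocity, m/s).
#'   \code{NULL} = rigid wall.
#' @param theta_scheme Time-integration weight; the default 0.6 damps the
#'   undamped grid-frequency ringing of Crank-Nicolson (0.5) on stiff radial
#'   modes while staying close to second-order accuracy; 1 = implicit Euler.
#' @param dean_coeff Azimuthal modulation coefficient of axial WSS by the
#'   curvature ratio delta = R_lumen/R_curvature (default 1.5, the low-Dean
#'   inner/outer asymmetry closure; configurable, see vignette).
#' @param secondary_coeff Transverse (secondary-flow) WSS closure
#'   coefficient (default 0.5).
#' @param bending_shear_coeff Coefficient of the Stokes-layer transverse
#'   shear induced by lateral wall velocity (default 1).
#' @param keep_profiles If TRUE, store the radial velocity profiles of the
#'   returned cycle.
#' @return Object of class \code{wss_field}: \code{tau} (n_axial x n_circ x
#'   n_t x 3, Pa, global coordinates, tangent to the lumen), \code{time},
#'   \code{theta}, \code{pressure} (n_axial x n_t, Pa), \code{flow}
#'   (n_axial x n_t, m^3/s), \code{tau_axial} (base axisymmetric magnitude),
#'   \code{geometry}, and optionally \code{profiles} with \code{u}
#'   (n_axial x n_r x n_t) and radii.
#' @export
solve_pulsatile_flow <- function(geometry, bc, model, n_t = 200L, n_r = 33L,
                                 n_cycles = 3L, motion = NULL,
                                 theta_scheme = 0.6, dean_coeff = 1.5,
                                 secondary_coeff = 0.5,
                                 bending_shear_coeff = 1,
                                 keep_profiles = FALSE) {
  g <- geometry
  T <- bc$T
  tt <- T * (seq_len(n_t) - 1L) / n_t
  dt <- T / n_t
  vmax <- periodic_interp(bc$velocity$time_s, bc$velocity$value, tt, T)
  p_out <- mmHg_to_Pa(periodic_interp(bc$pressure$time_s, bc$pressure$value,
                                      tt, T))

  # station radii over the cycle (m), with inlet extension prepended
  R_body <- if (is.null(motion)) {
    matrix(g$lumen_radius, g$n_axial, n_t) * 1e-3
  } else {
    if (!all(dim(motion$radius) == c(g$n_axial, n_t)))
      stop("motion$radius must be n_axial x n_t", call. = FALSE)
    motion$radius * 1e-3
  }
  ds_body <- diff(g$centerline$arc_length) * 1e-3
  ds_mean <- mean(ds_body)
  n_ext <- max(3L, ceiling(g$inlet_extension_length * 1e-3 / ds_mean))
  R_all <- rbind(matrix(R_body[1, ], n_ext, n_t, byrow = TRUE), R_body)
  ds_all <- c(rep(g$inlet_extension_length * 1e-3 / n_ext, n_ext), ds_body)
  n_st <- nrow(R_all)
  body_idx <- (n_ext + 1L):n_st

  # mass conservation: Q(s, t) = Q_in(t) - int_0^s dA/dt ds'
  Q_in <- 0.5 * vmax * pi * R_all[1, ]^2
  A_all <- pi * R_all^2
  dAdt <- t(apply(A_all, 1, periodic_deriv, T = T))
  Q <- matrix(0, n_st, n_t)
  Q[1, ] <- Q_in
  for (i in 2:n_st)
    Q[i, ] <- Q[i - 1, ] - 0.5 * (dAdt[i, ] + dAdt[i - 1, ]) * ds_all[i - 1]

  # per-station radial time integration
  tau0 <- matrix(0, n_st, n_t)      # signed axisymmetric wall shear (Pa)
  mu_w <- matrix(0, n_st, n_t)      # wall viscosity (Pa s)
  G <- matrix(0, n_st, n_t)         # -dp/ds (Pa/m)
  profiles <- if (keep_profiles) array(0, c(n_st, n_r, n_t)) else NULL
  steady_flow <- all(abs(Q - Q[, 1]) < 1e-14 * max(abs(Q), 1e-30)) &&
    all(abs(R_all - R_all[, 1]) < 1e-14 * max(R_all))

  for (i in seq_len(n_st)) {
    if (steady_flow) {
      sol <- steady_profile(R_all[i, 1], Q[i, 1], model, n_r)
      ws <- wall_shear(sol$u, R_all[i, 1] / (n_r - 1), model)
      tau0[i, ] <- ws$tau; mu_w[i, ] <- ws$mu_w; G[i, ] <- sol$G
      if (keep_profiles) for (k in seq_len(n_t)) profiles[i, , k] <- sol$u
      next
    }
    u <- steady_profile(R_all[i, 1], Q[i, 1], model, n_r)$u
    for (cyc in seq_len(n_cycles)) {
      for (k in seq_len(n_t)) {
        R_k <- R_all[i, k]
        dr <- R_k / (n_r - 1)
        mu_half <- carreau_viscosity(model, shear_rates_half(u, dr))
        sol <- radial_step(u, R_k, Q[i, k], model, dt, theta_scheme, mu_half)
        # one Picard correction for viscosity self-consistency
        mu_half <- carreau_viscosity(model, shear_rates_half(sol$u, dr))
        sol <- radial_step(u, R_k, Q[i, k], model, dt, theta_scheme, mu_half)
        u <- sol$u
        if (cyc == n_cycles) {
          ws <- wall_shear(u, dr, model)
          tau0[i, k] <- ws$tau; mu_w[i, k] <- ws$mu_w; G[i, k] <- sol$G
          if (keep_profiles) profiles[i, , k] <- u
        }
      }
    }
  }

  # pressure integrated backward from the outlet: dp/ds = -G
  p <- matrix(0, n_st, n_t)
  p[n_st, ] <- p_out
  for (i in (n_st - 1):1)
    p[i, ] <- p[i + 1, ] + 0.5 * (G[i, ] + G[i + 1, ]) * ds_all[i]

  # azimuthal closure on the body stations
  kappa <- row_norms(centerline_curvature(g$centerline))      # 1/mm
  delta <- g$lumen_radius * kappa                              # R/R_curv
  ct <- cos(g$theta); st <- sin(g$theta)
  omega <- 2 * pi / T
  tau <- array(0, c(g$n_axial, g$n_circ, n_t, 3))
  es <- g$frame$tangent
  for (ii in seq_along(body_idx)) {
    i <- body_idx[ii]
    R_i <- R_all[i, ]
    ubar <- Q[i, ] / (pi * R_i^2)
    Re <- model$rho * abs(ubar) * 2 * R_i / pmax(mu_w[i, ], 1e-9)
    De <- Re * sqrt(max(delta[ii], 0))
    az <- pmax(1 - dean_coeff * delta[ii] * outer(ct, rep(1, n_t)), 0.05)
    tau_ax <- sweep(az, 2, tau0[i, ], "*")                    # n_circ x n_t
    tau_tr <- secondary_coeff * delta[ii] *
      outer(st, tau0[i, ] * tanh(De / 50))
    e_th <- outer(-st, g$frame$normal[ii, ]) + outer(ct, g$frame$binormal[ii, ])
    n_hat <- outer(ct, g$frame$normal[ii, ]) + outer(st, g$frame$binormal[ii, ])
    for (kk in 1:3) {
      tau[ii, , , kk] <- outer(rep(es[ii, kk], g$n_circ), rep(1, n_t)) * tau_ax +
        e_th[, kk] * tau_tr
    }
    if (!is.null(motion) && !is.null(motion$lateral_velocity)) {
      v <- motion$lateral_velocity[ii, , ]                    # n_t x 3
      stokes <- bending_shear_coeff * sqrt(model$rho * mu_w[i, ] * omega)
      for (j in seq_len(g$n_circ)) {
        vn <- v %*% n_hat[j, ]                                # n_t x 1
        vt <- v - tcrossprod(as.vector(vn), n_hat[j, ])       # tangential
        for (kk in 1:3)
          tau[ii, j, , kk] <- tau[ii, j, , kk] - stokes * vt[, kk]
      }
    }
  }

  structure(list(
    tau = tau, time = tt, theta = g$theta,
    tau_axial = tau0[body_idx, , drop = FALSE],
    pressure = p[body_idx, , drop = FALSE],
    flow = Q[body_idx, , drop = FALSE],
    wall_viscosity = mu_w[body_idx, , drop = FALSE],
    geometry = g, n_ext = n_ext,
    profiles = if (keep_profiles)
      list(u = profiles[body_idx, , , drop = FALSE],
           radius = R_body) else NULL
  ), class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat(sprintf("<wss_field> %d stations x %d circ x %d time steps, |tau| median %.3f Pa\n",
              dim(x$tau)[1], dim(x$tau)[2], dim(x$tau)[3],
              stats::median(sqrt(x$tau[, , , 1]^2 + x$tau[, , , 2]^2 +
                                   x$tau[, , , 3]^2))))
  invisible(x)
}

#' Rigid-wall flow solve (CFD-equivalent arm)
#'
#' Identical solver with wall motion and distension disabled: the
#' rigid-wall computational-fluid-dynamics arm of the three-way comparison.
#'
#' @inheritParams solve_pulsatile_flow
#' @return A \code{wss_field}.
#' @export
rigid_wall_mode <- function(geometry, bc, model, n_t = 200L, n_r = 33L,
                            n_cycles = 3L, ...) {
  solve_pulsatile_flow(geometry, bc, model, n_t = n_t, n_r = n_r,
                       n_cycles = n_cycles, motion = NULL, ...)
}
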