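# Shared fixtures and independent oracles, built in code at test time.

straight_centerline <- function(L = 40, n = 21)
  centerline(cbind(seq(0, L, length.out = n), 0, 0))

semicircle_centerline <- function(R = 20, n = 101) {
  th <- seq(0, pi, length.out = n)
  centerline(cbind(R * cos(th), R * sin(th), 0))
}

# downscaled LAD-like test case shared by pipeline and acceptance tests
small_lad_case <- function(n_axial = 25, n_circ = 24, n_t = 96, seed = 1) {
  p <- make_artery_preset("lad", seed = seed)
  wf <- make_waveforms(p$waveforms, n_t = 120)
  bc <- flow_boundary_conditions(wf$velocity, wf$pressure, T = p$waveforms$T)
  cl <- resample_centerline(p$geometry$centerline, n_axial)
  s_full <- p$geometry$centerline$arc_length /
    total_length(p$geometry$centerline)
  rad <- stats::approx(s_full, p$geometry$lumen_radius,
                       cl$arc_length / total_length(cl))$y
  g <- build_tube(cl, rad, p$geometry$wall_thickness, n_circ)
  pair <- make_centerline_pair(cl, p$motion)
  list(geometry = g, bc = bc, pair = pair, preset = p, n_t = n_t)
}

# complex-argument Bessel functions by power series (|z| < ~10), used only
# as the analytic Womersley oracle
bessel_J0_c <- function(z) {
  s <- 1 + 0i; term <- 1 + 0i
  for (k in 1:40) { term <- term * (-z^2 / 4) / k^2; s <- s + term }
  s
}
bessel_J1_c <- function(z) {
  s <- 1 + 0i; term <- 1 + 0i
  for (k in 1:40) { term <- term * (-z^2 / 4) / (k * (k + 1)); s <- s + term }
  z / 2 * s
}

# analytic Womersley solution for pressure-gradient amplitude G0 cos(wt):
# returns u(r, t) on the given grids and the flow waveform Q(t)
womersley_analytic <- function(mu, rho, R, alpha, G0, rr, tt) {
  omega <- alpha^2 * mu / (rho * R^2)
  beta <- complex(modulus = alpha, argument = 3 * pi / 4)
  coef <- 1i * G0 / (rho * omega)
  u <- sapply(tt, function(t)
    Re(coef * (1 - bessel_J0_c(beta * rr / R) / bessel_J0_c(beta)) *
         exp(1i * omega * t)))
  Q <- Re(coef * pi * R^2 *
            (1 - 2 * bessel_J1_c(beta) / (beta * bessel_J0_c(beta))) *
            exp(1i * omega * tt))
  list(u = u, Q = Q, omega = omega, T = 2 * pi / omega)
}

# build a wss_field from an explicit tau array on a given tube geometry
synthetic_wss <- function(geometry, tau, T = 1) {
  n_t <- dim(tau)[3]
  structure(list(tau = tau, theta = geometry$theta,
                 time = T * (seq_len(n_t) - 1) / n_t, geometry = geometry),
            class = "wss_field")
}

steady_bc <- function(vmax = 0.3, p_mmHg = 90, T = 1)
  flow_boundary_conditions(data.frame(time_s = c(0, T / 2), value = vmax),
                           data.frame(time_s = c(0, T / 2), value = p_mmHg),
                           T = T)
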