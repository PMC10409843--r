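test_that("Carreau viscosity attains its plateaus and is shear-thinning", {
  m <- carreau_model()
  expect_equal(carreau_viscosity(m, 0), m$mu_0, tolerance = 1e-15)
  expect_equal(carreau_viscosity(m, 1e12), m$mu_inf, tolerance = 1e-6)
  expect_equal(carreau_viscosity(m, 1 / m$lambda_t),
               m$mu_inf + (m$mu_0 - m$mu_inf) * 2^((m$n - 1) / 2),
               tolerance = 1e-12)
  g <- 10^seq(-3, 6, length.out = 200)
  mu <- carreau_viscosity(m, g)
  expect_true(all(diff(mu) <= 0))
  expect_true(all(mu >= m$mu_inf & mu <= m$mu_0))
  expect_error(carreau_viscosity(m, -1), ">= 0")
  expect_error(carreau_model(mu_0 = 0.001, mu_inf = 0.003), "mu_0 > mu_inf")
})

test_that("steady Newtonian flow in a straight tube reproduces Poiseuille shear", {
  g <- build_tube(straight_centerline(40, 21), 1.5, 200, 16)
  mu <- 0.0035
  w <- rigid_wall_mode(g, steady_bc(vmax = 0.3), newtonian_model(mu),
                       n_t = 8, n_r = 33)
  R <- 1.5e-3
  tau_ref <- 4 * mu * (0.5 * 0.3 * pi * R^2) / (pi * R^3)
  expect_lt(max(abs(w$tau_axial - tau_ref)) / tau_ref, 0.01)
  expect_equal(unname(tawss(w)$values[3, 5]), w$tau_axial[3, 1],
               tolerance = 1e-12)
})

test_that("zero inflow in a rigid straight tube gives zero shear and uniform pressure", {
  g <- build_tube(straight_centerline(40, 11), 1.5, 200, 8)
  w <- rigid_wall_mode(g, steady_bc(vmax = 0), newtonian_model(), n_t = 8)
  expect_equal(max(abs(w$tau)), 0)
  expect_equal(max(abs(w$pressure - mmHg_to_Pa(90))), 0, tolerance = 1e-9)
})

test_that("oscillatory Newtonian flow matches the analytic Womersley profile", {
  mu <- 0.0035; rho <- 1050; R <- 1.5e-3; alpha <- 3
  n_t <- 200L; n_r <- 33L
  rr <- seq(0, R, length.out = n_r)
  ana <- womersley_analytic(mu, rho, R, alpha, G0 = 500, rr = rr,
                            tt = numeric(0))
  tt <- ana$T * (seq_len(n_t) - 1) / n_t
  ana <- womersley_analytic(mu, rho, R, alpha, G0 = 500, rr = rr, tt = tt)
  bc <- flow_boundary_conditions(
    data.frame(time_s = tt, value = 2 * ana$Q / (pi * R^2)),
    data.frame(time_s = tt, value = rep(90, n_t)), T = ana$T)
  g <- build_tube(straight_centerline(40, 11), 1.5, 200, 8)
  w <- solve_pulsatile_flow(g, bc, newtonian_model(mu), n_t = n_t, n_r = n_r,
                            n_cycles = 3, keep_profiles = TRUE)
  u_num <- w$profiles$u[6, , ]
  err <- sqrt(sum((u_num - ana$u)^2) / sum(ana$u^2))
  expect_lt(err, 0.02)
})

test_that("steady flow accelerates along a tapering tube", {
  g <- build_tube(straight_centerline(40, 21),
                  seq(1.7, 1.0, length.out = 21), 200, 8)
  w <- solve_pulsatile_flow(g, steady_bc(), newtonian_model(), n_t = 8,
                            keep_profiles = TRUE)
  expect_true(all(diff(w$profiles$u[, 1, 1]) > 0))
  # and the pressure falls monotonically downstream
  expect_true(all(diff(w$pressure[, 1]) < 0))
})

test_that("mass conservation holds with a moving wall", {
  cs <- small_lad_case(n_axial = 15, n_circ = 8)
  g <- cs$geometry
  n_t <- 64
  tt <- (seq_len(n_t) - 1) / n_t
  radius <- outer(g$lumen_radius, 1 + 0.03 * sin(2 * pi * tt))
  w <- solve_pulsatile_flow(g, cs$bc, carreau_model(), n_t = n_t, n_r = 17,
                            n_cycles = 2, motion = list(radius = radius))
  # dA/dt + dQ/ds = 0 per station and time step (storage form)
  A <- pi * (radius * 1e-3)^2
  dAdt <- t(apply(A, 1, corofsi:::periodic_deriv, T = cs$bc$T))
  ds <- diff(g$centerline$arc_length) * 1e-3
  for (i in 2:g$n_axial) {
    lhs <- (w$flow[i, ] - w$flow[i - 1, ]) / ds[i - 1]
    rhs <- -0.5 * (dAdt[i, ] + dAdt[i - 1, ])
    expect_lt(max(abs(lhs - rhs)) / max(abs(w$flow) / sum(ds)), 1e-6)
  }
})

test_that("WSS vectors are tangent to the lumen surface everywhere", {
  cs <- small_lad_case(n_axial = 12, n_circ = 12)
  w <- solve_pulsatile_flow(cs$geometry, cs$bc, carreau_model(), n_t = 24,
                            n_r = 17, n_cycles = 2)
  g <- cs$geometry
  worst <- 0
  for (i in seq_len(g$n_axial)) for (j in seq_len(g$n_circ)) {
    nh <- cos(g$theta[j]) * g$frame$normal[i, ] +
      sin(g$theta[j]) * g$frame$binormal[i, ]
    tv <- w$tau[i, j, , ]
    num <- abs(tv %*% nh)
    den <- sqrt(rowSums(tv^2))
    worst <- max(worst, max(num / pmax(den, 1e-30)))
  }
  expect_lt(worst, 1e-10)
})

test_that("the curvature closure vanishes in the straight-tube limit", {
  g <- build_tube(straight_centerline(40, 11), 1.5, 200, 16)
  w <- rigid_wall_mode(g, steady_bc(), carreau_model(), n_t = 8)
  # straight rigid tube: no transverse component, no azimuthal variation
  eth_mag <- apply(w$tau, c(1, 3), function(v) diff(range(sqrt(rowSums(v^2)))))
  expect_lt(max(eth_mag), 1e-12)
  expect_equal(max(abs(tss(w)$values)), 0, tolerance = 1e-12)
  # curved tube: outer wall carries more shear than inner wall
  gc <- build_tube(semicircle_centerline(20, 21), 1.5, 200, 16)
  wc <- rigid_wall_mode(gc, steady_bc(), carreau_model(), n_t = 8)
  tw <- tawss(wc)$values
  expect_true(all(tw[, 9] > tw[, 1]))   # theta = pi vs theta = 0
})

test_that("rigid-wall mode equals the general solver on a constant geometry", {
  cs <- small_lad_case(n_axial = 10, n_circ = 8)
  n_t <- 32
  w1 <- rigid_wall_mode(cs$geometry, cs$bc, carreau_model(), n_t = n_t,
                        n_r = 17, n_cycles = 2)
  radius <- matrix(cs$geometry$lumen_radius, cs$geometry$n_axial, n_t)
  w2 <- solve_pulsatile_flow(cs$geometry, cs$bc, carreau_model(), n_t = n_t,
                             n_r = 17, n_cycles = 2,
                             motion = list(radius = radius))
  expect_equal(w2$tau, w1$tau, tolerance = 1e-9)
  expect_equal(w2$pressure, w1$pressure, tolerance = 1e-9)
})

test_that("viscosity bounds hold at the wall throughout a pulsatile solve", {
  cs <- small_lad_case(n_axial = 10, n_circ = 8)
  m <- carreau_model()
  w <- solve_pulsatile_flow(cs$geometry, cs$bc, m, n_t = 32, n_r = 17,
                            n_cycles = 2)
  expect_true(all(w$wall_viscosity >= m$mu_inf & w$wall_viscosity <= m$mu_0))
})
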