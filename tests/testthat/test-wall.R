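test_that("strain energy vanishes at identity and reduces to neo-Hooke", {
  m <- ogden_material()
  expect_equal(strain_energy(m, 1, 1, 1), 0)
  nh <- ogden_material(mu = 5, alpha = 2, D1 = 1e-3)
  l <- c(1.3, 0.9, 1 / (1.3 * 0.9))
  expect_equal(strain_energy(nh, l[1], l[2], l[3]),
               5 / 2 * (sum(l^2) - 3), tolerance = 1e-12)
  expect_error(strain_energy(m, -1, 1, 1), "positive")
})

test_that("strain energy and uniaxial stress match the symbolic evaluation", {
  # frozen from an exact symbolic evaluation of the three-term sum with the
  # porcine coronary coefficients at incompressible uniaxial lambda = 1.2
  m <- ogden_material()
  l <- 1.2
  expect_equal(strain_energy(m, l, 1 / sqrt(l), 1 / sqrt(l)),
               1.2954734980151296, tolerance = 1e-10)
  expect_equal(uniaxial_stress(m, l), 16.432661445575078, tolerance = 1e-10)
  expect_equal(uniaxial_stress(m, 1), 0)
})

test_that("strain energy is invariant under stretch permutations", {
  m <- ogden_material()
  l <- c(1.25, 0.85, 1.1)
  w <- strain_energy(m, l[1], l[2], l[3])
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(strain_energy(m, l[p[1]], l[p[2]], l[p[3]]), w)
})

test_that("the near-zero exponent term tends to 3 mu log(lambda)", {
  # alpha2 = 3e-4 is near-degenerate; the series branch must agree with the
  # analytic small-exponent limit and with direct evaluation above threshold
  lam <- c(0.8, 1.2, 1.5)
  m_small <- ogden_material(mu = 10, alpha = 1e-6, D1 = 1e-3)
  expect_equal(uniaxial_stress(m_small, lam), 3 * 10 * log(lam),
               tolerance = 1e-6)
  s_series <- uniaxial_stress(ogden_material(mu = 10, alpha = 0.009,
                                             D1 = 1e-3), lam)
  s_direct <- 2 * 10 / 0.009 * (lam^0.009 - lam^(-0.009 / 2))
  expect_equal(s_series, s_direct, tolerance = 1e-7)
})

test_that("uniaxial stress is strictly increasing for the coronary wall coefficients", {
  m <- ogden_material()
  lam <- seq(0.5, 2, length.out = 400)
  expect_true(all(diff(uniaxial_stress(m, lam)) > 0))
})

test_that("stress operator is the stretch-derivative of the energy", {
  m <- ogden_material()
  for (l in c(0.8, 1.05, 1.4)) {
    h <- 1e-6
    w_fun <- function(x) strain_energy(m, x, 1 / sqrt(x), 1 / sqrt(x))
    dW <- (w_fun(l + h) - w_fun(l - h)) / (2 * h)
    # incompressible uniaxial: dW/dlambda is the nominal stress sigma/lambda
    expect_equal(dW, uniaxial_stress(m, l, nominal = TRUE),
                 tolerance = 1e-6 * max(1, abs(dW)))
  }
})

test_that("initial moduli reproduce the printed elastic constants", {
  im <- initial_moduli(ogden_material())
  expect_equal(round(im$nu, 3), 0.495)
  expect_lt(abs(im$K0 / im$mu0 - 100) / 100, 1e-3)
  inc <- initial_moduli(ogden_material(D1 = 0))
  expect_identical(inc$nu, 0.5)
  expect_true(inc$incompressible)
})

test_that("hoop stress series branch agrees with direct evaluation", {
  lt <- c(0.9, 1.1, 1.3); lz <- 1.35
  direct <- function(mu, a) 2 * mu / a * (lt^a - (lt * lz)^(-a))
  s <- hoop_stress(ogden_material(mu = 8, alpha = 0.009, D1 = 1e-3), lt, lz)
  expect_equal(s, direct(8, 0.009), tolerance = 1e-7)
  s2 <- hoop_stress(ogden_material(mu = 8, alpha = 1e-7, D1 = 1e-3), lt, lz)
  expect_equal(s2, 2 * 8 * (2 * log(lt) + log(lz)), tolerance = 1e-6)
})

test_that("unloaded tube equilibrium leaves geometry and stress at zero", {
  g <- build_tube(straight_centerline(40, 11), 1.5, 250, 16)
  st <- tube_equilibrium(g, ogden_material(), pressure = 0)
  expect_equal(st$radius, matrix(1.5, 11, 16), tolerance = 1e-12)
  expect_equal(max(abs(st$stress)), 0, tolerance = 1e-10)
  expect_equal(st$positions, surface_points(g), tolerance = 1e-12)
})

test_that("small-pressure inflation reproduces the Laplace thin-wall stress", {
  R <- 1.5; h_um <- 200
  g <- build_tube(straight_centerline(40, 11), R, h_um, 16)
  p <- 100   # Pa: gives < 1% strain for this wall
  st <- tube_equilibrium(g, ogden_material(), peri = NULL, pressure = p)
  sigma <- st$stress[1, 1] * 1000                   # kPa -> Pa
  expect_lt(abs(sigma - p * R / (h_um * 1e-3)) / (p * R / (h_um * 1e-3)), 0.02)
  # strain is small and uniform along an axially uniform tube
  expect_lt(max(st$stretches$circ) - 1, 0.01)
  expect_lt(diff(range(st$radius)), 1e-12)
})

test_that("imposed patch displacements are honoured and decay off-patch", {
  g <- build_tube(straight_centerline(40, 11), 1.5, 200, 24)
  sys <- centerline(sweep(g$centerline$points, 2, c(0, 0.5, 0), "+"))
  f <- compute_bending_vectors(g$centerline, sys, 11)
  f$peri_full_circumference <- FALSE
  f <- assign_to_wall(f, g, 0.3)
  st <- tube_equilibrium(g, ogden_material(), peri = NULL, pressure = 0,
                         imposed = list(field = f, amplitude = 1))
  # patch nodes keep the imposed (diastolic-relative) radius exactly
  expect_equal(unname(st$radius[5, f$patch_mask[5, ]]), rep(1.5, 7),
               tolerance = 1e-12)
  # the translation transmission factor decays with distance from the patch
  gt <- corofsi:::ring_transmission(g, f$patch_mask, peri_full = FALSE)
  off <- which(!f$patch_mask[1, ])
  dist <- abs(((g$theta[off] + pi) %% (2 * pi)) - pi)
  expect_true(all(gt[1, f$patch_mask[1, ]] == 1))
  expect_lt(cor(dist, gt[1, off]), -0.8)
  # with the full-circumference perivascular loading the ring moves rigidly
  expect_true(all(corofsi:::ring_transmission(g, f$patch_mask) == 1))
})

test_that("backward-incremental pre-stress is the identity for zero loads", {
  g <- build_tube(straight_centerline(40, 11), 1.5, 250, 16)
  st <- backward_incremental_prestress(
    g, ogden_material(),
    prestress_schedule(axial_load_max = 0, pressure_max = 0))
  expect_equal(st$lambda_z, 1)
  expect_equal(st$R0, rep(1.5, 11), tolerance = 1e-12)
  expect_equal(max(abs(st$stress)), 0, tolerance = 1e-10)
})

test_that("full BI schedule recovers the imaged lumen radius at every station", {
  g <- build_tube(straight_centerline(40, 21),
                  seq(1.7, 1.0, length.out = 21), 250, 16)
  st <- backward_incremental_prestress(g, ogden_material())
  expect_true(st$prestressed)
  expect_lt(max(abs(st$recovered_radius - g$lumen_radius) / g$lumen_radius),
            1e-3)
  # the unloaded reference is smaller than the pressurised imaged state
  expect_true(all(st$R0 < g$lumen_radius))
  expect_gt(st$lambda_z, 1)
  # diastolic wall stress is tensile
  expect_true(all(st$stress > 0))
})

test_that("cyclic logarithmic strain matches closed forms", {
  g <- build_tube(straight_centerline(40, 11), 1.5, 250, 16)
  ref <- list(radius = matrix(1.5, 11, 16), positions = surface_points(g))
  # no motion: zero strain
  s0 <- cyclic_log_strain(list(ref, ref), ref)
  expect_equal(max(abs(unlist(s0))), 0)
  # uniform 5.2% dilation: circumferential strain ln(1.052), radial opposes
  r2 <- matrix(1.5 * 1.052, 11, 16)
  sys <- list(radius = r2, positions = surface_points(g, radius = r2))
  s <- cyclic_log_strain(list(ref, sys), ref)
  expect_equal(as.vector(s$circ), rep(100 * log(1.052), 11 * 16),
               tolerance = 1e-9)
  expect_equal(s$radial, -(s$circ + s$axial), tolerance = 1e-12)
  # fixed length: radial strain = -circumferential (incompressible wall)
  expect_equal(as.vector(s$radial), rep(-100 * log(1.052), 11 * 16),
               tolerance = 1e-6)
})
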