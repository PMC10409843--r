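make_tube_for_metrics <- function(n_ax = 5, n_circ = 8)
  build_tube(straight_centerline(20, max(3, n_ax)), 1.5, 200, n_circ)

test_that("TAWSS reproduces constant and sinusoidal closed forms", {
  g <- make_tube_for_metrics()
  n_t <- 200
  tau <- array(0, c(5, 8, n_t, 3))
  tau[, , , 2] <- 1.4
  expect_equal(as.vector(tawss(synthetic_wss(g, tau))$values),
               rep(1.4, 40), tolerance = 1e-12)
  tau2 <- array(0, c(5, 8, n_t, 3))
  tau2[, , , 1] <- rep(sin(2 * pi * (0:(n_t - 1)) / n_t), each = 40)
  # dense-quadrature oracle for mean |sin|
  dense <- mean(abs(sin(2 * pi * (0:999999) / 1e6)))
  expect_equal(tawss(synthetic_wss(g, tau2))$values[1, 1], dense,
               tolerance = 1e-3)
  expect_equal(dense, 2 / pi, tolerance = 1e-6)
})

test_that("TAWSS at the default sampling matches a refined-grid oracle", {
  g <- make_tube_for_metrics(3, 4)
  f <- function(t) 1.2 + 0.8 * sin(2 * pi * t) + 0.3 * cos(6 * pi * t)
  build <- function(n_t) {
    tau <- array(0, c(3, 4, n_t, 3))
    tau[, , , 1] <- rep(f((0:(n_t - 1)) / n_t), each = 12)
    tawss(synthetic_wss(g, tau))$values[1, 1]
  }
  expect_lt(abs(build(200) - build(20000)) / build(20000), 1e-3)
})

test_that("OSI hits its analytic extremes and bounds", {
  g <- make_tube_for_metrics()
  n_t <- 128
  uni <- array(0, c(5, 8, n_t, 3))
  uni[, , , 1] <- rep(1 + 0.5 * sin(2 * pi * (0:(n_t - 1)) / n_t), each = 40)
  expect_equal(max(abs(osi(synthetic_wss(g, uni))$values)), 0)
  rev <- array(0, c(5, 8, n_t, 3))
  rev[, , , 1] <- rep(sin(2 * pi * (0:(n_t - 1)) / n_t), each = 40)
  expect_equal(as.vector(osi(synthetic_wss(g, rev))$values), rep(0.5, 40))
  # rotating constant-magnitude shear: vector integral vanishes
  rot <- array(0, c(5, 8, n_t, 3))
  ph <- 2 * pi * (0:(n_t - 1)) / n_t
  for (k in seq_len(n_t)) {
    rot[, , k, 1] <- cos(ph[k]); rot[, , k, 2] <- sin(ph[k])
  }
  expect_equal(as.vector(osi(synthetic_wss(g, rot))$values), rep(0.5, 40),
               tolerance = 1e-12)
  # zero field is defined as 0
  expect_equal(max(abs(osi(synthetic_wss(g, array(0, c(5, 8, 16, 3))))$values)), 0)
})

test_that("OSI and tSS satisfy their bounds on random smooth fields", {
  g <- make_tube_for_metrics()
  set.seed(42)
  n_t <- 64
  ph <- 2 * pi * (0:(n_t - 1)) / n_t
  for (rep_i in 1:20) {
    tau <- array(0, c(5, 8, n_t, 3))
    for (k in 1:3) {
      a <- rnorm(3, sd = c(1, 0.5, 0.2))
      tau[, , , k] <- rep(a[1] + a[2] * sin(ph) + a[3] * cos(2 * ph),
                          each = 40) * runif(1)
    }
    w <- synthetic_wss(g, tau)
    o <- osi(w)$values; t1 <- tss(w)$values; tw <- tawss(w)$values
    expect_true(all(o >= 0 & o <= 0.5))
    expect_true(all(t1 >= 0))
    expect_true(all(t1 <= tw + 1e-12))
  }
})

test_that("tSS separates parallel from rotating shear histories", {
  g <- make_tube_for_metrics()
  n_t <- 256
  # always parallel to its mean direction -> zero
  par <- array(0, c(5, 8, n_t, 3))
  par[, , , 1] <- rep(1 + 0.9 * sin(2 * pi * (0:(n_t - 1)) / n_t), each = 40)
  expect_equal(max(abs(tss(synthetic_wss(g, par))$values)), 0,
               tolerance = 1e-12)
  # shear rotating in each node's tangent plane, with non-uniform angular
  # speed so the cycle-mean vector is non-degenerate; oracle is a dense
  # independent quadrature of the unsigned perpendicular component
  tau0 <- 0.7
  ph <- 2 * pi * (0:(n_t - 1)) / n_t
  tangent_field <- function(ang_fun) {
    tau <- array(0, c(5, 8, n_t, 3))
    for (i in 1:5) for (j in 1:8) {
      es <- g$frame$tangent[i, ]
      eth <- -sin(g$theta[j]) * g$frame$normal[i, ] +
        cos(g$theta[j]) * g$frame$binormal[i, ]
      a <- ang_fun(ph)
      for (k in seq_len(n_t))
        tau[i, j, k, ] <- tau0 * (cos(a[k]) * es + sin(a[k]) * eth)
    }
    tau
  }
  tss_oracle <- function(ang_fun) {
    phd <- 2 * pi * (0:999999) / 1e6
    a <- ang_fun(phd)
    m <- c(mean(tau0 * cos(a)), mean(tau0 * sin(a)))
    mh <- m / sqrt(sum(m^2))
    mean(abs(tau0 * (-mh[2] * cos(a) + mh[1] * sin(a))))
  }
  swirl <- function(p) p + 0.4 * sin(p)       # full non-uniform rotation
  wobble <- function(p) 0.3 * sin(p)          # small symmetric oscillation
  for (fn in list(swirl, wobble)) {
    vals <- tss(synthetic_wss(g, tangent_field(fn)))$values
    expect_equal(as.vector(vals), rep(tss_oracle(fn), 40), tolerance = 1e-3)
  }
})

test_that("shear metrics are invariant under rigid rotations of the frame", {
  cs <- small_lad_case(n_axial = 8, n_circ = 8)
  w <- solve_pulsatile_flow(cs$geometry, cs$bc, carreau_model(), n_t = 16,
                            n_r = 17, n_cycles = 2)
  th <- 0.7; ax <- c(1, 2, 3) / sqrt(14)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  Rm <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  wr <- w
  d <- dim(w$tau)
  taur <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    taur[i, j, , ] <- w$tau[i, j, , ] %*% t(Rm)
  wr$tau <- taur
  gr <- w$geometry
  for (f in names(gr$frame)) gr$frame[[f]] <- gr$frame[[f]] %*% t(Rm)
  wr$geometry <- gr
  expect_lt(max(abs(tawss(wr)$values - tawss(w)$values)), 1e-12)
  expect_lt(max(abs(osi(wr)$values - osi(w)$values)), 1e-9)
  expect_lt(max(abs(tss(wr)$values - tss(w)$values)), 1e-9)
})

test_that("summary statistics follow the linear-interpolation quantile rule", {
  cm <- metric_map(matrix(3.3, 4, 5), "TAWSS", "Pa")
  expect_equal(unlist(cm$summary), c(median = 3.3, q1 = 3.3, q3 = 3.3,
                                     min = 3.3, max = 3.3))
  s <- summarize(matrix(1:100, 10, 10))
  expect_equal(s$median, 50.5)
  expect_equal(s$q1, 25.75)
  expect_equal(s$q3, 75.25)
  # one extreme value moves the extremes but barely the median
  s2 <- summarize(c(1:100, 1e6))
  expect_equal(s2$max, 1e6)
  expect_equal(s2$median, 51)
})

test_that("distribution comparisons follow the rank tests with Bonferroni", {
  set.seed(7)
  a <- matrix(rnorm(100), 10)
  # identical groups: H ~ 0, corrected p = 1
  same <- compare_distributions(list(x = a, y = a))
  expect_lt(same$kruskal$H, 1e-8)
  expect_equal(same$kruskal$p, 1)
  # a large shift at n = 100 is significant after correction
  shift <- compare_distributions(list(x = a, y = a + 5))
  expect_lt(shift$kruskal$p, 0.05)
  expect_lt(shift$pairwise$p, 0.05)
  # Bonferroni rule: corrected = min(1, raw * n_comparisons)
  three <- compare_distributions(list(x = a, y = a + 0.1, z = a + 5))
  expect_equal(three$n_comparisons, 3)
  expect_equal(three$pairwise$p, pmin(1, three$pairwise$p_raw * 3))
  # paired signed-rank branch
  paired <- compare_distributions(list(x = a, y = a + 1), paired = TRUE)
  expect_lt(paired$pairwise$p, 0.05)
  expect_equal(compare_distributions(list(x = a, y = a),
                                     paired = TRUE)$pairwise$p, 1)
  expect_error(compare_distributions(list(a)), "at least 2")
})

test_that("flattening is a lossless re-indexing with the documented layout", {
  m <- metric_map(matrix(seq_len(21 * 8), 21, 8), "OSI", "")
  fm <- flatten_map(m)
  expect_equal(dim(fm), c(8, 21))
  expect_equal(unname(fm[, 1]), unname(m$values[1, ]))   # proximal column
  expect_equal(t(unclass(fm))[, ], m$values[, ])         # round trip
  # cut-line adjacency: first and last rows are circumferential neighbours
  th <- attr(fm, "theta")
  expect_equal(th[1], 0)
  expect_equal(diff(th)[1], th[2] - th[1])
  expect_equal((th[8] + diff(th)[1]) %% (2 * pi), 0)
})
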