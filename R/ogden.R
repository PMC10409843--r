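#' Ogden hyperelastic material for the artery wall
#'
#' Three-term isotropic Ogden strain-energy model in principal deviatoric
#' stretches, W = sum_i (2 mu_i / alpha_i^2)(l1^a_i + l2^a_i + l3^a_i - 3),
#' with near-incompressibility handled through the volumetric parameter D1
#' (initial bulk modulus K0 = 2/D1). The defaults are the porcine coronary
#' wall coefficients obtained from inflation-test regression.
#'
#' @param mu Shear-like moduli per term (kPa).
#' @param alpha Dimensionless exponents per term.
#' @param D1 Compressibility parameter (1/kPa); K0 = 2/D1.
#' @return Object of class \code{ogden_material}.
#' @examples
#' m <- ogden_material()
#' initial_moduli(m)
#' @export
ogden_material <- function(mu = c(6.8991, 10.0284, 3.9691),
                           alpha = c(8.5782, 0.0003, 8.5782),
                           D1 = 9.57e-4) {
  if (length(mu) != length(alpha))
    stop("mu and alpha must have equal length", call. = FALSE)
  if (sum(mu) <= 0) stop("initial shear modulus sum(mu) must be positive",
                         call. = FALSE)
  if (D1 < 0) stop("D1 must be >= 0", call. = FALSE)
  structure(list(mu = mu, alpha = alpha, D1 = D1, N = length(mu)),
            class = "ogden_material")
}

#' Linear elastic material (perivascular support)
#'
#' @param E Young's modulus (kPa); default 10 kPa, soft enough not to
#'   restrict artery wall expansion.
#' @param nu Poisson's ratio; default 0.05 (nearly uncoupled).
#' @param support_thickness Equivalent thickness of the surrounding tissue
#'   layer used to reduce the 3D support to an elastic foundation (mm).
#' @return Object of class \code{linear_elastic_material}.
#' @export
linear_elastic_material <- function(E = 10, nu = 0.05, support_thickness = 2) {
  stopifnot_scalar(E, "E")
  if (nu <= -1 || nu >= 0.5) stop("nu must be in (-1, 0.5)", call. = FALSE)
  structure(list(E = E, nu = nu, support_thickness = support_thickness),
            class = "linear_elastic_material")
}

# Per-term helper: (l^a - 1)/a^2 summed over stretches, with a series branch
# for |alpha| < 1e-2 where direct evaluation loses precision (alpha2 = 3e-4
# is near-degenerate). Series in L = log(l): (l^a-1)/a^2 =
# L/a + L^2/2 + a L^3/6 + a^2 L^4/24.
ogden_term_sum <- function(alpha, L) {
  if (abs(alpha) < 1e-2) {
    sum(L) / alpha + sum(L^2) / 2 + alpha * sum(L^3) / 6 +
      alpha^2 * sum(L^4) / 24
  } else {
    sum(expm1(alpha * L)) / alpha^2
  }
}

#' Ogden strain-energy density
#'
#' Deviatoric strain energy W(l1, l2, l3) in kPa; the volumetric response is
#' carried separately by D1 and is not included here.
#'
#' @param m An \code{ogden_material}.
#' @param l1,l2,l3 Principal deviatoric stretches (> 0).
#' @return Energy density (kPa).
#' @export
strain_energy <- function(m, l1, l2, l3) {
  if (any(c(l1, l2, l3) <= 0)) stop("stretches must be positive", call. = FALSE)
  L <- log(c(l1, l2, l3))
  sum(vapply(seq_len(m$N), function(i)
    2 * m$mu[i] * ogden_term_sum(m$alpha[i], L), numeric(1)))
}

# (l^a - l^(-a/2))/a with small-alpha series:
# = 3L/2 + a 3L^2/8 + a^2 3L^3/16 (+ O(a^3)), L = log(l).
uniax_term <- function(alpha, L) {
  if (abs(alpha) < 1e-2) {
    1.5 * L + alpha * 0.375 * L^2 + alpha^2 * 0.1875 * L^3
  } else {
    (expm1(alpha * L) - expm1(-alpha * L / 2)) / alpha
  }
}

#' Incompressible uniaxial Cauchy stress of an Ogden material
#'
#' sigma(l) = sum_i (2 mu_i / alpha_i)(l^a_i - l^(-a_i/2)) for uniaxial
#' stretch l with free lateral contraction (l2 = l3 = 1/sqrt(l)).
#'
#' @param m An \code{ogden_material}.
#' @param lambda Axial stretch(es) (> 0).
#' @param nominal If TRUE return nominal (first Piola) stress sigma/lambda.
#' @return Stress (kPa), vectorised over \code{lambda}.
#' @export
uniaxial_stress <- function(m, lambda, nominal = FALSE) {
  if (any(lambda <= 0)) stop("stretch must be positive", call. = FALSE)
  s <- vapply(lambda, function(l) {
    L <- log(l)
    sum(vapply(seq_len(m$N), function(i)
      2 * m$mu[i] * uniax_term(m$alpha[i], L), numeric(1)))
  }, numeric(1))
  if (nominal) s / lambda else s
}

#' Initial (small-strain) moduli of an Ogden material
#'
#' mu0 = sum(mu_i), K0 = 2/D1, and the equivalent Poisson's ratio
#' nu = (3 K0 - 2 mu0) / (6 K0 + 2 mu0). D1 = 0 flags exact
#' incompressibility (nu = 0.5).
#'
#' @param m An \code{ogden_material}.
#' @return List with \code{mu0} (kPa), \code{K0} (kPa, Inf if D1 = 0),
#'   \code{nu}, \code{incompressible} flag.
#' @export
initial_moduli <- function(m) {
  mu0 <- sum(m$mu)
  if (m$D1 == 0)
    return(list(mu0 = mu0, K0 = Inf, nu = 0.5, incompressible = TRUE))
  K0 <- 2 / m$D1
  nu <- (3 * K0 - 2 * mu0) / (6 * K0 + 2 * mu0)
  list(mu0 = mu0, K0 = K0, nu = nu, incompressible = FALSE)
}

#' Hoop Cauchy stress of an incompressible tube wall
#'
#' Membrane (plane-stress, sigma_r ~ 0) circumferential Cauchy stress for an
#' incompressible Ogden wall at circumferential stretch \code{lt} and fixed
#' axial stretch \code{lz} (radial stretch 1/(lt lz)):
#' sigma_theta = sum_i (2 mu_i / alpha_i)(lt^a_i - (lt lz)^(-a_i)).
#'
#' @param m An \code{ogden_material}.
#' @param lt Circumferential stretch(es).
#' @param lz Axial stretch (scalar).
#' @return Hoop Cauchy stress (kPa), vectorised over \code{lt}.
#' @export
hoop_stress <- function(m, lt, lz = 1) {
  vapply(lt, function(l) {
    sum(vapply(seq_len(m$N), function(i) {
      a <- m$alpha[i]
      if (abs(a) < 1e-2) {
        # series in a with L = log(lt), M = log(lt lz):
        # (l^a - (l lz)^-a)/a = (L + M) + a (L^2 - M^2)/2 + a^2 (L^3 + M^3)/6
        L <- log(l); M <- log(l * lz)
        2 * m$mu[i] * ((L + M) + a * (L^2 - M^2) / 2 + a^2 * (L^3 + M^3) / 6)
      } else {
        2 * m$mu[i] / a * (l^a - (l * lz)^(-a))
      }
    }, numeric(1)))
  }, numeric(1))
}

# d sigma_theta / d lt (needed by the ring Newton solver)
hoop_stress_dlt <- function(m, lt, lz = 1) {
  vapply(lt, function(l) {
    sum(vapply(seq_len(m$N), function(i) {
      a <- m$alpha[i]
      2 * m$mu[i] * (l^(a - 1) + lz^(-a) * l^(-a - 1))
    }, numeric(1)))
  }, numeric(1))
}
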