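#' Carreau shear-thinning blood rheology
#'
#' Carreau viscosity law
#' mu(gdot) = mu_inf + (mu_0 - mu_inf) [1 + (lambda_t gdot)^a]^((n-1)/a),
#' interpolating between the zero-shear plateau mu_0 and the high-shear
#' plateau mu_inf. Defaults are the standard whole-blood Carreau constants.
#'
#' @param mu_0 Zero-shear viscosity (Pa s); default 0.056.
#' @param mu_inf Infinite-shear viscosity (Pa s); default 0.00345.
#' @param lambda_t Time constant (s); default 3.313.
#' @param n Flow behaviour index; default 0.3568.
#' @param a Transition parameter; default 2.
#' @param rho Density (kg/m^3); default 1050.
#' @return Object of class \code{carreau_model}.
#' @examples
#' m <- carreau_model()
#' carreau_viscosity(m, c(0, 1, 100, 1e6))
#' @export
carreau_model <- function(mu_0 = 0.056, mu_inf = 0.00345, lambda_t = 3.313,
                          n = 0.3568, a = 2, rho = 1050) {
  if (!(mu_0 > mu_inf && mu_inf > 0))
    stop("need mu_0 > mu_inf > 0", call. = FALSE)
  stopifnot_scalar(lambda_t, "lambda_t")
  if (n <= 0 || n >= 1) stop("flow index n must be in (0, 1)", call. = FALSE)
  structure(list(mu_0 = mu_0, mu_inf = mu_inf, lambda_t = lambda_t,
                 n = n, a = a, rho = rho), class = "carreau_model")
}

#' Carreau viscosity at a given shear rate
#'
#' @param m A \code{carreau_model}.
#' @param shear_rate Shear rate(s) (1/s), >= 0.
#' @return Dynamic viscosity (Pa s), bounded by [mu_inf, mu_0] and monotone
#'   non-increasing in shear rate.
#' @export
carreau_viscosity <- function(m, shear_rate) {
  if (any(shear_rate < 0)) stop("shear rate must be >= 0", call. = FALSE)
  m$mu_inf + (m$mu_0 - m$mu_inf) *
    (1 + (m$lambda_t * shear_rate)^m$a)^((m$n - 1) / m$a)
}

#' Newtonian special case of the Carreau container
#'
#' Convenience constructor collapsing both plateaus to one viscosity (used
#' by analytic-oracle comparisons).
#'
#' @param mu Viscosity (Pa s).
#' @param rho Density (kg/m^3).
#' @return A \code{carreau_model} whose viscosity is \code{mu} at all shear
#'   rates (within machine tolerance).
#' @export
newtonian_model <- function(mu = 0.0035, rho = 1050) {
  structure(list(mu_0 = mu * (1 + 1e-12), mu_inf = mu, lambda_t = 1,
                 n = 0.5, a = 2, rho = rho), class = "carreau_model")
}
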