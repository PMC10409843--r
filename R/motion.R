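#' Bending displacement field from a diastole/systole centreline pair
#'
#' Resamples both centrelines to \code{n_stations} equally spaced points in
#' normalised arc length (the correspondence assumption; any change in vessel
#' length between phases is absorbed by the normalisation) and takes the
#' pointwise difference, giving one 3D displacement vector per station,
#' diastole to systole.
#'
#' @param diastole,systole \code{centerline} objects for the two cardiac
#'   phases.
#' @param n_stations Number of stations to co-register on.
#' @return Object of class \code{bending_field}: \code{vectors}
#'   (n_stations x 3, mm), \code{arc_length} (diastolic, mm),
#'   \code{patch_mask} (filled by \code{\link{assign_to_wall}}),
#'   \code{peri_full_circumference} flag.
#' @export
compute_bending_vectors <- function(diastole, systole, n_stations) {
  d <- resample_centerline(diastole, n_stations)
  s <- resample_centerline(systole, n_stations)
  if (nrow(d$points) != nrow(s$points))
    stop("station counts differ after resampling", call. = FALSE)
  v <- s$points - d$points
  if (!all(is.finite(v))) stop("non-finite bending vectors", call. = FALSE)
  structure(list(vectors = v, arc_length = d$arc_length,
                 diastole = d, systole = s,
                 patch_mask = NULL, peri_full_circumference = TRUE),
            class = "bending_field")
}

#' @export
print.bending_field <- function(x, ...) {
  cat(sprintf("<bending_field> %d stations, max |d| = %.3f mm\n",
              nrow(x$vectors), max(row_norms(x$vectors))))
  invisible(x)
}

#' Assign centreline bending vectors to wall nodes
#'
#' Every wall node in station ring i lying inside the inner-curvature patch
#' receives exactly \code{vectors[i, ]} (nodes on the same circumferential
#' set share one displacement); nodes outside the patch are unloaded. The
#' perivascular outer surface is additionally loaded on its full
#' circumference when \code{field$peri_full_circumference} is TRUE.
#'
#' @param field A \code{bending_field} with stations co-registered to
#'   \code{geometry}.
#' @param geometry An \code{artery_geometry} with \code{n_axial} equal to the
#'   field's station count.
#' @param patch_fraction Circumferential fraction loaded (default 0.3).
#' @return The field with \code{patch_mask} (logical n_axial x n_circ) and
#'   \code{wall_displacement} (n_axial x n_circ x 3; zero off-patch) filled.
#' @export
assign_to_wall <- function(field, geometry, patch_fraction = 0.3) {
  if (nrow(field$vectors) != geometry$n_axial)
    stop("field stations not co-registered with geometry stations", call. = FALSE)
  mask <- inner_curvature_mask(geometry, patch_fraction)
  disp <- array(0, c(geometry$n_axial, geometry$n_circ, 3))
  for (k in 1:3) disp[, , k] <- field$vectors[, k] * mask
  field$patch_mask <- mask
  field$wall_displacement <- disp
  field
}

#' Smoothed asymmetric sawtooth bending amplitude
#'
#' Amplitude function A(t) on one cardiac period: 0 at diastole (t = 0),
#' linear rise to 1 at systole, linear fall back to 0 at the period end.
#' Both extrema are blended over a window of width \code{smoothing_width}
#' using monotone cubic Hermite segments with zero slope at the extremum, so
#' A is C1 and periodic (no displacement-rate impulse when the artery
#' reverses direction at end-systole and end-diastole), stays in [0, 1], and
#' attains A = 0 and A = 1 exactly.
#'
#' @param T Cardiac period (s).
#' @param t_systole Time of peak amplitude (s), 0 < t_systole < T.
#' @param smoothing_width Half-width of the blend window (s); default 5% of
#'   T; must be < min(t_systole, T - t_systole).
#' @param n_t Number of samples on the uniform periodic grid [0, T).
#' @return Object of class \code{amplitude_waveform}: \code{time},
#'   \code{samples}, \code{t_systole}, \code{t_diastole} (= 0), \code{T},
#'   and \code{fun}, the underlying A(t) closure (periodic).
#' @export
make_amplitude <- function(T, t_systole, smoothing_width = 0.05 * T,
                           n_t = 200L) {
  stopifnot_scalar(T, "T")
  if (t_systole <= 0 || t_systole >= T)
    stop("t_systole must lie strictly inside (0, T)", call. = FALSE)
  if (smoothing_width < 0 ||
      smoothing_width >= min(t_systole, T - t_systole))
    stop("smoothing_width too large for this period split", call. = FALSE)

  w <- smoothing_width
  s_up <- 1 / t_systole          # rising slope
  s_dn <- 1 / (T - t_systole)    # falling slope (magnitude)

  # cubic Hermite on [0,1] given endpoint values/slopes (slopes per unit x)
  hermite <- function(x, y0, y1, m0, m1) {
    h00 <- 2 * x^3 - 3 * x^2 + 1; h10 <- x^3 - 2 * x^2 + x
    h01 <- -2 * x^3 + 3 * x^2;    h11 <- x^3 - x^2
    h00 * y0 + h10 * m0 + h01 * y1 + h11 * m1
  }

  afun <- function(t) {
    t <- t %% T
    a <- numeric(length(t))
    for (ii in seq_along(t)) {
      ti <- t[ii]
      if (w > 0 && ti < w) {                    # diastolic blend, rising side
        a[ii] <- hermite(ti / w, 0, w * s_up, 0, w * s_up)
      } else if (ti <= t_systole - w) {         # linear rise
        a[ii] <- ti * s_up
      } else if (ti < t_systole) {              # blend into systolic peak
        x <- (ti - (t_systole - w)) / max(w, .Machine$double.eps)
        a[ii] <- hermite(x, 1 - w * s_up, 1, w * s_up, 0)
      } else if (w > 0 && ti < t_systole + w) { # blend out of systolic peak
        x <- (ti - t_systole) / w
        a[ii] <- hermite(x, 1, 1 - w * s_dn, 0, -w * s_dn)
      } else if (ti <= T - w || w == 0) {       # linear fall
        a[ii] <- (T - ti) * s_dn
      } else {                                  # diastolic blend, falling side
        x <- (ti - (T - w)) / w
        a[ii] <- hermite(x, w * s_dn, 0, -w * s_dn, 0)
      }
    }
    a
  }

  tt <- T * (seq_len(n_t) - 1L) / n_t
  structure(list(time = tt, samples = afun(tt), t_systole = t_systole,
                 t_diastole = 0, T = T, fun = afun),
            class = "amplitude_waveform")
}

#' Synchronise amplitude and haemodynamic waveforms on a common grid
#'
#' Resamples the bending amplitude, inlet velocity and outlet pressure
#' waveforms onto one uniform periodic time grid on [0, T), phase-aligned so
#' that the R peak sits at t = 0 (the role the ECG plays for the measured
#' waveforms). Waveform values are interpolated periodically and linearly.
#'
#' @param amplitude An \code{amplitude_waveform}.
#' @param velocity,pressure Data frames with columns \code{time_s} and
#'   \code{value}, each covering one R-R interval.
#' @param r_peak_times Numeric vector of R-peak times (s); the first entry is
#'   taken as the phase origin and successive gaps define the period of the
#'   measured waveforms.
#' @param n_t Samples on the common grid.
#' @return List with \code{time} (length n_t), \code{time_normalised}
#'   (t / T), \code{amplitude}, \code{velocity}, \code{pressure} vectors.
#' @export
synchronize <- function(amplitude, velocity, pressure, r_peak_times,
                        n_t = 200L) {
  T <- amplitude$T
  if (length(r_peak_times) >= 2) {
    T_meas <- diff(r_peak_times)[1]
    if (abs(T_meas - T) / T > 0.01)
      stop(sprintf("waveform period (%.3f s) inconsistent with amplitude period (%.3f s)",
                   T_meas, T), call. = FALSE)
  }
  t0 <- r_peak_times[1]
  tt <- T * (seq_len(n_t) - 1L) / n_t
  list(time = tt,
       time_normalised = tt / T,
       amplitude = amplitude$fun(tt),
       velocity = periodic_interp(velocity$time_s - t0, velocity$value, tt, T),
       pressure = periodic_interp(pressure$time_s - t0, pressure$value, tt, T))
}

# Periodic linear interpolation of samples (x, y) with period T at xout.
periodic_interp <- function(x, y, xout, T) {
  x <- x %% T
  o <- order(x)
  x <- x[o]; y <- y[o]
  dup <- duplicated(x)
  x <- x[!dup]; y <- y[!dup]
  # wrap one point each side for periodicity
  xx <- c(x[length(x)] - T, x, x[1] + T)
  yy <- c(y[length(y)], y, y[1])
  stats::approx(xx, yy, xout = xout %% T)$y
}

#' Bending-derivative profile of a displacement field
#'
#' The coronary bending metric: the first spatial derivative, along the
#' vessel, of the magnitude of the bending displacement after subtracting the
#' inlet displacement (removing rigid-body translation). Zero everywhere
#' means pure translation; non-zero values flag local centreline deformation.
#'
#' @param field A \code{bending_field}.
#' @param centerline Optional \code{centerline} supplying arc length; by
#'   default the field's own diastolic arc length is used.
#' @return Object of class \code{bending_derivative}: \code{values}
#'   (dimensionless, per station) and \code{arc_length}.
#' @export
bending_derivative <- function(field, centerline = NULL) {
  s <- if (is.null(centerline)) field$arc_length else centerline$arc_length
  d <- sweep(field$vectors, 2, field$vectors[1, ])
  m <- row_norms(d)
  n <- length(m)
  if (n < 3) stop("need at least 3 stations", call. = FALSE)
  v <- numeric(n)
  v[1] <- (m[2] - m[1]) / (s[2] - s[1])
  v[n] <- (m[n] - m[n - 1]) / (s[n] - s[n - 1])
  v[2:(n - 1)] <- (m[3:n] - m[1:(n - 2)]) / (s[3:n] - s[1:(n - 2)])
  structure(list(values = v, arc_length = s), class = "bending_derivative")
}

#' Decompose a centreline motion into translation, bend and lever modes
#'
#' Least-squares projection of the displacement field between two centrelines
#' onto the three coronary motion modes: rigid translation, smooth curvature
#' change (bend) and rotation about the proximal end (lever). The basis
#' fields are built from the diastolic centreline alone, so the fit is an
#' independent recovery of the composition used by the synthetic generator.
#'
#' @param diastole,systole \code{centerline} objects (same station count, or
#'   they are co-registered at the diastolic station count).
#' @param bend_profile Optional axial profile of the bend mode; defaults to
#'   the generator's raised-cosine bump.
#' @return List with \code{weights} (named, summing to 1 over positive
#'   contributions), \code{coefficients} (mm amplitudes of each mode) and
#'   \code{residual} (relative L2 misfit).
#' @export
fit_motion_modes <- function(diastole, systole, bend_profile = NULL) {
  n <- nrow(diastole$points)
  if (nrow(systole$points) == n) {
    # matched stations: use the pointwise correspondence directly
    d <- systole$points - diastole$points
    base <- diastole
  } else {
    pair <- compute_bending_vectors(diastole, systole, n)
    d <- pair$vectors
    base <- pair$diastole
  }
  basis <- motion_mode_basis(base, bend_profile)
  y <- as.vector(d)
  X <- cbind(as.vector(basis$translation), as.vector(basis$bend),
             as.vector(basis$lever))
  cf <- stats::lsfit(X, y, intercept = FALSE)$coefficients
  cf <- pmax(cf, 0)
  w <- if (sum(cf) > 0) cf / sum(cf) else cf
  names(w) <- names(cf) <- c("translation", "bend", "lever")
  fit <- X %*% cf
  res <- if (sum(y^2) > 0) sqrt(sum((y - fit)^2) / sum(y^2)) else 0
  list(weights = w, coefficients = cf, residual = res)
}

# Unit-normalised (max |.| = 1) basis displacement fields for the three
# motion modes on a given base centreline.
motion_mode_basis <- function(base, bend_profile = NULL) {
  n <- nrow(base$points)
  s <- base$arc_length / total_length(base)
  fr <- transport_frames(base)
  u_plane <- fr$normal[1, ]                       # motion-plane direction
  translation <- matrix(rep(u_plane, each = n), n, 3)
  if (is.null(bend_profile)) bend_profile <- 0.5 * (1 - cos(2 * pi * s^1.5))
  bend <- bend_profile / max(abs(bend_profile)) * translation
  axis <- fr$binormal[1, ]                        # lever rotation axis
  r <- sweep(base$points, 2, base$points[1, ])
  lever <- t(vapply(seq_len(n), function(i) cross3(axis, r[i, ]), numeric(3)))
  mx <- max(row_norms(lever)); if (mx > 0) lever <- lever / mx
  list(translation = translation, bend = bend, lever = lever)
}
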