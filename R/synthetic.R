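# Coronary-like synthetic inputs: geometries, diastole/systole centreline
# pairs with controlled motion composition, and two-phase velocity/pressure
# waveforms, all seeded, so the full pipeline runs without any measurement.

#' Synthetic coronary artery preset
#'
#' Builds an artery-like tapered curved tube plus motion and waveform
#' presets for one of the three main coronary branches. Wall thickness is
#' branch-specific (LAD 250 um; LCx and RCA 190 um). Motion composition is
#' bend-dominant for the LAD and RCA and translation-dominant for the LCx;
#' left-system waveforms are diastolic-dominant.
#'
#' @param name Preset: "lad", "lcx" or "rca".
#' @param seed Integer seed controlling the small random perturbations.
#' @return List with \code{geometry} (an \code{artery_geometry}),
#'   \code{motion} (a \code{motion_preset}) and \code{waveforms} (a
#'   \code{waveform_preset}).
#' @examples
#' p <- make_artery_preset("lad", seed = 1)
#' p$geometry
#' @export
make_artery_preset <- function(name = c("lad", "lcx", "rca"), seed = 0) {
  name <- match.arg(name)
  cfg <- switch(name,
    lad = list(h = 250, L = 45, r0 = 1.7, r1 = 1.0, curv = 0.022,
               weights = c(translation = 0.30, bend = 0.50, lever = 0.20),
               amplitude = 4.0, dia_dominant = TRUE),
    lcx = list(h = 190, L = 40, r0 = 1.5, r1 = 0.9, curv = 0.028,
               weights = c(translation = 0.60, bend = 0.25, lever = 0.15),
               amplitude = 3.0, dia_dominant = TRUE),
    rca = list(h = 190, L = 50, r0 = 1.6, r1 = 1.0, curv = 0.030,
               weights = c(translation = 0.35, bend = 0.45, lever = 0.20),
               amplitude = 4.5, dia_dominant = FALSE))
  n_sta <- 41L
  rng <- make_rng(seed)
  s <- seq(0, cfg$L, length.out = n_sta)
  # gently curved planar centreline with a mild out-of-plane component
  amp_y <- cfg$curv * cfg$L^2 / 8
  pts <- cbind(s,
               amp_y * sin(pi * s / cfg$L) * (1 + 0.05 * rng()),
               0.15 * amp_y * sin(2 * pi * s / cfg$L) * (1 + 0.05 * rng()))
  cl <- centerline(pts)
  radius <- cfg$r0 + (cfg$r1 - cfg$r0) * (s / cfg$L)
  geometry <- build_tube(cl, radius, wall_thickness = cfg$h, n_circ = 40L)
  motion <- structure(list(mode_weights = cfg$weights,
                           amplitude_mm = cfg$amplitude,
                           plane = "transport-normal", seed = seed),
                      class = "motion_preset")
  waveforms <- waveform_preset(T = 1,
                               dia_dominant = cfg$dia_dominant, seed = seed)
  list(geometry = geometry, motion = motion, waveforms = waveforms,
       name = name)
}

# small deterministic RNG helper (isolated from the global stream)
make_rng <- function(seed) {
  env <- new.env()
  env$state <- seed
  function(n = 1) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      env$state <- (1103515245 * (env$state + 12345)) %% 2147483648
      out[i] <- env$state / 2147483648 * 2 - 1
    }
    out
  }
}

#' Waveform shape preset
#'
#' @param T Cardiac period (s).
#' @param systolic_peak Systolic pressure peak (mmHg); default 120.
#' @param diastolic_baseline Diastolic pressure (mmHg); default 80, the
#'   pre-stress reference state.
#' @param v_sys,v_dia Systolic/diastolic velocity peaks (m/s).
#' @param dia_dominant Left-system flow pattern (dominant diastolic flow).
#' @param noise_sd Gaussian noise added before smoothing (emulates raw
#'   measurement; 0 = clean).
#' @param seed Seed for the noise.
#' @return Object of class \code{waveform_preset}.
#' @export
waveform_preset <- function(T = 1, systolic_peak = 120,
                            diastolic_baseline = 80, v_sys = 0.15,
                            v_dia = 0.35, dia_dominant = TRUE,
                            noise_sd = 0, seed = 0) {
  if (T <= 0) stop("period must be positive", call. = FALSE)
  if (systolic_peak <= diastolic_baseline || diastolic_baseline <= 0)
    stop("pressures must be positive with peak > baseline", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!dia_dominant) { tmp <- v_sys; v_sys <- v_dia; v_dia <- tmp }
  structure(list(T = T, systolic_peak = systolic_peak,
                 diastolic_baseline = diastolic_baseline,
                 v_sys = v_sys, v_dia = v_dia, dia_dominant = dia_dominant,
                 noise_sd = noise_sd, seed = seed),
            class = "waveform_preset")
}

# periodic raised-cosine bump centred at t0 with half-width w, zero outside
raised_cosine <- function(t, t0, w, T) {
  d <- abs(((t - t0 + T / 2) %% T) - T / 2)
  ifelse(d < w, 0.5 * (1 + cos(pi * d / w)), 0)
}

#' Synthetic coronary velocity and pressure waveforms
#'
#' Smooth periodic two-phase waveforms built from raised-cosine bumps on a
#' baseline: the velocity has systolic and diastolic peaks (diastolic
#' dominant for left-system presets), the pressure rises from the 80 mmHg
#' diastolic baseline to the systolic peak. Optional Gaussian noise is
#' added and then smoothed with a periodic moving average, mimicking the
#' smoothing of raw measured data into a cyclic waveform.
#'
#' @param preset A \code{waveform_preset}.
#' @param n_t Samples on [0, T).
#' @return List with \code{velocity} and \code{pressure} data frames
#'   (\code{time_s}, \code{value}) and \code{r_peak_times} (= c(0, T)).
#' @export
make_waveforms <- function(preset, n_t = 200L) {
  T <- preset$T
  tt <- T * (seq_len(n_t) - 1L) / n_t
  v <- 0.05 +
    preset$v_sys * raised_cosine(tt, 0.18 * T, 0.14 * T, T) +
    preset$v_dia * raised_cosine(tt, 0.62 * T, 0.26 * T, T)
  p <- preset$diastolic_baseline +
    (preset$systolic_peak - preset$diastolic_baseline) *
    (0.85 * raised_cosine(tt, 0.30 * T, 0.28 * T, T) +
       0.15 * raised_cosine(tt, 0.55 * T, 0.35 * T, T))
  if (preset$noise_sd > 0) {
    rng <- make_rng(preset$seed)
    gauss <- function(n) {   # Box-Muller on the package's isolated stream
      u1 <- (rng(n) + 1) / 2; u2 <- (rng(n) + 1) / 2
      sqrt(-2 * log(pmax(u1, 1e-12))) * cos(2 * pi * u2)
    }
    v <- smooth_periodic(v + preset$noise_sd * gauss(n_t))
    p <- smooth_periodic(p + preset$noise_sd * 100 * gauss(n_t))
  }
  list(velocity = data.frame(time_s = tt, value = v),
       pressure = data.frame(time_s = tt, value = p),
       r_peak_times = c(0, T))
}

# periodic moving-average smoothing (window fraction of the cycle)
smooth_periodic <- function(x, passes = 4, width_frac = 0.03) {
  n <- length(x)
  k <- max(3L, 2L * floor(width_frac * n / 2) + 1L)
  half <- (k - 1L) %/% 2L
  for (p in seq_len(passes)) {
    xp <- c(x[(n - half + 1):n], x, x[1:half])
    x <- as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(half + 1):(half + n)]
  }
  x
}

#' Synthetic diastole/systole centreline pair
#'
#' Transforms a base (diastolic) centreline into a systolic one by the
#' weighted composition of the three coronary motion modes: rigid
#' translation, smooth curvature change (bend) and rotation about the
#' proximal end (lever). The total displacement magnitude is scaled so its
#' maximum equals \code{preset$amplitude_mm}.
#'
#' @param base A \code{centerline} (the diastolic configuration).
#' @param preset A \code{motion_preset} (weights sum to 1) or a named
#'   numeric vector of weights.
#' @param amplitude_mm Peak displacement (mm); default from the preset.
#' @return List with \code{diastole}, \code{systole} (\code{centerline}s)
#'   and \code{displacement} (n x 3, mm).
#' @export
make_centerline_pair <- function(base, preset, amplitude_mm = NULL) {
  w <- if (inherits(preset, "motion_preset")) preset$mode_weights else preset
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("mode weights must be >= 0 and sum to 1", call. = FALSE)
  if (is.null(amplitude_mm))
    amplitude_mm <- if (inherits(preset, "motion_preset"))
      preset$amplitude_mm else 1
  basis <- motion_mode_basis(base)
  d <- w[1] * basis$translation + w[2] * basis$bend + w[3] * basis$lever
  mx <- max(row_norms(d))
  if (mx > 0) d <- d * (amplitude_mm / mx)
  systole <- centerline(base$points + d)
  list(diastole = base, systole = systole, displacement = d)
}
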