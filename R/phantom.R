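#' Specification of the synthetic annulus phantom
#'
#' The phantom emulates the geometry and motion the pipeline is designed
#' for: a (possibly saddle-shaped) annular ring on a long axis, imaged by
#' three long-axis planes 60 degrees apart, descending toward the apex in
#' systole and returning in two diastolic waves (E and A, each a
#' raised-cosine velocity pulse) separated by a diastasis plateau.
#'
#' Defaults describe a normal-sized, normally relaxing ventricle: ring
#' radius 15 mm, systolic descent 12 mm, 70% of the descent recovered in
#' early diastole, 25 phases over an RR of 857 ms (70 bpm), timing
#' fractions (0.35, 0.20, 0.25, 0.20) of RR for systole/ED/MD/AS, and
#' 1.4 mm pixels — typical cine-CMR in-plane resolution.
#'
#' When `ea_peak_ratio` is `NULL` each velocity pulse fills its interval
#' and the peak-rate ratio follows from `e_fraction` and the interval
#' durations (`fE/(1-fE) * T_AS/T_ED`; 2.33 at the defaults). A prescribed
#' ratio is honoured by narrowing whichever pulse has surplus velocity; a
#' ratio that would need a pulse narrower than two phase spacings is an
#' error.
#'
#' @param radius_mm annular ring radius.
#' @param saddle_height_mm amplitude of the saddle (out-of-plane cos(2
#'   theta) term).
#' @param tilt_mm peak first-harmonic (cos(theta)) axial wobble of the
#'   ring, scaling with the instantaneous descent — the annular tilt seen
#'   in vivo, which makes septal and lateral excursions differ. Its
#'   azimuthal mean is zero, so the ring centroid (and hence the analytic
#'   sweep curve) is unaffected.
#' @param sway_mm peak transverse (in-plane) displacement of the ring
#'   center, scaling with the instantaneous descent; also leaves the axial
#'   centroid motion unchanged.
#' @param systolic_descent_mm total apex-ward annular excursion in systole.
#' @param e_fraction fraction of the descent recovered in early diastole.
#' @param ea_peak_ratio prescribed E:A peak axial velocity ratio, or `NULL`
#'   (derived; see Details).
#' @param timing fractions of RR for systole, early diastole, mid-diastole
#'   and atrial systole; must sum to 1.
#' @param rr_ms RR interval (ms).
#' @param n_phases reconstructed phases per cycle (>= 8).
#' @param size_px square image side (pixels).
#' @param spacing_mm isotropic pixel spacing.
#' @param noise_sigma additive Gaussian image noise SD (image units; frames
#'   are ~[0, 1]).
#' @param blur_sigma Gaussian blur SD in pixels (0 = none).
#' @param seed RNG seed controlling texture phases and noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(radius_mm = 15, saddle_height_mm = 2,
                         tilt_mm = 2, sway_mm = 2,
                         systolic_descent_mm = 12, e_fraction = 0.7,
                         ea_peak_ratio = NULL,
                         timing = c(systole = 0.35, ed = 0.20,
                                    md = 0.25, as = 0.20),
                         rr_ms = 857, n_phases = 25L,
                         size_px = 128L, spacing_mm = 1.4,
                         noise_sigma = 0, blur_sigma = 0, seed = 1L) {
  if (radius_mm <= 0) stop("radius_mm must be positive")
  if (n_phases < 8L) stop("n_phases must be >= 8")
  if (abs(sum(timing) - 1) > 1e-9) stop("timing fractions must sum to 1")
  if (e_fraction <= 0 || e_fraction >= 1)
    stop("e_fraction must lie strictly in (0, 1)")
  structure(list(radius_mm = radius_mm, saddle_height_mm = saddle_height_mm,
                 tilt_mm = tilt_mm, sway_mm = sway_mm,
                 systolic_descent_mm = systolic_descent_mm,
                 e_fraction = e_fraction, ea_peak_ratio = ea_peak_ratio,
                 timing = timing, rr_ms = rr_ms,
                 n_phases = as.integer(n_phases),
                 size_px = as.integer(size_px), spacing_mm = spacing_mm,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# normalized Hann-pulse integral: H(0)=0, H(1)=1
hann_int <- function(s) s - sin(2 * pi * s) / (2 * pi)

# fixed azimuths of the tilt axis and sway direction, deliberately
# incommensurate with the 0/60/120-degree view planes so every tracked
# point gets a distinct axial trajectory
TILT_AZIMUTH <- 40 * pi / 180
SWAY_DIR <- c(cos(20 * pi / 180), sin(20 * pi / 180))

#' Build the annular motion profile
#'
#' Constructs the axial displacement z(t) (mm toward the apex, z(0) =
#' z(RR) = 0) and ring area per phase, together with continuous-time
#' accessors and the analytic wave parameters. Systole is a half-cosine
#' descent over its interval; the E and A recoveries are raised-cosine
#' (Hann) velocity pulses whose areas split the descent `e_fraction :
#' 1 - e_fraction` and whose peak velocities realize the E:A ratio.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `motion_profile`: per-phase `z_mm` and
#'   `area_mm2` (length P, phase times `t_ms`), continuous functions
#'   `z_fun(t_ms)` and `v_fun(t_ms)` (mm/ms), and the pulse parameters
#'   (`w_e_ms`, `w_a_ms`, `v_e_peak_mms`, `v_a_peak_mms`, interval
#'   boundaries, realized `ea_peak_ratio`).
#' @export
build_motion_profile <- function(spec) {
  rr <- spec$rr_ms
  D <- spec$systolic_descent_mm
  fE <- spec$e_fraction
  Ts <- spec$timing[["systole"]] * rr
  Ted <- spec$timing[["ed"]] * rr
  Tas <- spec$timing[["as"]] * rr
  if (D > 0) {
    if (is.null(spec$ea_peak_ratio)) {
      w_e <- Ted; w_a <- Tas
    } else {
      rho <- spec$ea_peak_ratio
      if (rho <= 0) stop("ea_peak_ratio must be positive")
      a_ratio <- fE / (1 - fE)           # E:A recovered-volume ratio
      if (a_ratio / rho >= Ted / Tas) {
        w_e <- Ted; w_a <- Ted * rho / a_ratio
      } else {
        w_a <- Tas; w_e <- Tas * a_ratio / rho
      }
      dt <- rr / spec$n_phases
      if (w_e < 2 * dt || w_a < 2 * dt)
        stop("requested ea_peak_ratio needs a velocity pulse narrower than ",
             "two phase spacings; adjust timing or e_fraction")
    }
    v_e <- 2 * fE * D / w_e              # mm/ms peak
    v_a <- 2 * (1 - fE) * D / w_a
  } else {
    w_e <- Ted; w_a <- Tas; v_e <- 0; v_a <- 0
  }
  t_as0 <- rr - w_a                      # A pulse ends at the R wave
  z_fun <- function(t) {
    t <- t %% rr
    z <- numeric(length(t))
    i <- t < Ts
    z[i] <- D / 2 * (1 - cos(pi * t[i] / Ts))
    i <- t >= Ts & t < Ts + w_e
    z[i] <- D - fE * D * hann_int((t[i] - Ts) / w_e)
    i <- t >= Ts + w_e & t < t_as0
    z[i] <- D * (1 - fE)
    i <- t >= t_as0
    z[i] <- D * (1 - fE) * (1 - hann_int((t[i] - t_as0) / w_a))
    z
  }
  v_fun <- function(t) {
    t <- t %% rr
    v <- numeric(length(t))
    i <- t < Ts
    v[i] <- D * pi / (2 * Ts) * sin(pi * t[i] / Ts)
    i <- t >= Ts & t < Ts + w_e
    v[i] <- -v_e / 2 * (1 - cos(2 * pi * (t[i] - Ts) / w_e))
    i <- t >= t_as0
    v[i] <- -v_a / 2 * (1 - cos(2 * pi * (t[i] - t_as0) / w_a))
    v
  }
  t_ms <- (seq_len(spec$n_phases) - 1) * rr / spec$n_phases
  structure(list(t_ms = t_ms, z_mm = z_fun(t_ms),
                 area_mm2 = rep(pi * spec$radius_mm^2, spec$n_phases),
                 z_fun = z_fun, v_fun = v_fun,
                 w_e_ms = w_e, w_a_ms = w_a,
                 v_e_peak_mms = v_e * 1000, v_a_peak_mms = v_a * 1000,
                 ea_peak_ratio = if (v_a > 0) v_e / v_a else NA_real_,
                 systole_end_ms = Ts, ed_end_ms = Ts + w_e,
                 as_onset_ms = t_as0, rr_ms = rr),
            class = "motion_profile")
}

#' Analytic diastolic parameters of a phantom
#'
#' Computes the ground-truth diastolic indices directly from the
#' continuous motion profile (not from rendered images): peak and average
#' normalized rates from the pulse parameters, recovery percentages from
#' `e_fraction`, AT from the pulse center, DT by least-squares linear
#' extrapolation of the continuous descending E limb to baseline (evaluated
#' on a fine time grid), and the 50% recovery time by root finding on z(t).
#'
#' @param spec a [phantom_spec()].
#' @param profile its [build_motion_profile()] (recomputed if missing).
#' @param recovery_threshold recovery fraction for the recovery-time index
#'   (default 0.5).
#' @return list of ground-truth parameters (same names as
#'   [compute_parameters()] where applicable).
#' @export
phantom_truth_params <- function(spec, profile = build_motion_profile(spec),
                                 recovery_threshold = 0.5) {
  D <- spec$systolic_descent_mm
  if (D <= 0) stop("truth parameters undefined for a motionless phantom")
  fE <- spec$e_fraction
  rr <- spec$rr_ms
  A <- pi * spec$radius_mm^2
  essv_cm3 <- A * D / 1000
  psr_e <- profile$v_e_peak_mms / D        # 1/s
  psr_a <- profile$v_a_peak_mms / D
  Ts <- profile$systole_end_ms
  # DT: LS line on the continuous descending half of the E Hann pulse
  w <- profile$w_e_ms
  tt <- seq(Ts + w / 2, Ts + w, length.out = 2001)
  rcont <- -profile$v_fun(tt) * 1000 / D   # normalized rate, 1/s
  fit <- stats::lm.fit(cbind(1, tt), rcont)
  dt_sv <- unname(-fit$coefficients[1L] / fit$coefficients[2L]) -
    (Ts + w / 2)
  # recovery-time index: z falls through threshold*D after end-systole
  zf <- function(t) profile$z_fun(t) - recovery_threshold * D
  t50 <- stats::uniroot(zf, c(Ts, rr - 1e-9), tol = 1e-10)$root
  list(psr_e = psr_e, psr_a = psr_a, psr_ratio = psr_e / psr_a,
       avg_rate_ed = fE / (profile$w_e_ms / 1000),
       avg_rate_as = (1 - fE) / (profile$w_a_ms / 1000),
       pct_recovery_ed = 100 * fE, pct_recovery_as = 100 * (1 - fE),
       abs_sweep_ed_cm3 = fE * essv_cm3,
       abs_sweep_as_cm3 = (1 - fE) * essv_cm3,
       at_sv_ms = profile$w_e_ms / 2, dt_sv_ms = dt_sv,
       dsvrt50_pct_rr = 100 * (t50 - Ts) / rr,
       essv_cm3 = essv_cm3, ed_onset_ms = Ts,
       ed_end_ms = profile$ed_end_ms, as_onset_ms = profile$as_onset_ms)
}

#' Analytic sweep curve of a phantom
#'
#' The ground-truth `sweep_curve` at the sampled phase times: for the
#' rigidly translating ring the cumulative swept volume is exactly (ring
#' area) x (axial displacement).
#'
#' @inheritParams phantom_truth_params
#' @return a [sweep_volume()]-compatible `sweep_curve` object.
#' @export
phantom_truth_curve <- function(spec, profile = build_motion_profile(spec)) {
  A <- pi * spec$radius_mm^2
  cumu <- A * profile$z_mm
  P <- spec$n_phases
  structure(list(increments_mm3 = diff(cumu), cumulative_mm3 = cumu,
                 closure_mm3 = cumu[1L] - cumu[P],
                 essv_mm3 = max(cumu), normalized = cumu / max(cumu),
                 times_ms = profile$t_ms,
                 es_phase = which.max(cumu) - 1L,
                 rr_interval_ms = spec$rr_ms,
                 long_axis = c(0, 0, -1),
                 areas_mm2 = profile$area_mm2,
                 centroids = cbind(0, 0, -profile$z_mm)),
            class = "sweep_curve")
}

# separable Gaussian blur, reflected edges
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {  # convolve each column with k, reflect-padded
    n <- nrow(m)
    idx <- c(rev(seq_len(h) + 1L), seq_len(n), n - seq_len(h))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (s in seq_along(k))
      out <- out + k[s] * mp[s:(s + n - 1L), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

# analytic AVJ texture blob: sharp Gaussian envelope carrying a broadband
# (incommensurate-frequency) pattern; translates exactly with fractional
# position so the rendered appearance is the same at any subpixel location
avj_blob <- function(drow, dcol, phase1, phase2) {
  env <- exp(-(drow^2 + dcol^2) / (2 * 3.2^2))
  # amplitude kept low enough that blob + blood pool never saturates the
  # [0, 1] intensity range: clipping would flatten the core and break
  # subpixel translation-equivariance
  0.5 * env * (0.55 + 0.28 * cos(1.15 * drow + 0.55 * dcol + phase1) +
                 0.17 * cos(0.65 * dcol - 0.85 * drow + phase2))
}

#' Render the three-view cine phantom
#'
#' Generates the three long-axis planes (0/60/120 degrees about the long
#' axis, assigned to the four-, two- and three-chamber labels), renders per
#' phase a bright blood pool, darker myocardial bands and two
#' high-contrast textured blobs centered exactly on the annulus-plane
#' intersection points, records the exact (fractional, 0-based) AVJ pixel
#' locations as ground truth, and only then applies optional blur and
#' noise. Deterministic for a fixed `seed`.
#'
#' The transverse sway can carry a ring point up to `sway_mm` off the
#' nominal view plane; as in thick-slice cine imaging (typical slice
#' thickness 6 mm) the point is rendered at its in-plane projection, and
#' `avj_pixels` records that projected location. The axial (z) coordinate
#' is unaffected, so the hexagonal mean of the six mapped points still
#' equals the analytic centroid height exactly.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_study`: `study` (a [study_geometry]),
#'   `truth` (list: `profile`, `truth_curve`, `truth_params` or `NULL` for
#'   a motionless phantom, `avj_pixels` — named list per
#'   `"<view>/<point>"` of P x 2 matrices), and `spec`.
#' @export
render_views <- function(spec) {
  profile <- build_motion_profile(spec)
  R <- spec$radius_mm
  N <- spec$size_px
  sp <- spec$spacing_mm
  P <- spec$n_phases
  D <- spec$systolic_descent_mm
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  tex_phase <- matrix(stats::runif(12, 0, 2 * pi), 6, 2)  # per point
  angles <- c(four_chamber = 0, two_chamber = 60, three_chamber = 120) * pi / 180
  half_fov <- (N - 1) / 2 * sp
  if (R + 12 > half_fov || D + 12 > half_fov)
    stop("annulus leaves the field of view; increase size_px or spacing_mm")
  views <- list()
  avj <- list()
  pt_idx <- 0L
  for (lab in names(angles)) {
    phi <- angles[[lab]]
    u <- c(cos(phi), sin(phi), 0)
    row_dir <- u
    col_dir <- c(0, 0, -1)
    center <- c(0, 0, -D / 2)
    # independently prescribed slices do not share a pixel grid: offset each
    # view's raster by a sub-pixel amount so quantization decorrelates
    # across views, as in real multi-view acquisitions
    grid_off <- stats::runif(2, 0, sp)
    origin <- center - ((N - 1) / 2 * sp + grid_off[1]) * col_dir -
      ((N - 1) / 2 * sp + grid_off[2]) * row_dir
    # pixel-grid coordinates in the plane: along u and along world z
    u0 <- sum(origin * u); z0 <- origin[3]
    jj <- (seq_len(N) - 1)
    u_pix <- u0 + jj * sp                 # per column
    z_pix <- z0 - jj * sp                 # per row (col_dir = -z)
    Umat <- matrix(u_pix, N, N, byrow = TRUE)
    Zmat <- matrix(z_pix, N, N)
    frames <- vector("list", P)
    p_sep <- matrix(NA_real_, P, 2); p_lat <- matrix(NA_real_, P, 2)
    for (n in seq_len(P)) {
      zf <- if (D > 0) profile$z_mm[n] / D else 0  # descent fraction
      z_lvl <- -profile$z_mm[n] + spec$saddle_height_mm * cos(2 * phi)
      img <- 0.15 +
        0.4 * stats::plogis((z_lvl - Zmat) / 3) * exp(-(Umat / (1.6 * R))^4) -
        0.12 * exp(-((abs(Umat) - (R + 6)) / 5)^2)
      for (side in c(1, -1)) {
        theta <- if (side > 0) phi else phi + pi
        z_ann <- z_lvl +
          spec$tilt_mm * zf * cos(theta - TILT_AZIMUTH)
        sway <- spec$sway_mm * zf * SWAY_DIR
        w <- c(side * R * u[1] + sway[1], side * R * u[2] + sway[2], z_ann)
        pr <- sum((w - origin) * col_dir) / sp
        pc <- sum((w - origin) * row_dir) / sp
        k <- pt_idx + if (side > 0) 1L else 2L
        img <- img + avj_blob(matrix(jj, N, N) - pr,
                              matrix(jj, N, N, byrow = TRUE) - pc,
                              tex_phase[k, 1], tex_phase[k, 2])
        if (side > 0) p_sep[n, ] <- c(pr, pc) else p_lat[n, ] <- c(pr, pc)
      }
      if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
      if (spec$noise_sigma > 0)
        img <- img + matrix(stats::rnorm(N * N, 0, spec$noise_sigma), N, N)
      frames[[n]] <- pmin(pmax(img, 0), 1)
    }
    pt_idx <- pt_idx + 2L
    views[[lab]] <- cine_view(frames, lab, origin, row_dir, col_dir,
                              c(sp, sp), spec$rr_ms)
    avj[[paste0(lab, "/septal")]] <- p_sep
    avj[[paste0(lab, "/lateral")]] <- p_lat
  }
  truth <- list(profile = profile,
                truth_curve = if (D > 0) phantom_truth_curve(spec, profile) else NULL,
                truth_params = if (D > 0) phantom_truth_params(spec, profile) else NULL,
                avj_pixels = avj)
  structure(list(study = study_geometry(unname(views)), truth = truth,
                 spec = spec),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("<phantom_study> P=%d, RR %.0f ms, R %.1f mm, descent %.1f mm, E:A %.2f\n",
              x$spec$n_phases, x$spec$rr_ms, x$spec$radius_mm,
              x$spec$systolic_descent_mm, x$truth$profile$ea_peak_ratio))
  invisible(x)
}

#' Seed pixels for tracking a phantom
#'
#' Rounded phase-0 ground-truth AVJ locations, in the format
#' [track_study()] expects.
#'
#' @param phantom a [render_views()] result.
#' @return named list (`"<view>/<point>"`) of integer `(row, col)` pairs.
#' @export
phantom_seed_pixels <- function(phantom) {
  lapply(phantom$truth$avj_pixels, function(m) round(m[1L, ]))
}

#' Rigid integer-translation test sequence
#'
#' A textured scene (seeded smoothed noise) observed through a fixed
#' window, translated by an integer pixel shift per phase — the standard
#' exactness benchmark for chained template tracking.
#'
#' @param shift_per_phase integer `(drow, dcol)` added each phase.
#' @param n_phases number of frames.
#' @param size_px window side.
#' @param seed texture seed.
#' @param rr_ms nominal RR (metadata only).
#' @return list with `view` (a [cine_view], axis-aligned geometry) and
#'   `trajectory(seed_pixel)` — a function returning the exact tracked
#'   trajectory for a 0-based seed.
#' @export
translating_view <- function(shift_per_phase, n_phases = 25L, size_px = 96L,
                             seed = 1L, rr_ms = 857) {
  shift_per_phase <- as.integer(round(shift_per_phase))
  pad <- max(abs(shift_per_phase)) * n_phases + 1L
  M <- size_px + 2L * pad
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  master <- gaussian_blur(matrix(stats::runif(M * M), M, M), 1.2)
  master <- (master - min(master)) / diff(range(master))
  frames <- lapply(seq_len(n_phases), function(n) {
    off <- (n - 1L) * shift_per_phase
    master[(pad + 1L - off[1]):(pad + size_px - off[1]),
           (pad + 1L - off[2]):(pad + size_px - off[2])]
  })
  view <- cine_view(frames, "four_chamber", c(0, 0, 0), c(1, 0, 0),
                    c(0, 1, 0), c(1, 1), rr_ms)
  list(view = view,
       trajectory = function(seed_pixel) {
         t(vapply(seq_len(n_phases) - 1L,
                  function(n) as.numeric(seed_pixel) + n * shift_per_phase,
                  numeric(2)))
       })
}
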