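#' Normalized sweep-volume recovery rate
#'
#' First derivative of the normalized sweep-volume curve, computed by
#' central differences on the periodic phase grid (spacing RR/P) and
#' sign-flipped so that diastolic recovery (the annulus returning toward
#' its end-diastolic position) is positive — the convention in which the
#' early-diastolic and atrial-systolic peaks are directly comparable. The
#' signed derivative of the normalized curve itself is retained in `deriv`.
#'
#' @param curve a [sweep_volume()] result.
#' @return object of class `sweep_rate`: `rate` (s^-1, positive during
#'   recovery), `deriv` (= -rate), `times_ms`.
#' @export
sweep_rate <- function(curve) {
  y <- curve$normalized
  P <- length(y)
  if (P < 5L) stop("at least 5 phases are required to differentiate")
  dt_s <- curve$rr_interval_ms / P / 1000
  ip <- c(2:P, 1L); im <- c(P, 1:(P - 1L))
  deriv <- (y[ip] - y[im]) / (2 * dt_s)
  structure(list(rate = -deriv, deriv = deriv, times_ms = curve$times_ms),
            class = "sweep_rate")
}

# discrete peak prominence (height above the higher of the two bases);
# O(n^2) is fine at cine phase counts
peak_prominence <- function(x, i) {
  n <- length(x)
  lo_l <- x[i]; j <- i - 1L
  while (j >= 1L && x[j] <= x[i]) { lo_l <- min(lo_l, x[j]); j <- j - 1L }
  if (j < 1L) lo_l <- min(x[seq_len(i)])
  lo_r <- x[i]; j <- i + 1L
  while (j <= n && x[j] <= x[i]) { lo_r <- min(lo_r, x[j]); j <- j + 1L }
  if (j > n) lo_r <- min(x[i:n])
  x[i] - max(lo_l, lo_r)
}

local_maxima <- function(x) {
  n <- length(x)
  which(vapply(seq_len(n), function(i) {
    (i == 1L || x[i] > x[i - 1L]) && (i == n || x[i] >= x[i + 1L])
  }, TRUE) & seq_len(n) > 1L & seq_len(n) < n)
}

local_minima <- function(x) local_maxima(-x)

# non-strict interior minima: on an exactly flat valley (e.g. the diastasis
# plateau of a noiseless curve) every plateau sample qualifies, so the
# first marks the valley entry and the last its exit
local_minima_nonstrict <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] <= x[i - 1L] & x[i] <= x[i + 1L]]
}

#' Segment the cardiac cycle on the sweep-volume curve
#'
#' Automatic realization of the slope-transition division of the cycle into
#' systole, early diastole (ED), mid-diastole (MD) and atrial systole (AS):
#' end-systole (ES) is the maximum of the cumulative curve; within diastole
#' the recovery-rate curve's local maxima with prominence at least
#' `prominence_frac` of the diastolic rate maximum are the E and A waves
#' (first and last qualifying peak); ED ends at the rate minimum after the
#' E peak and AS starts at the rate minimum immediately before the A peak,
#' with MD spanning between (possibly empty). Any boundary can be
#' overridden to reproduce a manual segmentation.
#'
#' @param curve a [sweep_volume()] result.
#' @param rate a [sweep_rate()] result (computed if missing).
#' @param override optional named list replacing any subset of
#'   `ed_onset_ms`, `ed_end_ms`, `md_end_ms`, `as_onset_ms`,
#'   `cycle_end_ms` (values in ms).
#' @param prominence_frac peak-prominence threshold as a fraction of the
#'   maximal diastolic rate (default 0.1).
#' @return object of class `interval_segmentation` with the boundary times
#'   (ms), `es_phase` (0-based), E/A peak times and indices, and `source`
#'   (`"automatic"` or `"manual"`).
#' @export
segment_intervals <- function(curve, rate = sweep_rate(curve),
                              override = NULL, prominence_frac = 0.1) {
  y <- curve$normalized
  P <- length(y)
  t_ms <- curve$times_ms
  rr <- curve$rr_interval_ms
  # end-systole: last index of the (contiguous) run attaining the maximum —
  # pixel-quantized tracking can hold the curve flat for a phase or two
  imax <- which(y == max(y))
  if (length(imax) > 1L && any(diff(imax) != 1L))
    stop("cumulative sweep curve has no unique maximum")
  ies <- imax[length(imax)]
  r <- rate$rate
  bnames <- c("ed_onset_ms", "ed_end_ms", "md_end_ms", "as_onset_ms",
              "cycle_end_ms")
  if (!is.null(override) && all(bnames %in% names(override))) {
    # fully manual division: no automatic wave detection needed
    b <- override[bnames]
    return(finish_segmentation(b, "manual", ies, t_ms, r, rr))
  }
  win <- ies:P  # diastole: from ES sample to last sample
  rw <- r[win]
  cand <- local_maxima(rw)
  rmax <- max(rw)
  cand <- cand[vapply(cand, function(i) peak_prominence(rw, i), 0) >=
                 prominence_frac * rmax]
  if (length(cand) < 2L)
    stop("E/A fusion - manual segmentation required (",
         length(cand), " qualifying diastolic rate peak(s))")
  ie <- win[cand[1L]]
  ia <- win[cand[length(cand)]]
  between <- r[ie:ia]
  mins <- local_minima_nonstrict(between)
  if (!length(mins)) mins <- which.min(between[-c(1, length(between))]) + 1L
  ied_end <- ie + mins[1L] - 1L
  ias_on <- ie + mins[length(mins)] - 1L
  b <- list(ed_onset_ms = t_ms[ies], ed_end_ms = t_ms[ied_end],
            md_end_ms = t_ms[ias_on], as_onset_ms = t_ms[ias_on],
            cycle_end_ms = rr)
  src <- "automatic"
  if (!is.null(override) && length(override)) {
    bad <- setdiff(names(override), names(b))
    if (length(bad)) stop("unknown boundary override(s): ",
                          paste(bad, collapse = ", "))
    b[names(override)] <- override
    src <- "manual"
  }
  finish_segmentation(b, src, ies, t_ms, r, rr,
                      e_index = ie, a_index = ia)
}

# validate boundaries and assemble the segmentation object; E/A peak
# indices default to the rate argmax within the ED and AS windows
finish_segmentation <- function(b, src, ies, t_ms, r, rr,
                                e_index = NULL, a_index = NULL) {
  if (!(0 < b$ed_onset_ms && b$ed_onset_ms < b$ed_end_ms &&
        b$ed_end_ms <= b$md_end_ms && b$md_end_ms <= b$as_onset_ms &&
        b$as_onset_ms < b$cycle_end_ms && b$cycle_end_ms <= rr + 1e-9))
    stop("inconsistent interval boundaries: require 0 < ED onset < ED end ",
         "<= MD end <= AS onset < cycle end <= RR")
  if (is.null(e_index)) {
    w <- which(t_ms >= b$ed_onset_ms - 1e-9 & t_ms <= b$ed_end_ms + 1e-9)
    e_index <- w[which.max(r[w])]
  }
  if (is.null(a_index)) {
    w <- which(t_ms >= b$as_onset_ms - 1e-9 & t_ms <= b$cycle_end_ms + 1e-9)
    a_index <- w[which.max(r[w])]
  }
  structure(c(b, list(es_phase = ies - 1L,
                      e_peak_ms = t_ms[e_index], a_peak_ms = t_ms[a_index],
                      e_peak_index = e_index - 1L, a_peak_index = a_index - 1L,
                      source = src)),
            class = "interval_segmentation")
}

#' @export
print.interval_segmentation <- function(x, ...) {
  cat(sprintf(paste0("<interval_segmentation> (%s) ES %.0f ms | ED %.0f-%.0f",
                     " | MD %.0f-%.0f | AS %.0f-%.0f ms\n"),
              x$source, x$ed_onset_ms, x$ed_onset_ms, x$ed_end_ms,
              x$ed_end_ms, x$as_onset_ms, x$as_onset_ms, x$cycle_end_ms))
  invisible(x)
}

# linear-interpolated first time (after index i0) at which y crosses `level`
# downward; NA if never
first_crossing_after <- function(t_ms, y, i0, level) {
  for (i in (i0 + 1L):length(y)) {
    if (y[i] <= level) {
      if (y[i] == level || y[i - 1L] == y[i]) return(t_ms[i])
      f <- (y[i - 1L] - level) / (y[i - 1L] - y[i])
      return(t_ms[i - 1L] + f * (t_ms[i] - t_ms[i - 1L]))
    }
  }
  NA_real_
}

#' Compute the diastolic-function parameters
#'
#' Derives all sweep-volume diastolic indices from the normalized curve,
#' its recovery rate and the interval segmentation:
#' \itemize{
#'   \item `psr_e`, `psr_a` — normalized peak sweep rates in early diastole
#'     and atrial systole (s^-1), and their ratio `psr_ratio` (the analogue
#'     of the tissue-Doppler e'/a' ratio); absolute versions in cm^3/s.
#'   \item `avg_rate_ed`, `avg_rate_md`, `avg_rate_as` — mean normalized
#'     rates per interval (s^-1).
#'   \item `pct_recovery_ed`, `pct_recovery_as` — percentage of the
#'     end-systolic sweep volume recovered over each interval (interval
#'     endpoint values of the normalized curve), with absolute volumes in
#'     cm^3.
#'   \item `at_sv_ms` — time from ED onset to the E-wave rate peak.
#'   \item `dt_sv_ms` — deceleration time: a least-squares line through the
#'     descending rate samples from the E peak to the following rate
#'     minimum, extrapolated to baseline (zero rate), measured from the
#'     peak time.
#'   \item `dsvrt50_pct_rr` — time after end-systole for the normalized
#'     curve to first fall through `recovery_threshold` (linear
#'     interpolation), as a percentage of the RR interval; `NA` with a QC
#'     flag when recovery is incomplete.
#' }
#'
#' @param curve a [sweep_volume()] result.
#' @param rate a [sweep_rate()] (computed if missing).
#' @param seg an [interval_segmentation][segment_intervals()] (automatic if
#'   missing).
#' @param stroke_volume_ml optional LV stroke volume (mL); when supplied the
#'   interval sweep volumes are also reported as percentages of it.
#' @param recovery_threshold recovery fraction defining the recovery-time
#'   index (default 0.5, i.e. DSVRT_50).
#' @return object of class `diastolic_params` (see
#'   [as.data.frame.diastolic_params()]).
#' @export
compute_parameters <- function(curve, rate = sweep_rate(curve),
                               seg = segment_intervals(curve, rate),
                               stroke_volume_ml = NULL,
                               recovery_threshold = 0.5) {
  t_ms <- curve$times_ms
  y <- curve$normalized
  r <- rate$rate
  rr <- curve$rr_interval_ms
  essv_cm3 <- curve$essv_mm3 / 1000
  flags <- character(0)

  in_win <- function(a, b) which(t_ms >= a - 1e-9 & t_ms <= b + 1e-9)
  ed <- in_win(seg$ed_onset_ms, seg$ed_end_ms)
  as_ <- in_win(seg$as_onset_ms, seg$cycle_end_ms)
  md <- which(t_ms > seg$ed_end_ms + 1e-9 & t_ms < seg$as_onset_ms - 1e-9)

  ie <- ed[which.max(r[ed])]
  psr_e <- r[ie]
  psr_a <- max(r[as_])
  at_sv <- t_ms[ie] - seg$ed_onset_ms

  norm_at <- function(tt) stats::approx(t_ms, y, xout = tt, rule = 2)$y
  norm_cycle_end <- y[length(y)] + curve$closure_mm3 / curve$essv_mm3
  pct_ed <- 100 * (norm_at(seg$ed_onset_ms) - norm_at(seg$ed_end_ms))
  pct_as <- 100 * (norm_at(seg$as_onset_ms) - norm_cycle_end)
  pct_md <- 100 * (norm_at(seg$ed_end_ms) - norm_at(seg$as_onset_ms))

  # DT_SV: least-squares line on the monotone descending limb E peak -> min
  after <- r[ie:length(r)]
  mins <- local_minima(after)
  imin <- if (length(mins)) ie + mins[1L] - 1L else length(r)
  limb <- ie:imin
  dt_sv <- NA_real_
  if (length(limb) >= 2L) {
    fit <- stats::lm.fit(cbind(1, t_ms[limb]), r[limb])
    slope <- unname(fit$coefficients[2L])
    if (is.finite(slope) && slope < 0)
      dt_sv <- unname(-fit$coefficients[1L]) / slope - t_ms[ie]
  }
  if (!is.finite(dt_sv)) {
    dt_sv <- NA_real_
    flags <- c(flags, "dt_sv_undefined")
  }

  t50 <- first_crossing_after(t_ms, y, seg$es_phase + 1L, recovery_threshold)
  if (is.na(t50)) {
    flags <- c(flags, "incomplete_recovery")
    dsvrt <- NA_real_
  } else dsvrt <- 100 * (t50 - seg$ed_onset_ms) / rr

  out <- list(
    psr_e = psr_e, psr_a = psr_a, psr_ratio = psr_e / psr_a,
    psr_e_abs_cm3s = psr_e * essv_cm3, psr_a_abs_cm3s = psr_a * essv_cm3,
    avg_rate_ed = mean(r[ed]),
    avg_rate_md = if (length(md)) mean(r[md]) else NA_real_,
    avg_rate_as = mean(r[as_]),
    pct_recovery_ed = pct_ed, pct_recovery_as = pct_as,
    pct_recovery_md = pct_md,
    abs_sweep_ed_cm3 = pct_ed * essv_cm3 / 100,
    abs_sweep_as_cm3 = pct_as * essv_cm3 / 100,
    at_sv_ms = at_sv, dt_sv_ms = dt_sv, dsvrt50_pct_rr = dsvrt,
    essv_cm3 = essv_cm3, rr_interval_ms = rr,
    sweep_over_sv_ed_pct = NA_real_, sweep_over_sv_as_pct = NA_real_,
    qc_flags = flags, segmentation = seg)
  if (!is.null(stroke_volume_ml)) {
    out$sweep_over_sv_ed_pct <- 100 * out$abs_sweep_ed_cm3 / stroke_volume_ml
    out$sweep_over_sv_as_pct <- 100 * out$abs_sweep_as_cm3 / stroke_volume_ml
  }
  structure(out, class = "diastolic_params")
}

#' @export
print.diastolic_params <- function(x, ...) {
  cat("<diastolic_params>\n")
  cat(sprintf("  PSR_E %.2f /s  PSR_A %.2f /s  PSR_E/PSR_A %.2f\n",
              x$psr_e, x$psr_a, x$psr_ratio))
  cat(sprintf("  recovery ED %.1f%%  AS %.1f%%   ESSV %.1f cm3\n",
              x$pct_recovery_ed, x$pct_recovery_as, x$essv_cm3))
  cat(sprintf("  AT_SV %.0f ms  DT_SV %.0f ms  DSVRT_50 %.1f %%RR\n",
              x$at_sv_ms, x$dt_sv_ms, x$dsvrt50_pct_rr))
  if (length(x$qc_flags))
    cat("  QC flags:", paste(x$qc_flags, collapse = ", "), "\n")
  invisible(x)
}

#' One-row data frame of diastolic parameters
#'
#' @param x a `diastolic_params` object.
#' @param ... unused.
#' @return a one-row data.frame (the per-subject export format), including
#'   the segmentation boundaries and QC flags.
#' @export
as.data.frame.diastolic_params <- function(x, ...) {
  seg <- x$segmentation
  data.frame(
    psr_e = x$psr_e, psr_a = x$psr_a, psr_ratio = x$psr_ratio,
    psr_e_abs_cm3s = x$psr_e_abs_cm3s, psr_a_abs_cm3s = x$psr_a_abs_cm3s,
    avg_rate_ed = x$avg_rate_ed, avg_rate_md = x$avg_rate_md,
    avg_rate_as = x$avg_rate_as,
    pct_recovery_ed = x$pct_recovery_ed, pct_recovery_as = x$pct_recovery_as,
    abs_sweep_ed_cm3 = x$abs_sweep_ed_cm3,
    abs_sweep_as_cm3 = x$abs_sweep_as_cm3,
    at_sv_ms = x$at_sv_ms, dt_sv_ms = x$dt_sv_ms,
    dsvrt50_pct_rr = x$dsvrt50_pct_rr,
    sweep_over_sv_ed_pct = x$sweep_over_sv_ed_pct,
    sweep_over_sv_as_pct = x$sweep_over_sv_as_pct,
    essv_cm3 = x$essv_cm3, rr_interval_ms = x$rr_interval_ms,
    ed_onset_ms = seg$ed_onset_ms, ed_end_ms = seg$ed_end_ms,
    as_onset_ms = seg$as_onset_ms, cycle_end_ms = seg$cycle_end_ms,
    seg_source = seg$source,
    qc_flags = paste(x$qc_flags, collapse = ";"))
}

#' Plot the normalized sweep-volume curve and its rate
#'
#' Two stacked panels with the cardiac intervals shaded: the normalized
#' sweep-volume curve (top) and the recovery rate with the E and A peaks
#' marked (bottom).
#'
#' @param curve a [sweep_volume()] result.
#' @param rate a [sweep_rate()].
#' @param seg an [interval_segmentation][segment_intervals()].
#' @return invisibly, `NULL`.
#' @export
plot_sweep_curve <- function(curve, rate = sweep_rate(curve),
                             seg = segment_intervals(curve, rate)) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  shade <- function() {
    cols <- c(grDevices::adjustcolor("steelblue", 0.15),
              grDevices::adjustcolor("gray", 0.15),
              grDevices::adjustcolor("indianred", 0.15))
    xs <- c(seg$ed_onset_ms, seg$ed_end_ms, seg$as_onset_ms, seg$cycle_end_ms)
    for (i in 1:3)
      graphics::rect(xs[i], graphics::par("usr")[3], xs[i + 1],
                     graphics::par("usr")[4], col = cols[i], border = NA)
  }
  plot(curve$times_ms, curve$normalized, type = "l", lwd = 2,
       xlab = "time (ms)", ylab = "normalized sweep volume",
       main = "MA sweep volume")
  shade()
  graphics::lines(curve$times_ms, curve$normalized, lwd = 2)
  plot(rate$times_ms, rate$rate, type = "l", lwd = 2,
       xlab = "time (ms)", ylab = "recovery rate (1/s)",
       main = "MA sweep rate")
  shade()
  graphics::lines(rate$times_ms, rate$rate, lwd = 2)
  graphics::points(c(seg$e_peak_ms, seg$a_peak_ms),
                   rate$rate[c(seg$e_peak_index, seg$a_peak_index) + 1L],
                   pch = 19, col = "firebrick")
  invisible(NULL)
}
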