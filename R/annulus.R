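#' Order six annulus points circumferentially
#'
#' The six tracked 3D points (two per long-axis view) arrive labelled but in
#' arbitrary order; the closed interpolating spline needs them in
#' circumferential order. Points are sorted by angle around their centroid
#' in the least-squares plane, counter-clockwise about the plane normal,
#' starting at the septal point of the four-chamber view when that label is
#' present (otherwise at the first input point). The normal's sign is fixed
#' deterministically (largest-magnitude component positive).
#'
#' @param points n x 3 matrix (n >= 4) of 3D points (mm); row names are the
#'   point labels, conventionally `"<view_label>/<point_label>"`.
#' @return the same matrix with rows reordered; attributes `centroid` and
#'   `plane_normal`.
#' @export
order_annulus_points <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 4L) stop("at least four points are required")
  dd <- as.matrix(stats::dist(points))
  if (min(dd[upper.tri(dd)]) <= 1e-6)
    stop("coincident annulus points (pairwise separation <= 1e-6 mm)")
  ctr <- colMeans(points)
  rel <- sweep(points, 2L, ctr)
  sv <- svd(rel)
  if (sv$d[2] < 1e-6 * sv$d[1])
    stop("near-collinear annulus points: plane fit is degenerate")
  nrm <- sv$v[, 3L]
  k <- which.max(abs(nrm))
  if (nrm[k] < 0) nrm <- -nrm
  # in-plane basis completing nrm; angles measured CCW about nrm
  e1 <- sv$v[, 1L]
  e2 <- pracma::cross(nrm, e1)
  ang <- atan2(rel %*% e2, rel %*% e1)[, 1L]
  ord <- order(ang)
  start_lab <- "four_chamber/septal"
  labs <- rownames(points)
  s <- if (!is.null(labs) && start_lab %in% labs)
    which(labs[ord] == start_lab) else 1L
  ord <- ord[((seq_len(n) + s - 2L) %% n) + 1L]
  out <- points[ord, , drop = FALSE]
  attr(out, "centroid") <- ctr
  attr(out, "plane_normal") <- nrm
  out
}

#' Interpolate an ordered ring with a closed 3D spline
#'
#' Fits a periodic cubic spline through the ordered points,
#' chord-length parameterized, and resamples it at uniform parameter
#' values. The curve passes through every input point and is closed: the
#' last sample repeats the first.
#'
#' @param ring ordered m x 3 matrix (m >= 4) of 3D points.
#' @param n_samples number of samples of the closed curve (the last
#'   duplicates the first; default 120).
#' @return n_samples x 3 matrix of curve samples.
#' @export
interpolate_annulus <- function(ring, n_samples = 120L) {
  ring <- as.matrix(ring)
  m <- nrow(ring)
  if (m < 4L) stop("at least four points are required")
  closed <- rbind(ring, ring[1L, ])
  chords <- sqrt(rowSums(diff(closed)^2))
  if (any(chords <= 1e-9)) stop("coincident consecutive points")
  u <- c(0, cumsum(chords))
  uu <- seq(0, u[m + 1L], length.out = n_samples)
  vapply(1:3, function(k) {
    stats::spline(u, closed[, k], method = "periodic", xout = uu)$y
  }, numeric(n_samples))
}

#' Area, centroid and best-fit plane of a closed annulus curve
#'
#' The centroid is the mean of the (unique) curve samples. The area is the
#' triangle fan about the centroid with each triangle's signed area taken
#' along the least-squares plane normal, then the absolute total — a
#' definition that reduces exactly to the polygon area in the planar limit
#' and converges for mildly saddle-shaped annuli.
#'
#' @param curve closed n x 3 curve (last sample may repeat the first).
#' @return list with `area_mm2`, `centroid`, `plane_normal` (unit).
#' @export
annulus_area_centroid <- function(curve) {
  curve <- as.matrix(curve)
  n <- nrow(curve)
  if (n >= 2L && sqrt(sum((curve[1L, ] - curve[n, ])^2)) < 1e-9)
    curve <- curve[-n, , drop = FALSE]
  n <- nrow(curve)
  if (n < 3L) stop("degenerate curve")
  ctr <- colMeans(curve)
  rel <- sweep(curve, 2L, ctr)
  sv <- svd(rel)
  nrm <- sv$v[, 3L]
  k <- which.max(abs(nrm))
  if (nrm[k] < 0) nrm <- -nrm
  nxt <- c(2:n, 1L)
  cr <- cbind(rel[, 2] * rel[nxt, 3] - rel[, 3] * rel[nxt, 2],
              rel[, 3] * rel[nxt, 1] - rel[, 1] * rel[nxt, 3],
              rel[, 1] * rel[nxt, 2] - rel[, 2] * rel[nxt, 1])
  area <- abs(sum(0.5 * (cr %*% nrm)))
  if (area <= 1e-9) stop("degenerate (zero-area) curve")
  list(area_mm2 = area, centroid = ctr, plane_normal = nrm)
}

#' Build one annulus frame from six labelled 3D points
#'
#' Orders the points, interpolates the closed spline, and computes area,
#' centroid and plane normal.
#'
#' @param points6 6 x 3 labelled matrix of 3D points (mm).
#' @param phase 0-based phase index (metadata).
#' @param n_samples spline samples (default 120).
#' @return object of class `annulus_frame`.
#' @export
annulus_frame <- function(points6, phase = 0L, n_samples = 120L) {
  ring <- order_annulus_points(points6)
  curve <- interpolate_annulus(ring, n_samples)
  g <- annulus_area_centroid(curve)
  structure(list(phase = as.integer(phase), points6 = ring, curve = curve,
                 area_mm2 = g$area_mm2, centroid = g$centroid,
                 plane_normal = g$plane_normal),
            class = "annulus_frame")
}

#' @export
print.annulus_frame <- function(x, ...) {
  cat(sprintf("<annulus_frame> phase %d: area %.1f mm2, centroid (%.1f, %.1f, %.1f)\n",
              x$phase, x$area_mm2, x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Reconstruct the annulus at every phase from tracked points
#'
#' Maps each view's two tracked pixel trajectories into patient coordinates
#' and fuses the six points per phase into [annulus_frame]s. Plane normals
#' are sign-aligned across phases so consecutive normals have positive dot
#' product.
#'
#' @param study a [study_geometry].
#' @param tracks named list of six `track_result`s (two per view), names
#'   `"<view>/<point>"`.
#' @param n_samples spline samples per frame.
#' @return list of P `annulus_frame`s.
#' @export
reconstruct_annulus <- function(study, tracks, n_samples = 120L) {
  P <- study$n_phases
  if (length(tracks) != 6L) stop("six tracks are required (two per view)")
  pts3d <- lapply(names(tracks), function(key) {
    tr <- tracks[[key]]
    v <- study$views[[tr$view_label]]
    pixel_to_patient(v, tr$pixels)
  })
  frames <- lapply(seq_len(P), function(i) {
    p6 <- t(vapply(pts3d, function(m) m[i, ], numeric(3)))
    rownames(p6) <- names(tracks)
    annulus_frame(p6, phase = i - 1L, n_samples = n_samples)
  })
  for (i in seq_along(frames)[-1L]) {
    if (sum(frames[[i]]$plane_normal * frames[[i - 1L]]$plane_normal) < 0)
      frames[[i]]$plane_normal <- -frames[[i]]$plane_normal
  }
  frames
}

#' Estimate the apex-directed long axis from annulus frames
#'
#' The long axis is the end-diastolic best-fit plane normal, sign-oriented
#' so that the annular centroid's largest excursion over the cycle (the
#' systolic descent toward the apex) projects positively onto it. A fixed
#' axis avoids sign flips from frame-to-frame normal jitter.
#'
#' @param frames list of [annulus_frame]s in phase order.
#' @return unit 3-vector.
#' @export
estimate_long_axis <- function(frames) {
  n <- frames[[1L]]$plane_normal
  c0 <- frames[[1L]]$centroid
  proj <- vapply(frames, function(f) sum((f$centroid - c0) * n), 0)
  k <- which.max(abs(proj))
  if (length(k) && proj[k] < 0) n <- -n
  n
}

#' Accumulate the 3D sweep-volume curve
#'
#' For phases n = 1..P-1, the incremental volume is the swept-slab
#' (frustum) approximation `V_n = (A_{n-1} + A_n)/2 * d_n`, where `d_n` is
#' the signed displacement of the annular centroid along the fixed
#' apex-directed long axis. The net sweep volume is the running sum from
#' end-diastole (phase 0, cumulative 0); its maximum is the end-systolic
#' sweep volume (ESSV), the normalization denominator. The increment that
#' would close phase P-1 back to phase 0 is computed and reported as
#' `closure_mm3` (a tracking-drift diagnostic) but not added to the curve.
#'
#' @param frames list of >= 3 [annulus_frame]s in phase order.
#' @param rr_interval_ms cardiac cycle length (ms).
#' @param long_axis apex-directed unit vector; default
#'   [estimate_long_axis()].
#' @return object of class `sweep_curve` with fields `increments_mm3`
#'   (length P-1), `cumulative_mm3` (length P, starts at 0), `closure_mm3`,
#'   `essv_mm3`, `normalized`, `times_ms`, `es_phase` (0-based),
#'   `rr_interval_ms`, `long_axis`, `areas_mm2`, `centroids`.
#' @export
sweep_volume <- function(frames, rr_interval_ms,
                         long_axis = estimate_long_axis(frames)) {
  P <- length(frames)
  if (P < 3L) stop("at least three frames are required")
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  areas <- vapply(frames, `[[`, 0, "area_mm2")
  ctrs <- t(vapply(frames, `[[`, numeric(3), "centroid"))
  z <- as.numeric(ctrs %*% long_axis)
  d <- diff(z)
  inc <- 0.5 * (areas[-P] + areas[-1L]) * d
  cumu <- c(0, cumsum(inc))
  closure <- 0.5 * (areas[P] + areas[1L]) * (z[1L] - z[P])
  essv <- max(cumu)
  if (essv <= 0)
    stop("no systolic excursion: the annulus never descends along the long axis")
  structure(list(increments_mm3 = inc, cumulative_mm3 = cumu,
                 closure_mm3 = closure, essv_mm3 = essv,
                 normalized = cumu / essv,
                 times_ms = (seq_len(P) - 1) * rr_interval_ms / P,
                 es_phase = which.max(cumu) - 1L,
                 rr_interval_ms = rr_interval_ms,
                 long_axis = long_axis, areas_mm2 = areas,
                 centroids = ctrs),
            class = "sweep_curve")
}

#' @export
print.sweep_curve <- function(x, ...) {
  cat(sprintf("<sweep_curve> %d phases, ESSV %.2f cm3 at phase %d, closure residual %.2f cm3\n",
              length(x$cumulative_mm3), x$essv_mm3 / 1000, x$es_phase,
              x$closure_mm3 / 1000))
  invisible(x)
}

#' Per-phase geometry table
#'
#' One row per phase: time, annular area, centroid, incremental and
#' cumulative sweep volumes and the normalized curve — the per-phase CSV
#' export format.
#'
#' @param curve a [sweep_volume()] result.
#' @return a data.frame with P rows.
#' @export
sweep_table <- function(curve) {
  P <- length(curve$cumulative_mm3)
  data.frame(phase = seq_len(P) - 1L,
             time_ms = curve$times_ms,
             area_mm2 = curve$areas_mm2,
             centroid_x = curve$centroids[, 1],
             centroid_y = curve$centroids[, 2],
             centroid_z = curve$centroids[, 3],
             increment_mm3 = c(NA, curve$increments_mm3),
             cumulative_mm3 = curve$cumulative_mm3,
             normalized = curve$normalized)
}
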