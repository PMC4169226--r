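#' Tracking configuration
#'
#' Window sizes follow the published recipe of a 20-pixel template square
#' matched inside a 40-pixel search square; both are realized as odd,
#' centered windows (21 and 41) so the tracked point is a true window
#' center. Tracking quality was reported as insensitive to the precise
#' window size.
#'
#' @param template_px template side in pixels (rounded up to odd; >= 5).
#' @param roi_px search-region side in pixels (rounded up to odd; must
#'   exceed `template_px`).
#' @param min_corr correlation floor in `[-1, 1]`; phases whose peak NCC
#'   falls below it are flagged for review (stands in for interactive
#'   visual QC in batch runs).
#' @param subpixel logical; if `TRUE`, refine the argmax with a 3-point
#'   parabolic fit per axis (default `FALSE`: pixel-level localization).
#' @return object of class `track_config`.
#' @export
track_config <- function(template_px = 21L, roi_px = 41L, min_corr = 0.5,
                         subpixel = FALSE) {
  odd <- function(k) { k <- as.integer(k); if (k %% 2L == 0L) k + 1L else k }
  template_px <- odd(template_px); roi_px <- odd(roi_px)
  if (template_px < 5L) stop("template_px must be >= 5")
  if (roi_px <= template_px) stop("roi_px must exceed template_px")
  if (min_corr < -1 || min_corr > 1) stop("min_corr must lie in [-1, 1]")
  structure(list(template_px = template_px, roi_px = roi_px,
                 min_corr = min_corr, subpixel = isTRUE(subpixel)),
            class = "track_config")
}

#' Normalized cross-correlation template match
#'
#' Slides `template` over every fully contained placement inside
#' `search_region` and computes the zero-mean normalized correlation
#' coefficient (Pearson correlation of intensities) at each placement. The
#' argmax placement, expressed relative to the centered placement, is the
#' estimated displacement. Ties are broken toward the first occurrence in
#' row-major order. Placements with zero intensity variance get coefficient
#' `-Inf` and are never selected.
#'
#' @param template numeric matrix, strictly smaller than `search_region` in
#'   both dimensions, with nonzero intensity variance.
#' @param search_region numeric matrix.
#' @return list with `displacement` `(drow, dcol)`, `peak_corr`, and the
#'   full `corr_map` matrix (placements by top-left offset).
#' @export
ncc_match <- function(template, search_region) {
  th <- nrow(template); tw <- ncol(template)
  sh <- nrow(search_region); sw <- ncol(search_region)
  if (th >= sh || tw >= sw)
    stop("template must be strictly smaller than search_region")
  tv <- as.numeric(template) - mean(template)
  tnorm <- sqrt(sum(tv^2))
  if (tnorm < 1e-12 * max(1, abs(mean(template))))
    stop("untrackable feature: template has zero intensity variance")
  nr <- sh - th + 1L; nc <- sw - tw + 1L
  n <- th * tw
  # stack all candidate patches as columns, then one crossprod
  patches <- matrix(0, n, nr * nc)
  k <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      k <- k + 1L
      patches[, k] <- search_region[i:(i + th - 1L), j:(j + tw - 1L)]
    }
  }
  pm <- colMeans(patches)
  patches <- sweep(patches, 2L, pm)
  pnorm <- sqrt(colSums(patches^2))
  cc <- as.numeric(crossprod(tv, patches))
  corr <- ifelse(pnorm < 1e-12, -Inf, cc / (tnorm * pnorm))
  corr_map <- matrix(corr, nr, nc)  # filled column-wise: [i, j]
  # row-major first occurrence among ties
  best <- Inf; bi <- 1L; bj <- 1L; bc <- -Inf
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (corr_map[i, j] > bc) { bc <- corr_map[i, j]; bi <- i; bj <- j }
  }
  c0 <- c((sh - th) %/% 2L + 1L, (sw - tw) %/% 2L + 1L)
  disp <- c(bi, bj) - c0
  list(displacement = c(drow = disp[1], dcol = disp[2]),
       peak_corr = bc, corr_map = corr_map)
}

# 3-point parabolic vertex offset in (-0.5, 0.5); 0 at map edges/degenerate
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || den >= 0 || !is.finite(ym1) || !is.finite(yp1))
    return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(min(off, 0.5), -0.5)
}

# clamp a window of odd side `side` centered at `center` (1-based) into
# [1, limit]; returns c(lo, hi, anchor_offset_of_center_within_window)
clamp_window <- function(center, side, limit) {
  h <- (side - 1L) %/% 2L
  lo <- center - h; hi <- center + h
  if (lo < 1L) { hi <- min(hi + (1L - lo), limit); lo <- 1L }
  if (hi > limit) { lo <- max(1L, lo - (hi - limit)); hi <- limit }
  c(lo, hi, center - lo + 1L)
}

#' Track one AVJ point across the cardiac cycle
#'
#' Chained template tracking: the template centered at the phase-n position
#' is matched by [ncc_match()] inside the larger region of interest at the
#' same location in phase n+1; the correlation peak gives the phase-n+1
#' position, which seeds the next step. The chain runs once through all P
#' phases without wrapping. Phases whose peak correlation falls below
#' `config$min_corr` are flagged.
#'
#' @param view a [cine_view].
#' @param seed_pixel 0-based `(row, col)` of the point at phase 0.
#' @param config a [track_config()].
#' @param point_label `"septal"` or `"lateral"` (metadata only).
#' @return object of class `track_result`: `pixels` (P x 2, 0-based),
#'   `corr` (length P; phase 0 has correlation 1 by definition),
#'   `flagged_phases` (0-based indices with `corr < min_corr`),
#'   `corrected_phases` (empty here; see [correct_and_retrack()]).
#' @export
track_point <- function(view, seed_pixel, config = track_config(),
                        point_label = c("septal", "lateral")) {
  point_label <- match.arg(point_label)
  d <- frame_dim(view)
  seed <- round(as.numeric(seed_pixel)) + 1  # to 1-based integer pixels
  if (any(seed < 1) || seed[1] > d[1] || seed[2] > d[2])
    stop("seed pixel outside image bounds")
  h <- (config$template_px - 1L) %/% 2L
  if (d[1] < config$template_px || d[2] < config$template_px)
    stop("image too small for template support")
  P <- view$n_phases
  pixels <- matrix(NA_real_, P, 2L, dimnames = list(NULL, c("row", "col")))
  corr <- numeric(P)
  pixels[1L, ] <- seed
  corr[1L] <- 1
  pos <- seed
  for (ph in seq_len(P - 1L)) {
    st <- step_match(view$frames[[ph]], view$frames[[ph + 1L]], pos, config)
    pos <- st$pos
    pixels[ph + 1L, ] <- pos
    corr[ph + 1L] <- st$peak_corr
  }
  flagged <- which(corr < config$min_corr) - 1L
  structure(list(view_label = view$view_label, point_label = point_label,
                 pixels = pixels - 1,  # back to 0-based
                 corr = corr, flagged_phases = flagged,
                 corrected_phases = integer(0), config = config),
            class = "track_result")
}

# one NCC chaining step; pos is 1-based integer (row, col) in frame_a
step_match <- function(frame_a, frame_b, pos, config) {
  d <- dim(frame_a)
  ipos <- round(pos)
  wr <- clamp_window(ipos[1], config$template_px, d[1])
  wc <- clamp_window(ipos[2], config$template_px, d[2])
  template <- frame_a[wr[1]:wr[2], wc[1]:wc[2]]
  rr <- clamp_window(ipos[1], config$roi_px, d[1])
  rc <- clamp_window(ipos[2], config$roi_px, d[2])
  roi <- frame_b[rr[1]:rr[2], rc[1]:rc[2]]
  m <- ncc_match(template, roi)
  bm <- which(m$corr_map == m$peak_corr, arr.ind = TRUE)
  # first occurrence row-major
  bm <- bm[order(bm[, 1], bm[, 2]), , drop = FALSE][1L, ]
  newpos <- c(rr[1] + bm[1] - 1L + wr[3] - 1L,
              rc[1] + bm[2] - 1L + wc[3] - 1L)
  if (config$subpixel) {
    cm <- m$corr_map
    i <- bm[1]; j <- bm[2]
    dr <- if (i > 1 && i < nrow(cm))
      parabolic_offset(cm[i - 1, j], cm[i, j], cm[i + 1, j]) else 0
    dc <- if (j > 1 && j < ncol(cm))
      parabolic_offset(cm[i, j - 1], cm[i, j], cm[i, j + 1]) else 0
    newpos <- newpos + c(dr, dc)
  }
  list(pos = newpos, peak_corr = m$peak_corr)
}

#' @export
print.track_result <- function(x, ...) {
  cat(sprintf("<track_result> %s/%s: %d phases, mean corr %.3f, %d flagged, %d corrected\n",
              x$view_label, x$point_label, nrow(x$pixels), mean(x$corr),
              length(x$flagged_phases), length(x$corrected_phases)))
  invisible(x)
}

#' Apply a manual correction and re-track subsequent phases
#'
#' Replays the interactive correction workflow: the position at `phase` is
#' replaced by `new_pixel`, positions at earlier phases are untouched, and
#' tracking is re-run by chained NCC from the corrected location through the
#' remaining phases.
#'
#' @param result a [track_result][track_point()].
#' @param view the [cine_view] it was tracked in.
#' @param phase 0-based phase index of the correction.
#' @param new_pixel corrected 0-based `(row, col)`.
#' @param config a [track_config()]; defaults to the one stored in `result`.
#' @return an updated `track_result` with `phase` added to
#'   `corrected_phases`.
#' @export
correct_and_retrack <- function(result, view, phase, new_pixel,
                                config = result$config) {
  P <- view$n_phases
  if (phase < 0 || phase >= P) stop("phase out of range")
  d <- frame_dim(view)
  np <- round(as.numeric(new_pixel)) + 1
  if (any(np < 1) || np[1] > d[1] || np[2] > d[2])
    stop("corrected pixel outside image bounds")
  pixels <- result$pixels + 1
  corr <- result$corr
  i <- phase + 1L
  pixels[i, ] <- np
  pos <- np
  if (i < P) {
    for (ph in i:(P - 1L)) {
      st <- step_match(view$frames[[ph]], view$frames[[ph + 1L]], pos, config)
      pos <- st$pos
      pixels[ph + 1L, ] <- pos
      corr[ph + 1L] <- st$peak_corr
    }
  }
  result$pixels <- pixels - 1
  result$corr <- corr
  result$flagged_phases <- which(corr < config$min_corr) - 1L
  result$corrected_phases <- sort(unique(c(result$corrected_phases,
                                           as.integer(phase))))
  result$config <- config
  result
}

#' Apply a corrections file to a set of track results
#'
#' Corrections come as a JSON list of
#' `{view, point, phase, row, col}` records (the scriptable replacement for
#' interactive clicking); they are applied in phase order per track via
#' [correct_and_retrack()].
#'
#' @param tracks named list of `track_result`s, names `"<view>/<point>"`.
#' @param study the [study_geometry] they came from.
#' @param corrections data frame or path to a JSON file with columns
#'   `view`, `point`, `phase`, `row`, `col`.
#' @return the updated list of tracks.
#' @export
apply_corrections <- function(tracks, study, corrections) {
  if (is.character(corrections))
    corrections <- jsonlite::read_json(corrections, simplifyVector = TRUE)
  corrections <- as.data.frame(corrections)
  corrections <- corrections[order(corrections$phase), , drop = FALSE]
  for (k in seq_len(nrow(corrections))) {
    cr <- corrections[k, ]
    key <- paste0(cr$view, "/", cr$point)
    if (is.null(tracks[[key]])) stop("no track named ", key)
    tracks[[key]] <- correct_and_retrack(
      tracks[[key]], study$views[[cr$view]], cr$phase, c(cr$row, cr$col))
  }
  tracks
}

#' Export one tracking log as a data frame
#'
#' One row per phase: `phase`, `row`, `col`, `peak_corr`, `flagged`,
#' `corrected` — the per-point CSV log format.
#'
#' @param result a `track_result`.
#' @return a data.frame.
#' @export
tracking_log <- function(result) {
  P <- nrow(result$pixels)
  data.frame(view = result$view_label, point = result$point_label,
             phase = seq_len(P) - 1L,
             row = result$pixels[, 1], col = result$pixels[, 2],
             peak_corr = result$corr,
             flagged = (seq_len(P) - 1L) %in% result$flagged_phases,
             corrected = (seq_len(P) - 1L) %in% result$corrected_phases)
}
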