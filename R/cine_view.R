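#' Construct a cine long-axis view
#'
#' A `cine_view` bundles one long-axis cine series (an ordered list of 2D
#' grayscale frames, one per cardiac phase) with the spatial and temporal
#' geometry needed to map pixels into the 3D patient coordinate system
#' (DICOM LPS convention).
#'
#' Pixel indices throughout the package are 0-based `(row, col)` pairs
#' addressing pixel centers: pixel `(0, 0)` maps exactly to `origin`.
#'
#' @param frames list of numeric matrices, all with identical dimensions;
#'   phase index runs 0..P-1 in list order (phase 0 = end-diastole under
#'   retrospective gating).
#' @param view_label one of `"two_chamber"`, `"three_chamber"`,
#'   `"four_chamber"`.
#' @param origin 3D position (mm) of the center of pixel (0, 0)
#'   (DICOM ImagePositionPatient).
#' @param row_dir 3D unit vector along a row, i.e. the direction of
#'   increasing *column* index (first triplet of ImageOrientationPatient).
#' @param col_dir 3D unit vector down a column, i.e. the direction of
#'   increasing *row* index (second triplet of ImageOrientationPatient).
#' @param spacing numeric length-2 `(row_spacing_mm, col_spacing_mm)`:
#'   spacing between rows, then between columns (DICOM PixelSpacing order).
#' @param rr_interval_ms cardiac cycle length in milliseconds.
#' @return an object of class `cine_view`.
#' @export
cine_view <- function(frames, view_label, origin, row_dir, col_dir,
                      spacing, rr_interval_ms) {
  view_label <- match.arg(view_label, c("two_chamber", "three_chamber",
                                        "four_chamber"))
  if (!is.list(frames) || length(frames) < 1L)
    stop("'frames' must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share identical dimensions")
  origin  <- as.numeric(origin)
  row_dir <- as.numeric(row_dir)
  col_dir <- as.numeric(col_dir)
  spacing <- as.numeric(spacing)
  stopifnot(length(origin) == 3L, length(row_dir) == 3L,
            length(col_dir) == 3L, length(spacing) == 2L)
  if (any(spacing <= 0)) stop("pixel spacing components must be positive")
  row_dir <- row_dir / sqrt(sum(row_dir^2))
  col_dir <- col_dir / sqrt(sum(col_dir^2))
  if (abs(sum(row_dir * col_dir)) >= 1e-3)
    stop("row_dir and col_dir must be orthogonal (|dot| < 1e-3)")
  if (!is.numeric(rr_interval_ms) || rr_interval_ms <= 0)
    stop("rr_interval_ms must be positive")
  structure(
    list(frames = frames, view_label = view_label, origin = origin,
         row_dir = row_dir, col_dir = col_dir, spacing = spacing,
         rr_interval_ms = as.numeric(rr_interval_ms),
         n_phases = length(frames)),
    class = "cine_view")
}

#' @export
print.cine_view <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<cine_view> %s: %d phases, %dx%d px, spacing %.3gx%.3g mm, RR %.0f ms\n",
              x$view_label, x$n_phases, d[1], d[2],
              x$spacing[1], x$spacing[2], x$rr_interval_ms))
  invisible(x)
}

frame_dim <- function(view) dim(view$frames[[1]])

#' Map pixel coordinates to 3D patient coordinates
#'
#' Applies the DICOM plane equation: `origin + row * row_spacing * col_dir +
#' col * col_spacing * row_dir`. Indices are 0-based and address pixel
#' centers; fractional indices are allowed. Out-of-bounds pixels are mapped
#' with a warning (the affine map is defined everywhere in the plane).
#'
#' @param view a [cine_view].
#' @param pixel numeric length-2 `(row, col)` or an n x 2 matrix of pixels.
#' @return a 3D point (mm) as numeric length-3, or an n x 3 matrix.
#' @export
pixel_to_patient <- function(view, pixel) {
  p <- if (is.matrix(pixel)) pixel else matrix(as.numeric(pixel), ncol = 2L)
  d <- frame_dim(view)
  if (any(p[, 1] < -0.5 | p[, 1] > d[1] - 0.5 |
          p[, 2] < -0.5 | p[, 2] > d[2] - 0.5))
    warning("pixel outside image bounds; mapping extrapolated")
  out <- matrix(view$origin, nrow(p), 3L, byrow = TRUE) +
    outer(p[, 1] * view$spacing[1], view$col_dir) +
    outer(p[, 2] * view$spacing[2], view$row_dir)
  if (is.matrix(pixel)) out else drop(out)
}

#' Project a 3D patient point onto a view's pixel grid
#'
#' Inverse of [pixel_to_patient()] restricted to the view plane: the point is
#' orthogonally projected onto the plane and expressed as fractional 0-based
#' `(row, col)` indices. The out-of-plane distance is returned as an
#' attribute `"out_of_plane_mm"`.
#'
#' @inheritParams pixel_to_patient
#' @param point 3D point (mm) or n x 3 matrix.
#' @return `(row, col)` numeric length-2 (or n x 2 matrix) with attribute
#'   `out_of_plane_mm`.
#' @export
patient_to_pixel <- function(view, point) {
  q <- if (is.matrix(point)) point else matrix(as.numeric(point), ncol = 3L)
  rel <- sweep(q, 2L, view$origin)
  row <- as.numeric(rel %*% view$col_dir) / view$spacing[1]
  col <- as.numeric(rel %*% view$row_dir) / view$spacing[2]
  nrm <- pracma::cross(view$row_dir, view$col_dir)
  oop <- as.numeric(rel %*% nrm)
  out <- cbind(row = row, col = col)
  if (!is.matrix(point)) {
    out <- drop(out)
    oop <- drop(oop)
  }
  attr(out, "out_of_plane_mm") <- oop
  out
}

#' Bundle three long-axis views into a study
#'
#' Validates that the two-, three- and four-chamber views agree in phase
#' count and RR interval (to 1 ms), the configuration the annulus
#' reconstruction expects.
#'
#' @param views list of three [cine_view] objects with distinct labels.
#' @return object of class `study_geometry` (named list of views plus shared
#'   `n_phases` and `rr_interval_ms`).
#' @export
study_geometry <- function(views) {
  if (length(views) != 3L) stop("exactly three views are required")
  labs <- vapply(views, `[[`, "", "view_label")
  if (anyDuplicated(labs)) stop("view labels must be distinct")
  P <- vapply(views, `[[`, 0L, "n_phases")
  if (length(unique(P)) != 1L)
    stop("all views must share the same phase count; got ",
         paste(P, collapse = ", "))
  rr <- vapply(views, `[[`, 0, "rr_interval_ms")
  if (diff(range(rr)) > 1)
    stop("views disagree in RR interval by more than 1 ms")
  names(views) <- labs
  structure(list(views = views, n_phases = P[1],
                 rr_interval_ms = mean(rr)),
            class = "study_geometry")
}

#' @export
print.study_geometry <- function(x, ...) {
  cat(sprintf("<study_geometry> 3 views (%s), %d phases, RR %.0f ms\n",
              paste(names(x$views), collapse = ", "),
              x$n_phases, x$rr_interval_ms))
  invisible(x)
}
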