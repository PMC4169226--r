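#' Read a cine view from the plain fixture format
#'
#' The fixture format is a directory of 16-bit grayscale TIFF frames plus a
#' `geometry.json` sidecar holding the spatial/temporal geometry:
#' `view_label`, `origin`, `row_dir`, `col_dir`, `spacing`,
#' `rr_interval_ms` and the ordered `frame_files` list. It exists so that
#' complete analyses (and the test suite) can run without DICOM data; the
#' phantom generator emits it.
#'
#' @param dir directory containing `geometry.json` and the TIFF frames.
#' @return a [cine_view].
#' @export
read_fixture_view <- function(dir) {
  sidecar <- file.path(dir, "geometry.json")
  if (!file.exists(sidecar)) stop("no geometry.json sidecar in ", dir)
  g <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("view_label", "origin", "row_dir", "col_dir", "spacing",
            "rr_interval_ms", "frame_files")
  miss <- setdiff(need, names(g))
  if (length(miss)) stop("geometry.json missing fields: ",
                         paste(miss, collapse = ", "))
  frames <- lapply(file.path(dir, g$frame_files), function(f) {
    img <- tiff::readTIFF(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]  # collapse gray-as-RGB
    img
  })
  cine_view(frames, g$view_label, g$origin, g$row_dir, g$col_dir,
            g$spacing, g$rr_interval_ms)
}

#' Write a cine view in the plain fixture format
#'
#' Frames are clipped to `[0, 1]` and written as 16-bit grayscale TIFF;
#' geometry goes into `geometry.json`. Inverse of [read_fixture_view()].
#'
#' @param view a [cine_view].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture_view <- function(view, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("phase_%03d.tif", seq_len(view$n_phases) - 1L)
  for (i in seq_len(view$n_phases)) {
    img <- pmin(pmax(view$frames[[i]], 0), 1)
    tiff::writeTIFF(img, file.path(dir, files[i]), bits.per.sample = 16L)
  }
  g <- list(view_label = view$view_label, origin = view$origin,
            row_dir = view$row_dir, col_dir = view$col_dir,
            spacing = view$spacing, rr_interval_ms = view$rr_interval_ms,
            n_phases = view$n_phases, frame_files = files)
  jsonlite::write_json(g, file.path(dir, "geometry.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a three-view study in the fixture format
#'
#' One subdirectory per view, named by its label.
#'
#' @param study a [study_geometry].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_study <- function(study, dir) {
  for (v in study$views) write_fixture_view(v, file.path(dir, v$view_label))
  invisible(dir)
}

#' Read a three-view study from the fixture format
#'
#' @param dir directory with `two_chamber/`, `three_chamber/`,
#'   `four_chamber/` subdirectories.
#' @return a [study_geometry].
#' @export
read_fixture_study <- function(dir) {
  labs <- c("two_chamber", "three_chamber", "four_chamber")
  study_geometry(lapply(file.path(dir, labs), read_fixture_view))
}
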