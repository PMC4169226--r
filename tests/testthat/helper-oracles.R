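# Independent oracles and fixture builders used across the suite.

# Brute-force NCC oracle: Pearson correlation of the template against every
# fully contained placement, via stats::cor, double loop.
brute_ncc <- function(template, region) {
  th <- nrow(template); tw <- ncol(template)
  nr <- nrow(region) - th + 1L; nc <- ncol(region) - tw + 1L
  tv <- as.numeric(template)
  cm <- matrix(-Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    patch <- as.numeric(region[i:(i + th - 1L), j:(j + tw - 1L)])
    if (stats::sd(patch) > 0) cm[i, j] <- stats::cor(tv, patch)
  }
  best <- which(cm == max(cm), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1L, ]
  c0 <- c((nrow(region) - th) %/% 2L + 1L, (ncol(region) - tw) %/% 2L + 1L)
  list(displacement = unname(best - c0), peak = max(cm), map = cm)
}

# regular (optionally saddle-shaped) hexagon of labelled annulus points
make_hexagon <- function(R = 20, saddle = 0, center = c(0, 0, 0)) {
  th <- (0:5) * pi / 3
  pts <- cbind(R * cos(th), R * sin(th), saddle * cos(2 * th))
  pts <- sweep(pts, 2L, -center)
  rownames(pts) <- c("four_chamber/septal", "two_chamber/septal",
                     "three_chamber/septal", "four_chamber/lateral",
                     "two_chamber/lateral", "three_chamber/lateral")
  pts
}

# assemble a sweep_curve object directly from a normalized curve shape
# (for diastology tests that need exact constructed inputs)
make_curve <- function(normalized, rr_ms, essv_mm3 = 10000) {
  P <- length(normalized)
  cumu <- normalized * essv_mm3
  structure(list(increments_mm3 = diff(cumu), cumulative_mm3 = cumu,
                 closure_mm3 = cumu[1L] - cumu[P], essv_mm3 = essv_mm3,
                 normalized = normalized,
                 times_ms = (seq_len(P) - 1) * rr_ms / P,
                 es_phase = which.max(cumu) - 1L,
                 rr_interval_ms = rr_ms, long_axis = c(0, 0, -1),
                 areas_mm2 = rep(1000, P),
                 centroids = cbind(0, 0, -cumu / 1000)),
            class = "sweep_curve")
}

# circle-of-annulus frames translating/scaling along z, for sweep tests
ring_frame <- function(R, z, phase, n_pts = 6, saddle = 0, n_samples = 120) {
  th <- (seq_len(n_pts) - 1) * 2 * pi / n_pts
  pts <- cbind(R * cos(th), R * sin(th), z + saddle * cos(2 * th))
  rownames(pts) <- paste0("p", seq_len(n_pts))
  annulus_frame(pts, phase = phase, n_samples = n_samples)
}

# ---------------------------------------------------------------------------
# Minimal DICOM writer (independent of the package's reader): explicit or
# implicit VR little endian, single-frame monochrome, even-length values.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                endian = "little")

dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

dcm_element <- function(group, elem, vr, value, explicit = TRUE) {
  body <- switch(vr,
    DS = , IS = dcm_pad(charToRaw(paste(format(value, trim = TRUE),
                                        collapse = "\\"))),
    UI = dcm_pad(charToRaw(value), as.raw(0x00)),
    CS = , LO = dcm_pad(charToRaw(value)),
    US = unlist(lapply(value, dcm_u16)),
    OW = unlist(lapply(value, dcm_u16)))
  hdr <- c(dcm_u16(group), dcm_u16(elem))
  if (explicit) {
    if (vr %in% c("OB", "OW", "SQ", "UT", "UN"))
      c(hdr, charToRaw(vr), as.raw(c(0, 0)), dcm_u32(length(body)), body)
    else
      c(hdr, charToRaw(vr), dcm_u16(length(body)), body)
  } else {
    c(hdr, dcm_u32(length(body)), body)
  }
}

# pixels: integer matrix (rows x cols, values 0..32767)
write_test_dicom <- function(path, pixels, ipp, iop, spacing,
                             trigger_time = NULL, instance = NULL,
                             nominal_interval = NULL, explicit = TRUE,
                             preamble = TRUE, omit = character(0)) {
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  out <- raw(0)
  if (preamble) {
    out <- c(raw(128), charToRaw("DICM"),
             dcm_element(0x0002, 0x0010, "UI", ts, explicit = TRUE))
  }
  el <- function(g, e, vr, v) dcm_element(g, e, vr, v, explicit = explicit)
  add <- function(name, bytes) if (!(name %in% omit)) bytes else raw(0)
  out <- c(out,
    add("TriggerTime", if (!is.null(trigger_time))
      el(0x0018, 0x1060, "DS", trigger_time) else raw(0)),
    add("NominalInterval", if (!is.null(nominal_interval))
      el(0x0018, 0x1062, "IS", nominal_interval) else raw(0)),
    add("InstanceNumber", if (!is.null(instance))
      el(0x0020, 0x0013, "IS", instance) else raw(0)),
    add("ImagePositionPatient", el(0x0020, 0x0032, "DS", ipp)),
    add("ImageOrientationPatient", el(0x0020, 0x0037, "DS", iop)),
    add("Rows", el(0x0028, 0x0010, "US", nrow(pixels))),
    add("Columns", el(0x0028, 0x0011, "US", ncol(pixels))),
    add("PixelSpacing", el(0x0028, 0x0030, "DS", spacing)),
    add("BitsAllocated", el(0x0028, 0x0100, "US", 16L)),
    add("PixelRepresentation", el(0x0028, 0x0103, "US", 0L)),
    el(0x7FE0, 0x0010, "OW", as.integer(t(pixels))))
  writeBin(out, path)
  invisible(path)
}

# write a full test cine series (one file per phase) into a directory
write_test_series <- function(dir, frames, ipp, iop, spacing,
                              rr_ms = 800, use_trigger = TRUE, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  P <- length(frames)
  for (n in seq_len(P)) {
    write_test_dicom(
      file.path(dir, sprintf("im%03d.dcm", n)), frames[[n]],
      ipp = ipp, iop = iop, spacing = spacing,
      trigger_time = if (use_trigger) (n - 1) * rr_ms / P else NULL,
      instance = n, ...)
  }
  invisible(dir)
}
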