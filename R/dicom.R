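# Minimal DICOM reader: Part-10 files (or headerless datasets) in explicit
# or implicit VR little endian with uncompressed monochrome pixel data.
# Only the tags the cine pipeline needs are decoded; everything else is
# skipped structurally (sequences included).

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

# tags we decode: name -> c(group, element, vr-for-implicit)
DICOM_TAGS <- list(
  ImagePositionPatient    = list(0x0020L, 0x0032L, "DS"),
  ImageOrientationPatient = list(0x0020L, 0x0037L, "DS"),
  PixelSpacing            = list(0x0028L, 0x0030L, "DS"),
  Rows                    = list(0x0028L, 0x0010L, "US"),
  Columns                 = list(0x0028L, 0x0011L, "US"),
  BitsAllocated           = list(0x0028L, 0x0100L, "US"),
  PixelRepresentation     = list(0x0028L, 0x0103L, "US"),
  RescaleIntercept        = list(0x0028L, 0x1052L, "DS"),
  RescaleSlope            = list(0x0028L, 0x1053L, "DS"),
  NumberOfFrames          = list(0x0028L, 0x0008L, "IS"),
  TriggerTime             = list(0x0018L, 0x1060L, "DS"),
  NominalInterval         = list(0x0018L, 0x1062L, "IS"),
  InstanceNumber          = list(0x0020L, 0x0013L, "IS"),
  PixelData               = list(0x7FE0L, 0x0010L, "OW"))

long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

#' Read one DICOM file
#'
#' Parses a DICOM Part-10 file (explicit or implicit VR little endian,
#' uncompressed monochrome pixel data) and returns the header fields the
#' cine pipeline uses plus the pixel matrix. Compressed transfer syntaxes
#' and big-endian files are rejected.
#'
#' @param path file path.
#' @return list with any of `ImagePositionPatient`,
#'   `ImageOrientationPatient`, `PixelSpacing`, `Rows`, `Columns`,
#'   `TriggerTime`, `NominalInterval`, `InstanceNumber`, ... that are
#'   present, and `pixels` (numeric matrix, rescale slope/intercept
#'   applied).
#' @export
read_dicom <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2L,
                              endian = "little", signed = FALSE)
  u32 <- function(at) {
    v <- readBin(raw[at:(at + 3L)], "integer", size = 4L, endian = "little")
    if (v < 0) v + 2^32 else as.numeric(v)
  }
  pos <- 1L
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  explicit <- TRUE
  ts <- NULL
  fields <- list()

  read_element <- function(pos, explicit) {
    g <- u16(pos); e <- u16(pos + 2L)
    if (g == 0xFFFEL) {  # item / delimiter: implicit structure, 4-byte len
      len <- u32(pos + 4L)
      return(list(group = g, elem = e, vr = "NONE", len = len,
                  data_at = pos + 8L))
    }
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L)
        list(group = g, elem = e, vr = vr, len = len, data_at = pos + 12L)
      } else {
        len <- u16(pos + 6L)
        list(group = g, elem = e, vr = vr, len = len, data_at = pos + 8L)
      }
    } else {
      len <- u32(pos + 4L)
      list(group = g, elem = e, vr = "UN", len = len, data_at = pos + 8L)
    }
  }

  skip_undefined <- function(pos, explicit) {
    # advance past nested items until the sequence delimitation item
    repeat {
      if (pos + 7L > length(raw)) stop("truncated sequence in DICOM file")
      el <- read_element(pos, explicit)
      if (el$group == 0xFFFEL && el$elem == 0xE0DDL) return(el$data_at)
      if (el$len == 0xFFFFFFFF) pos <- skip_undefined(el$data_at, explicit)
      else pos <- el$data_at + el$len
    }
  }

  tag_lookup <- list()
  for (nm in names(DICOM_TAGS)) {
    tg <- DICOM_TAGS[[nm]]
    tag_lookup[[sprintf("%04X%04X", as.integer(tg[[1]]),
                        as.integer(tg[[2]]))]] <- c(nm, tg[[3]])
  }
  raw_text <- function(bytes) {
    bytes <- bytes[bytes != as.raw(0L)]
    trimws(rawToChar(bytes))
  }
  looks_explicit <- function(at) {
    vr <- rawToChar(raw[(at + 4L):(at + 5L)])
    grepl("^[A-Z]{2}$", vr)
  }

  in_meta <- TRUE
  while (pos + 7L <= length(raw)) {
    el <- read_element(pos, explicit = if (in_meta) TRUE else explicit)
    if (in_meta && el$group != 0x0002L) {
      # leaving the file meta group: switch to the negotiated syntax
      in_meta <- FALSE
      if (!is.null(ts)) {
        if (ts == TS_IMPLICIT_LE) explicit <- FALSE
        else if (ts != TS_EXPLICIT_LE)
          stop("unsupported transfer syntax: ", ts)
      } else explicit <- looks_explicit(pos)  # headerless dataset
      el <- read_element(pos, explicit)
    }
    if (el$len == 0xFFFFFFFF) {
      if (el$vr != "SQ" && !(el$vr %in% c("UN", "OW", "OB")))
        stop("undefined length on non-sequence element")
      pos <- skip_undefined(el$data_at, explicit)
      next
    }
    key <- sprintf("%04X%04X", el$group, el$elem)
    if (el$group == 0x0002L && el$elem == 0x0010L) {
      ts <- raw_text(raw[el$data_at:(el$data_at + el$len - 1L)])
    } else if (!is.null(hit <- tag_lookup[[key]])) {
      nm <- hit[1L]
      vr <- if (explicit && el$vr != "UN") el$vr else hit[2L]
      bytes <- if (el$len > 0L)
        raw[el$data_at:(el$data_at + el$len - 1L)] else raw(0)
      fields[[nm]] <-
        if (nm == "PixelData") bytes
        else if (vr %in% c("DS", "IS")) {
          as.numeric(strsplit(raw_text(bytes), "\\\\")[[1L]])
        } else if (vr == "US")
          readBin(bytes, "integer", n = el$len / 2L, size = 2L,
                  endian = "little", signed = FALSE)
        else raw_text(bytes)
    }
    pos <- el$data_at + el$len
  }
  if (!is.null(fields$PixelData)) {
    for (req in c("Rows", "Columns", "BitsAllocated"))
      if (is.null(fields[[req]]))
        stop("missing DICOM tag required to decode pixels: ", req)
    nr <- fields$Rows; nc <- fields$Columns
    ba <- fields$BitsAllocated
    signed <- identical(fields$PixelRepresentation, 1L) ||
      identical(fields$PixelRepresentation, 1)
    vals <- if (ba == 16L)
      readBin(fields$PixelData, "integer", n = nr * nc, size = 2L,
              endian = "little", signed = signed)
    else if (ba == 8L)
      as.integer(fields$PixelData[seq_len(nr * nc)])
    else stop("unsupported BitsAllocated: ", ba)
    m <- matrix(as.numeric(vals), nrow = nr, byrow = TRUE)
    slope <- if (is.null(fields$RescaleSlope)) 1 else fields$RescaleSlope
    icpt <- if (is.null(fields$RescaleIntercept)) 0 else fields$RescaleIntercept
    fields$pixels <- m * slope + icpt
    fields$PixelData <- NULL
  }
  fields
}

#' Load a cine view from a directory of DICOM files
#'
#' Reads every `*.dcm` (or extensionless DICOM) file in `path`, sorts
#' frames by TriggerTime when present (else InstanceNumber), validates that
#' the geometry tags agree across frames, and assembles a [cine_view].
#' Phase 0 is the first frame in sorted order (end-diastole under
#' retrospective gating). The RR interval is taken from NominalInterval
#' when present; otherwise it is extrapolated as P times the mean
#' inter-trigger spacing, and the chosen source is reported in a message.
#'
#' @param path directory containing one cine series.
#' @param view_label the long-axis view this series shows.
#' @return a [cine_view].
#' @export
load_dicom_view <- function(path, view_label) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!grepl("\\.(json|txt|csv)$", files)]
  if (!length(files)) stop("no DICOM files found in ", path)
  dsets <- lapply(files, read_dicom)
  tt <- vapply(dsets, function(d)
    if (is.null(d$TriggerTime)) NA_real_ else d$TriggerTime[1L], 0)
  if (!anyNA(tt)) {
    ord <- order(tt)
  } else {
    inum <- vapply(dsets, function(d)
      if (is.null(d$InstanceNumber)) NA_real_ else d$InstanceNumber[1L], 0)
    if (anyNA(inum))
      stop("cannot order frames: missing DICOM tag TriggerTime (0018,1060) ",
           "and InstanceNumber (0020,0013)")
    ord <- order(inum)
  }
  dsets <- dsets[ord]
  ref <- dsets[[1L]]
  for (tag in c("ImagePositionPatient", "ImageOrientationPatient",
                "PixelSpacing"))
    if (is.null(ref[[tag]]))
      stop("missing DICOM geometry tag: ", tag, " (",
           sprintf("%04X,%04X", DICOM_TAGS[[tag]][[1]],
                   DICOM_TAGS[[tag]][[2]]), ")")
  for (d in dsets[-1L]) {
    for (tag in c("ImagePositionPatient", "ImageOrientationPatient",
                  "PixelSpacing")) {
      if (is.null(d[[tag]]) ||
          length(d[[tag]]) != length(ref[[tag]]) ||
          max(abs(d[[tag]] - ref[[tag]])) > 1e-4)
        stop("inconsistent geometry across frames: ", tag)
    }
  }
  frames <- lapply(dsets, function(d) {
    if (is.null(d$pixels)) stop("a frame has no pixel data")
    d$pixels
  })
  P <- length(frames)
  if (!is.null(ref$NominalInterval) && ref$NominalInterval > 0) {
    rr <- ref$NominalInterval
    message("RR interval from NominalInterval: ", rr, " ms")
  } else if (!anyNA(tt) && P >= 2L) {
    rr <- P * mean(diff(sort(tt)))
    message(sprintf("RR interval extrapolated from trigger times: %.1f ms", rr))
  } else {
    stop("cannot determine RR interval: no NominalInterval (0018,1062) ",
         "and insufficient TriggerTime data")
  }
  iop <- ref$ImageOrientationPatient
  cine_view(frames, view_label, origin = ref$ImagePositionPatient,
            row_dir = iop[1:3], col_dir = iop[4:6],
            spacing = ref$PixelSpacing, rr_interval_ms = rr)
}
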