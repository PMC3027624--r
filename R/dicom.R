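# Minimal DICOM support: single-frame MR slices, explicit VR little endian,
# uncompressed 16-bit pixel data. This covers the standard axial T1 series the
# tool consumes and the series the test suite fabricates; anything else (other
# transfer syntaxes, compressed pixel data, multiframe objects) is rejected
# with a clear message.

.dcmExplicitLongVR <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one DICOM file into a named list tag -> raw payload.
readDicomFile <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  pos <- 1L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(raw[at:(at + 3L)], "integer", size = 4,
                              endian = "little")
  elements <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("only explicit-VR little-endian DICOM is supported: ", path)
    if (vr %in% .dcmExplicitLongVR) {
      len <- u32(pos + 8L)
      body <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      body <- pos + 8L
    }
    if (vr == "SQ")
      stop("DICOM sequences are not supported by this reader: ", path)
    if (len < 0 || body + len - 1L > n)
      stop("truncated DICOM element in ", path)
    key <- sprintf("%04X,%04X", group, elem)
    elements[[key]] <- if (len > 0) raw[body:(body + len - 1L)] else raw(0)
    pos <- body + len
  }
  elements
}

.dcmStr <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  trimws(rawToChar(el[[key]]))
}
.dcmDS <- function(el, key) {
  s <- .dcmStr(el, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
.dcmUS <- function(el, key) {
  if (is.null(el[[key]])) return(NULL)
  readBin(el[[key]], "integer", size = 2, signed = FALSE, endian = "little")
}

#' Read a DICOM series directory as a volume
#'
#' Assembles the single-frame slices of one series into a 3D volume, applies
#' the rescale slope/intercept, verifies consistent orientation and in-plane
#' spacing, checks for missing or irregularly spaced slices, and reorients the
#' result to the canonical internal frame.
#'
#' @param dir directory containing one DICOM slice per file.
#' @return an [ImageVolume-class].
#' @export
readDicomSeries <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no DICOM files found in ", dir)
  slices <- lapply(files, readDicomFile)

  iop <- .dcmDS(slices[[1]], "0020,0037")
  psp <- .dcmDS(slices[[1]], "0028,0030")
  rows <- .dcmUS(slices[[1]], "0028,0010")
  cols <- .dcmUS(slices[[1]], "0028,0011")
  if (is.null(iop) || is.null(psp) || is.null(rows) || is.null(cols))
    stop("DICOM series lacks orientation/spacing/shape tags")
  for (s in slices) {
    if (max(abs(.dcmDS(s, "0020,0037") - iop)) > 1e-4)
      stop("inconsistent ImageOrientationPatient across slices")
    if (max(abs(.dcmDS(s, "0028,0030") - psp)) > 1e-6)
      stop("inconsistent PixelSpacing across slices")
    if (.dcmUS(s, "0028,0010") != rows || .dcmUS(s, "0028,0011") != cols)
      stop("inconsistent slice shape across series")
    ba <- .dcmUS(s, "0028,0100")
    if (!is.null(ba) && ba != 16L)
      stop("only 16-bit DICOM pixel data is supported")
  }

  rowdir <- iop[1:3]; coldir <- iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  posAlong <- vapply(slices, function(s)
    sum(.dcmDS(s, "0020,0032") * normal), numeric(1))
  ord <- order(posAlong)
  slices <- slices[ord]
  posAlong <- posAlong[ord]

  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(posAlong)
    if (any(gaps < 1e-6))
      stop("duplicate slice positions in series")
    dz <- stats::median(gaps)
    big <- which(gaps > 1.5 * dz)
    if (length(big))
      stop(sprintf("missing slice(s): gap of %.3f mm between positions %.3f and %.3f (expected %.3f mm)",
                   gaps[big[1]], posAlong[big[1]], posAlong[big[1] + 1L], dz))
    if (max(abs(gaps - dz)) > 0.01 * dz)
      stop("inconsistent slice spacing across series")
  } else {
    dz <- .dcmDS(slices[[1]], "0018,0050")
    if (is.null(dz)) dz <- 1
  }

  dx <- psp[2]; dy <- psp[1]  # PixelSpacing is (row spacing, column spacing)
  arr <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    pix <- s[["7FE0,0010"]]
    if (is.null(pix)) stop("slice without PixelData")
    signed <- isTRUE(.dcmUS(s, "0028,0103") == 1L)
    vals <- readBin(pix, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
    slope <- .dcmDS(s, "0028,1053"); if (is.null(slope)) slope <- 1
    inter <- .dcmDS(s, "0028,1052"); if (is.null(inter)) inter <- 0
    arr[, , k] <- vals * slope + inter
  }

  # DICOM world frame is LPS; flip x and y to the internal RAS-like frame.
  ipp0 <- .dcmDS(slices[[1]], "0020,0032")
  affLPS <- diag(4)
  affLPS[1:3, 1] <- rowdir * dx
  affLPS[1:3, 2] <- coldir * dy
  affLPS[1:3, 3] <- normal * dz
  affLPS[1:3, 4] <- ipp0
  flip <- diag(c(-1, -1, 1, 1))
  out <- reorientCanonical(arr, flip %*% affLPS)
  ImageVolume(out$data, affine = out$affine)
}

.dcmElement <- function(group, elem, vr, payload) {
  if (length(payload) %% 2L == 1L)
    payload <- c(payload, as.raw(if (vr %in% c("UI")) 0L else 0x20))
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% .dcmExplicitLongVR) {
    head <- c(head, as.raw(c(0, 0)),
              writeBin(length(payload), raw(), size = 4, endian = "little"))
  } else {
    head <- c(head, writeBin(length(payload), raw(), size = 2,
                             endian = "little"))
  }
  c(head, payload)
}
.dcmStrEl <- function(group, elem, vr, x)
  .dcmElement(group, elem, vr, charToRaw(paste(x, collapse = "\\")))

#' Write a volume as a DICOM series
#'
#' Writes one explicit-VR little-endian MR slice per axial plane, chiefly to
#' fabricate test inputs for [readDicomSeries()]. Intensities are stored as
#' 16-bit integers with a series-wide rescale slope/intercept chosen so that
#' integer-valued volumes round-trip exactly.
#'
#' @param vol an [ImageVolume-class] on the canonical grid.
#' @param dir output directory (created if needed).
#' @param seriesUID series instance UID; fixed default keeps output
#'   deterministic.
#' @return \code{dir}, invisibly.
#' @export
writeDicomSeries <- function(vol, dir,
                             seriesUID = "1.2.826.0.1.3680043.9999.1") {
  stopifnot(is(vol, "ImageVolume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- vol@data
  if (anyNA(arr)) stop("cannot write a volume containing out-of-field NAs")
  d <- dim(arr)
  aff <- vol@affine
  sp <- voxelSpacing(vol)
  rng <- range(arr)
  if (all(arr == round(arr)) && rng[1] >= -32768 && rng[2] <= 32767) {
    slope <- 1; inter <- 0
  } else {
    inter <- (rng[1] + rng[2]) / 2
    slope <- max((rng[2] - rng[1]) / 65000, 1e-12)
  }
  # internal RAS-like frame -> DICOM LPS
  flip <- diag(c(-1, -1, 1, 1))
  affLPS <- flip %*% aff
  rowdir <- affLPS[1:3, 1] / sp[1]
  coldir <- affLPS[1:3, 2] / sp[2]
  fmt <- function(x) sprintf("%.8g", x)
  for (k in seq_len(d[3])) {
    ipp <- affLPS[1:3, 1:3] %*% c(0, 0, k - 1) + affLPS[1:3, 4]
    stored <- as.integer(round((as.vector(arr[, , k]) - inter) / slope))
    el <- c(
      .dcmStrEl(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.4"),
      .dcmStrEl(0x0008, 0x0018, "UI", paste0(seriesUID, ".", k)),
      .dcmStrEl(0x0008, 0x0060, "CS", "MR"),
      .dcmStrEl(0x0020, 0x000D, "UI", paste0(seriesUID, ".0")),
      .dcmStrEl(0x0020, 0x000E, "UI", seriesUID),
      .dcmStrEl(0x0020, 0x0013, "IS", as.character(k)),
      .dcmStrEl(0x0020, 0x0032, "DS", fmt(ipp)),
      .dcmStrEl(0x0020, 0x0037, "DS", fmt(c(rowdir, coldir))),
      .dcmStrEl(0x0018, 0x0050, "DS", fmt(sp[3])),
      .dcmElement(0x0028, 0x0002, "US",
                  writeBin(1L, raw(), size = 2, endian = "little")),
      .dcmStrEl(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcmElement(0x0028, 0x0010, "US",
                  writeBin(as.integer(d[2]), raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x0011, "US",
                  writeBin(as.integer(d[1]), raw(), size = 2, endian = "little")),
      .dcmStrEl(0x0028, 0x0030, "DS", fmt(c(sp[2], sp[1]))),
      .dcmElement(0x0028, 0x0100, "US",
                  writeBin(16L, raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x0101, "US",
                  writeBin(16L, raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x0102, "US",
                  writeBin(15L, raw(), size = 2, endian = "little")),
      .dcmElement(0x0028, 0x0103, "US",
                  writeBin(1L, raw(), size = 2, endian = "little")),
      .dcmStrEl(0x0028, 0x1052, "DS", fmt(inter)),
      .dcmStrEl(0x0028, 0x1053, "DS", fmt(slope)),
      .dcmElement(0x7FE0, 0x0010, "OW",
                  writeBin(stored, raw(), size = 2, endian = "little"))
    )
    meta <- .dcmStrEl(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
    metaLen <- .dcmElement(0x0002, 0x0000, "UL",
                           writeBin(length(meta), raw(), size = 4,
                                    endian = "little"))
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(c(raw(128), charToRaw("DICM"), metaLen, meta, el), con)
    close(con)
  }
  invisible(dir)
}
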