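# Minimal DICOM support: explicit-VR little-endian single-frame CT slices,
# one file per slice. Covers exactly what the pipeline needs -- geometry tags,
# rescale slope/intercept calibration, and 16-bit pixel data. Sequences with
# undefined length and compressed transfer syntaxes are rejected.

.EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

# DICOM strings may be padded with NUL or space; strip both.
.raw_to_str <- function(v) trimws(rawToChar(v[v != as.raw(0)]))

# Parse one DICOM file into a named list of raw element values (tag -> raw).
.read_dicom_elements <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  n <- length(raw)
  out <- list()
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2L,
                              endian = "little", signed = FALSE)
  u32 <- function(at) {
    v <- readBin(raw[at:(at + 3L)], "integer", size = 4L, endian = "little")
    if (v < 0) v <- v + 2^32
    v
  }
  while (pos + 7L <= n + 1L && pos <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- u32(pos + 8L)
      hdr <- 12L
    } else {
      len <- u16(pos + 6L)
      hdr <- 8L
    }
    if (len == 4294967295)
      stop("undefined-length element unsupported: ", path, call. = FALSE)
    val_start <- pos + hdr
    if (len > 0 && val_start + len - 1L > n)
      stop("truncated DICOM element in ", path, call. = FALSE)
    key <- .tag_key(group, element)
    out[[key]] <- if (len > 0) raw[val_start:(val_start + len - 1L)] else raw(0)
    if (key == .tag_key(0x0002, 0x0010)) {
      ts <- .raw_to_str(out[[key]])
      if (ts != .EXPLICIT_VR_LE)
        stop("unsupported transfer syntax '", ts, "' in ", path,
             call. = FALSE)
    }
    pos <- val_start + len
  }
  out
}

.dcm_str <- function(el, tag) {
  v <- el[[tag]]
  if (is.null(v)) return(NULL)
  .raw_to_str(v)
}

.dcm_ds <- function(el, tag) {
  s <- .dcm_str(el, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcm_us <- function(el, tag) {
  v <- el[[tag]]
  if (is.null(v)) return(NULL)
  readBin(v, "integer", n = length(v) / 2L, size = 2L, endian = "little",
          signed = FALSE)
}

# Read one slice: list(pixels = [x, y] HU matrix, ipp, iop, spacing_xy)
.read_dicom_slice <- function(path) {
  el <- .read_dicom_elements(path)
  ipp <- .dcm_ds(el, .tag_key(0x0020, 0x0032))
  iop <- .dcm_ds(el, .tag_key(0x0020, 0x0037))
  ps <- .dcm_ds(el, .tag_key(0x0028, 0x0030))
  rows <- .dcm_us(el, .tag_key(0x0028, 0x0010))
  cols <- .dcm_us(el, .tag_key(0x0028, 0x0011))
  if (is.null(ipp) || length(ipp) != 3L || is.null(iop) || length(iop) != 6L ||
      is.null(ps) || length(ps) != 2L || is.null(rows) || is.null(cols))
    stop("DICOM metadata error: missing spatial headers in ", path,
         call. = FALSE)
  bits <- .dcm_us(el, .tag_key(0x0028, 0x0100))
  if (!identical(bits, 16L))
    stop("only 16-bit DICOM pixel data is supported (", path, ")",
         call. = FALSE)
  signed <- identical(.dcm_us(el, .tag_key(0x0028, 0x0103)), 1L)
  slope <- .dcm_ds(el, .tag_key(0x0028, 0x1053))
  inter <- .dcm_ds(el, .tag_key(0x0028, 0x1052))
  if (is.null(slope)) slope <- 1
  if (is.null(inter)) inter <- 0
  pd <- el[[.tag_key(0x7FE0, 0x0010)]]
  if (is.null(pd) || length(pd) < 2L * rows * cols)
    stop("DICOM pixel data missing or short in ", path, call. = FALSE)
  stored <- readBin(pd, "integer", n = rows * cols, size = 2L,
                    endian = "little", signed = signed)
  hu <- slope * stored + inter
  list(pixels = matrix(hu, nrow = cols, ncol = rows),  # [x, y]
       ipp = ipp, iop = iop,
       spacing_xy = c(ps[2], ps[1]))  # (column spacing, row spacing)
}

#' Load a DICOM series as a calibrated CT volume
#'
#' Reads every `.dcm` file (or every regular file when none end in `.dcm`)
#' in a directory, applies the rescale slope/intercept to obtain HU, checks
#' that all slices share one image orientation and a uniform slice spacing,
#' and stacks them along the slice normal in ascending order.
#'
#' @param dir Directory containing one DICOM series.
#' @return A [ct_volume()].
#' @export
load_dicom_series <- function(dir) {
  if (!dir.exists(dir))
    stop("no such directory: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L)
    files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("no DICOM files found in ", dir, call. = FALSE)
  slices <- lapply(sort(files), .read_dicom_slice)

  iop0 <- slices[[1]]$iop
  for (s in slices)
    if (max(abs(s$iop - iop0)) > 1e-5)
      stop("DICOM series error: mixed image orientations in series",
           call. = FALSE)
  sp0 <- slices[[1]]$spacing_xy
  dims0 <- dim(slices[[1]]$pixels)
  for (s in slices)
    if (max(abs(s$spacing_xy - sp0)) > 1e-9 || !all(dim(s$pixels) == dims0))
      stop("DICOM series error: inconsistent pixel grid", call. = FALSE)

  xdir <- iop0[1:3]; ydir <- iop0[4:6]
  zdir <- c(xdir[2] * ydir[3] - xdir[3] * ydir[2],
            xdir[3] * ydir[1] - xdir[1] * ydir[3],
            xdir[1] * ydir[2] - xdir[2] * ydir[1])
  pos <- vapply(slices, function(s) sum(s$ipp * zdir), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  if (length(slices) > 1L) {
    dz <- diff(pos)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-4)
      stop("DICOM series error: non-uniform or duplicate slice spacing",
           call. = FALSE)
    dz <- mean(dz)
  } else dz <- 1
  vox <- array(0, dim = c(dims0, length(slices)))
  for (k in seq_along(slices)) vox[, , k] <- slices[[k]]$pixels
  ct_volume(vox, spacing = c(sp0, dz), origin = slices[[1]]$ipp,
            orientation = cbind(xdir, ydir, zdir))
}

# ---- writer ----------------------------------------------------------------

.enc_elem_short <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L)
    value_raw <- c(value_raw, as.raw(if (vr %in% c("UI")) 0L else 0x20))
  c(writeBin(as.integer(c(group, element)), raw(), size = 2L,
             endian = "little"),
    charToRaw(vr),
    writeBin(length(value_raw), raw(), size = 2L, endian = "little"),
    value_raw)
}

.enc_elem_long <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) value_raw <- c(value_raw, as.raw(0))
  c(writeBin(as.integer(c(group, element)), raw(), size = 2L,
             endian = "little"),
    charToRaw(vr), as.raw(c(0, 0)),
    writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
    value_raw)
}

.enc_str <- function(group, element, vr, s)
  .enc_elem_short(group, element, vr, charToRaw(s))

.enc_us <- function(group, element, v)
  .enc_elem_short(group, element, "US",
                  writeBin(as.integer(v), raw(), size = 2L,
                           endian = "little"))

.fmt_ds <- function(v) paste(sprintf("%.8g", v), collapse = "\\")

#' Write a CT volume as a single-frame DICOM series
#'
#' Emits one explicit-VR little-endian file per slice with 16-bit signed
#' stored values; HU are encoded through the given rescale slope/intercept
#' (stored = round((HU - intercept) / slope)), so HU outside the
#' representable range or not on the slope grid are quantized.
#'
#' @param vol A [ct_volume()].
#' @param dir Output directory (created if absent).
#' @param slope,intercept Rescale calibration written to the headers.
#' @return Invisibly, the vector of file paths written.
#' @export
write_dicom_series <- function(vol, dir, slope = 1, intercept = 0) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vol$voxels)
  stored_all <- round((vol$voxels - intercept) / slope)
  if (any(stored_all < -32768 | stored_all > 32767))
    stop("HU values not representable with this slope/intercept",
         call. = FALSE)
  iop <- c(vol$orientation[, 1], vol$orientation[, 2])
  paths <- character(d[3])
  meta <- c(
    .enc_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    .enc_str(0x0002, 0x0003, "UI", "1.2.3.4.5"),
    .enc_str(0x0002, 0x0010, "UI", .EXPLICIT_VR_LE))
  meta_grp <- c(.enc_elem_short(0x0002, 0x0000, "UL",
                                writeBin(length(meta), raw(), size = 4L,
                                         endian = "little")),
                meta)
  preamble <- c(raw(128), charToRaw("DICM"))
  for (k in seq_len(d[3])) {
    ipp <- vol$origin + (k - 1) * vol$spacing[3] * vol$orientation[, 3]
    stored <- as.integer(stored_all[, , k])
    body <- c(
      .enc_str(0x0008, 0x0060, "CS", "CT"),
      .enc_str(0x0020, 0x0013, "IS", as.character(k)),
      .enc_str(0x0020, 0x0032, "DS", .fmt_ds(ipp)),
      .enc_str(0x0020, 0x0037, "DS", .fmt_ds(iop)),
      .enc_us(0x0028, 0x0002, 1L),
      .enc_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .enc_us(0x0028, 0x0010, d[2]),   # Rows (y)
      .enc_us(0x0028, 0x0011, d[1]),   # Columns (x)
      .enc_str(0x0028, 0x0030, "DS",
               .fmt_ds(c(vol$spacing[2], vol$spacing[1]))),
      .enc_us(0x0028, 0x0100, 16L),
      .enc_us(0x0028, 0x0101, 16L),
      .enc_us(0x0028, 0x0102, 15L),
      .enc_us(0x0028, 0x0103, 1L),
      .enc_str(0x0028, 0x1052, "DS", .fmt_ds(intercept)),
      .enc_str(0x0028, 0x1053, "DS", .fmt_ds(slope)),
      .enc_elem_long(0x7FE0, 0x0010, "OW",
                     writeBin(stored, raw(), size = 2L, endian = "little")))
    paths[k] <- file.path(dir, sprintf("slice_%04d.dcm", k))
    writeBin(c(preamble, meta_grp, body), paths[k])
  }
  invisible(paths)
}
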