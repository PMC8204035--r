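# Minimal DICOM support: reading a single uncompressed CT-like series
# (explicit or implicit VR little endian) and writing such a series for
# phantoms and tests. No installed R package reads DICOM, so the subset of
# the format this package needs is implemented here. Multi-frame/enhanced
# DICOM and compressed transfer syntaxes are out of scope.

.dcm_uint <- function(raw, pos, n) {
  v <- 0
  for (i in seq_len(n)) v <- v + as.numeric(raw[pos + i - 1]) * 256^(i - 1)
  v
}

.dcm_parse <- function(raw) {
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file")
  pos <- 133
  elements <- list()
  explicit <- TRUE
  ts_checked <- FALSE
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7 <= length(raw)) {
    group <- .dcm_uint(raw, pos, 2)
    elem <- .dcm_uint(raw, pos + 2, 2)
    pos <- pos + 4
    in_meta <- group == 2
    if (!in_meta && !ts_checked) {
      ts <- elements[["2,16"]]
      if (!is.null(ts)) {
        uid <- .dcm_str(ts)
        if (uid == "1.2.840.10008.1.2") explicit <- FALSE
        else if (uid != "1.2.840.10008.1.2.1")
          stop("unsupported DICOM transfer syntax: ", uid)
      }
      ts_checked <- TRUE
    }
    if (in_meta || explicit) {
      vr <- rawToChar(raw[pos:(pos + 1)])
      if (vr %in% long_vrs) {
        len <- .dcm_uint(raw, pos + 4, 4)
        pos <- pos + 8
      } else {
        len <- .dcm_uint(raw, pos + 2, 2)
        pos <- pos + 4
      }
    } else {
      vr <- NA_character_
      len <- .dcm_uint(raw, pos, 4)
      pos <- pos + 4
    }
    if (!is.na(len) && len == 4294967295) {
      # undefined length (sequence): scan for the sequence delimiter
      if (identical(vr, "SQ") || is.na(vr)) {
        dpos <- pos
        while (dpos + 7 <= length(raw)) {
          if (.dcm_uint(raw, dpos, 2) == 0xFFFE && .dcm_uint(raw, dpos + 2, 2) == 0xE0DD) {
            pos <- dpos + 8
            break
          }
          dpos <- dpos + 2
        }
        next
      }
      stop("undefined-length element outside a sequence")
    }
    if (pos + len - 1 > length(raw)) stop("truncated DICOM element")
    key <- paste(group, elem, sep = ",")
    elements[[key]] <- raw[seq.int(pos, length.out = len)]
    pos <- pos + len
  }
  elements
}

.dcm_str <- function(el) {
  if (is.null(el)) return(NULL)
  # strip trailing NUL/space padding at the raw level (rawToChar rejects NULs)
  while (length(el) && el[length(el)] %in% as.raw(c(0L, 32L)))
    el <- el[-length(el)]
  rawToChar(el)
}
.dcm_ds <- function(el) if (is.null(el)) NULL else as.numeric(strsplit(.dcm_str(el), "\\\\")[[1]])
.dcm_us <- function(el) if (is.null(el)) NULL else .dcm_uint(el, 1, 2)

#' Read a DICOM series directory as a volume
#'
#' Reads all part-10 files in `dir`, checks that they belong to a single
#' series, sorts slices along the slice normal and assembles an
#' [image_volume]. Only uncompressed little-endian transfer syntaxes and
#' single-sample (grayscale) 8/16-bit pixel data are supported. Rescale
#' slope/intercept are applied.
#'
#' @param dir directory of single-series DICOM slices.
#' @return An [image_volume].
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2) stop("DICOM series needs at least 2 slice files in ", dir)
  slices <- lapply(files, function(f) {
    raw <- readBin(f, "raw", file.size(f))
    el <- .dcm_parse(raw)
    bits <- .dcm_us(el[["40,256"]])      # (0028,0100) BitsAllocated
    if (is.null(bits) || !(bits %in% c(8, 16)))
      stop("unsupported BitsAllocated in ", f)
    signed <- isTRUE(.dcm_us(el[["40,259"]]) == 1)  # (0028,0103)
    rows <- .dcm_us(el[["40,16"]])       # (0028,0010)
    cols <- .dcm_us(el[["40,17"]])       # (0028,0011)
    px <- el[["32736,16"]]               # (7FE0,0010)
    if (is.null(px) || is.null(rows) || is.null(cols))
      stop("missing pixel data in ", f)
    vals <- readBin(px, "integer", rows * cols, size = bits / 8,
                    signed = if (bits == 8) signed else signed, endian = "little")
    if (bits == 16 && !signed) {
      vals <- readBin(px, "integer", rows * cols, size = 2, signed = TRUE,
                      endian = "little")
      vals <- ifelse(vals < 0, vals + 65536, vals)
    }
    slope <- .dcm_ds(el[["40,4179"]])    # (0028,1053)
    inter <- .dcm_ds(el[["40,4178"]])    # (0028,1052)
    vals <- as.numeric(vals) * (if (is.null(slope)) 1 else slope) +
      (if (is.null(inter)) 0 else inter)
    list(series = .dcm_str(el[["32,14"]]),          # (0020,000E)
         ipp = .dcm_ds(el[["32,50"]]),              # (0020,0032)
         iop = .dcm_ds(el[["32,55"]]),              # (0020,0037)
         pixel_spacing = .dcm_ds(el[["40,48"]]),    # (0028,0030)
         rows = rows, cols = cols,
         data = array(vals, c(cols, rows)))         # [col, row] = row-major stream
  })
  uids <- unique(vapply(slices, function(s) s$series %||% "<missing>", ""))
  if (length(uids) > 1)
    stop("directory mixes multiple DICOM series: ", paste(uids, collapse = ", "))
  iop <- slices[[1]]$iop %||% c(1, 0, 0, 0, 1, 0)
  rowdir <- iop[1:3]; coldir <- iop[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  z <- vapply(slices, function(s) sum(s$ipp * normal), 0)
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  dz <- diff(z)
  if (length(dz) && (max(dz) - min(dz)) > 1e-4 * mean(dz))
    warning("non-uniform DICOM slice spacing; using the mean")
  ps <- slices[[1]]$pixel_spacing %||% c(1, 1)  # (row spacing, col spacing)
  spacing <- c(ps[2], ps[1], if (length(dz)) mean(dz) else 1)
  data <- array(0, c(slices[[1]]$cols, slices[[1]]$rows, length(slices)))
  for (k in seq_along(slices)) data[, , k] <- slices[[k]]$data
  image_volume(data, spacing = spacing, origin = slices[[1]]$ipp,
               direction = cbind(rowdir, coldir, normal))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.dcm_pad <- function(s, nul = FALSE) {
  b <- charToRaw(s)
  if (length(b) %% 2 == 1) b <- c(b, if (nul) as.raw(0) else charToRaw(" "))
  b
}

.dcm_el <- function(group, elem, vr, value) {
  tag <- writeBin(as.integer(c(group, elem)), raw(), size = 2, endian = "little")
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  lenbytes <- if (long)
    c(charToRaw(vr), as.raw(c(0, 0)),
      writeBin(as.integer(length(value)), raw(), size = 4, endian = "little"))
  else c(charToRaw(vr), writeBin(as.integer(length(value)), raw(), size = 2, endian = "little"))
  c(tag, lenbytes, value)
}

#' Write a volume as a minimal DICOM series
#'
#' Writes one explicit-VR little-endian CT slice file per z-index with signed
#' 16-bit pixels, for use as test and phantom fixtures. Intensities must be
#' integers in the int16 range. This is deliberately a minimal writer; real
#' scan export should use MetaImage or NIfTI via [write_volume].
#'
#' @param vol an [image_volume] with identity-permutation direction.
#' @param dir output directory (created if missing).
#' @param series_uid optional series instance UID.
#' @return the directory, invisibly.
#' @export
write_dicom_series <- function(vol, dir, series_uid = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  x <- vol$data
  if (any(x != round(x)) || min(x) < -32768 || max(x) > 32767)
    stop("DICOM writer requires integer intensities in the int16 range")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(x)
  root <- "1.2.826.0.1.3680043.9.7432"
  if (is.null(series_uid)) series_uid <- paste0(root, ".1.1")
  study_uid <- paste0(root, ".1")
  rowdir <- vol$direction[, 1]; coldir <- vol$direction[, 2]
  for (k in seq_len(d[3])) {
    ipp <- voxel_to_world(vol, matrix(c(1, 1, k), 1))[1, ]
    px <- writeBin(as.integer(x[, , k]), raw(), size = 2, endian = "little")
    meta <- c(
      .dcm_el(2, 2, "UI", .dcm_pad("1.2.840.10008.5.1.4.1.1.2", TRUE)),
      .dcm_el(2, 3, "UI", .dcm_pad(sprintf("%s.2.%d", root, k), TRUE)),
      .dcm_el(2, 16, "UI", .dcm_pad("1.2.840.10008.1.2.1", TRUE)))
    meta <- c(.dcm_el(2, 0, "UL", writeBin(as.integer(length(meta)), raw(),
                                           size = 4, endian = "little")), meta)
    ds <- c(
      .dcm_el(8, 22, "UI", .dcm_pad("1.2.840.10008.5.1.4.1.1.2", TRUE)),
      .dcm_el(8, 24, "UI", .dcm_pad(sprintf("%s.2.%d", root, k), TRUE)),
      .dcm_el(8, 96, "CS", .dcm_pad("CT")),
      .dcm_el(32, 13, "UI", .dcm_pad(study_uid, TRUE)),
      .dcm_el(32, 14, "UI", .dcm_pad(series_uid, TRUE)),
      .dcm_el(32, 19, "IS", .dcm_pad(as.character(k))),
      .dcm_el(32, 50, "DS", .dcm_pad(paste(sprintf("%.10g", ipp), collapse = "\\"))),
      .dcm_el(32, 55, "DS", .dcm_pad(paste(sprintf("%.10g", c(rowdir, coldir)), collapse = "\\"))),
      .dcm_el(40, 2, "US", writeBin(1L, raw(), size = 2, endian = "little")),
      .dcm_el(40, 4, "CS", .dcm_pad("MONOCHROME2")),
      .dcm_el(40, 16, "US", writeBin(as.integer(d[2]), raw(), size = 2, endian = "little")),
      .dcm_el(40, 17, "US", writeBin(as.integer(d[1]), raw(), size = 2, endian = "little")),
      .dcm_el(40, 48, "DS", .dcm_pad(sprintf("%.10g\\%.10g", vol$spacing[2], vol$spacing[1]))),
      .dcm_el(40, 256, "US", writeBin(16L, raw(), size = 2, endian = "little")),
      .dcm_el(40, 257, "US", writeBin(16L, raw(), size = 2, endian = "little")),
      .dcm_el(40, 258, "US", writeBin(15L, raw(), size = 2, endian = "little")),
      .dcm_el(40, 259, "US", writeBin(1L, raw(), size = 2, endian = "little")),
      .dcm_el(40, 4178, "DS", .dcm_pad("0")),
      .dcm_el(40, 4179, "DS", .dcm_pad("1")),
      .dcm_el(32736, 16, "OW", px))
    con <- file(file.path(dir, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(as.raw(rep(0, 128)), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, ds), con)
    close(con)
  }
  invisible(dir)
}
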