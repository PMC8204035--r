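#' Read a 3D scan volume
#'
#' Supported formats: a DICOM series directory (uncompressed, single series),
#' MetaImage (`.mha`/`.mhd`), and NIfTI (`.nii`/`.nii.gz`, via RNifti).
#' Intensities are returned exactly as stored (after DICOM rescale
#' slope/intercept); spacing, origin and direction come from the metadata.
#'
#' @param path file path, or a directory of DICOM slices.
#' @param format one of `"auto"`, `"dicom_series"`, `"metaimage"`, `"nifti"`.
#' @return An [image_volume].
#' @export
read_volume <- function(path, format = c("auto", "dicom_series", "metaimage", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series"
    else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) "metaimage"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else stop("cannot infer format from path: ", path)
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  switch(format,
         dicom_series = read_dicom_series(path),
         metaimage = .read_metaimage(path),
         nifti = .read_nifti(path))
}

#' Write a 3D scan volume
#'
#' MetaImage and NIfTI writing are lossless round trips through
#' [read_volume] for the supported element types.
#' @param vol an [image_volume].
#' @param path output path (`.mha`, `.mhd`, `.nii`, `.nii.gz`).
#' @param format `"auto"` (from extension), `"metaimage"` or `"nifti"`.
#' @param dtype element type on disk: `"double"`, `"float"`, `"short"`,
#'   `"ushort"` or `"uchar"` (MetaImage only; NIfTI writes the array type
#'   chosen by RNifti).
#' @export
write_volume <- function(vol, path, format = c("auto", "metaimage", "nifti"),
                         dtype = "double") {
  stopifnot(inherits(vol, "image_volume"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) "metaimage"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else stop("cannot infer format from path: ", path)
  }
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ", dirname(path))
  switch(format,
         metaimage = .write_metaimage(vol, path, dtype),
         nifti = .write_nifti(vol, path))
  invisible(path)
}

.met_types <- list(
  MET_UCHAR = list(what = "integer", size = 1, signed = FALSE, r = "uchar"),
  MET_CHAR = list(what = "integer", size = 1, signed = TRUE, r = "char"),
  MET_SHORT = list(what = "integer", size = 2, signed = TRUE, r = "short"),
  MET_USHORT = list(what = "integer", size = 2, signed = FALSE, r = "ushort"),
  MET_INT = list(what = "integer", size = 4, signed = TRUE, r = "int"),
  MET_FLOAT = list(what = "numeric", size = 4, signed = TRUE, r = "float"),
  MET_DOUBLE = list(what = "numeric", size = 8, signed = TRUE, r = "double"))

.read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, 1, warn = FALSE)
    if (length(line) == 0) stop("truncated MetaImage header: ", path)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  if (is.null(hdr$ObjectType) || hdr$ObjectType != "Image")
    stop("not a MetaImage image file: ", path)
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage not supported")
  if (!is.null(hdr$BinaryDataByteOrderMSB) && toupper(hdr$BinaryDataByteOrderMSB) == "TRUE")
    stop("big-endian MetaImage not supported")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3D MetaImage supported")
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  direction <- if (!is.null(hdr$TransformMatrix))
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3, 3, byrow = TRUE)
  else diag(3)
  ty <- .met_types[[hdr$ElementType]]
  if (is.null(ty)) stop("unsupported MetaImage ElementType: ", hdr$ElementType)
  n <- prod(dims)
  if (hdr$ElementDataFile == "LOCAL") {
    data <- readBin(con, ty$what, n, size = ty$size, signed = ty$signed,
                    endian = "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("MetaImage data file missing: ", rawpath)
    con2 <- file(rawpath, "rb")
    data <- readBin(con2, ty$what, n, size = ty$size, signed = ty$signed,
                    endian = "little")
    close(con2)
  }
  if (length(data) != n) stop("truncated MetaImage data: ", path)
  image_volume(array(as.numeric(data), dims), spacing = spacing,
               origin = origin, direction = direction)
}

.write_metaimage <- function(vol, path, dtype = "double") {
  met <- switch(dtype,
                double = "MET_DOUBLE", float = "MET_FLOAT", short = "MET_SHORT",
                ushort = "MET_USHORT", uchar = "MET_UCHAR",
                stop("unsupported dtype: ", dtype))
  ty <- .met_types[[met]]
  x <- as.vector(vol$data)
  if (ty$what == "integer") {
    lim <- switch(met, MET_SHORT = c(-32768, 32767), MET_USHORT = c(0, 65535),
                  MET_UCHAR = c(0, 255))
    if (any(x != round(x)) || min(x) < lim[1] || max(x) > lim[2])
      stop("volume intensities do not fit dtype ", dtype, " losslessly")
    x <- as.integer(x)
  }
  mhd <- grepl("\\.mhd$", path, ignore.case = TRUE)
  datafile <- if (mhd) paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  else "LOCAL"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("TransformMatrix =", paste(sprintf("%.17g", t(vol$direction)), collapse = " ")),
           paste("Offset =", paste(sprintf("%.17g", vol$origin), collapse = " ")),
           paste("ElementSpacing =", paste(sprintf("%.17g", vol$spacing), collapse = " ")),
           paste("DimSize =", paste(dim(vol$data), collapse = " ")),
           paste("ElementType =", met),
           paste("ElementDataFile =", datafile))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (!mhd) {
    writeBin(x, con, size = ty$size, endian = "little")
    close(con)
  } else {
    close(con)
    con2 <- file(file.path(dirname(path), datafile), "wb")
    writeBin(x, con2, size = ty$size, endian = "little")
    close(con2)
  }
  invisible(path)
}

.read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  M <- unclass(x)[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  direction <- sweep(M, 2, spacing, "/")
  image_volume(array(as.numeric(img), dim(img)), spacing = spacing,
               origin = unclass(x)[1:3, 4], direction = direction)
}

.write_nifti <- function(vol, path) {
  aff <- diag(4)
  aff[1:3, 1:3] <- vol$direction %*% diag(vol$spacing)
  aff[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
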