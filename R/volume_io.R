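# Volume file I/O: NIfTI-1 (.nii / .nii.gz) and MetaImage (.mha / .mhd).
# No R NIfTI package is assumed; the formats are read/written directly.
# HU values are returned exactly as stored, after applying the format's own
# slope/intercept scaling (NIfTI scl_slope / scl_inter) and nothing else.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Read a HU volume from NIfTI-1 or MetaImage
#'
#' Supported: `.nii`, `.nii.gz` (NIfTI-1, datatypes uint8/int16/int32/
#' uint16/float32/float64, sform preferred over qform, `scl_slope` /
#' `scl_inter` honored) and `.mha` / `.mhd` (MetaImage, uncompressed,
#' MET_UCHAR/MET_SHORT/MET_USHORT/MET_INT/MET_FLOAT/MET_DOUBLE).
#'
#' @param path file path.
#' @return an [hu_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    read_nifti(path)
  } else if (grepl("\\.(mha|mhd)$", lp)) {
    read_metaimage(path)
  } else {
    stop("unrecognized volume format (expect .nii, .nii.gz, .mha or .mhd): ",
         path, call. = FALSE)
  }
}

#' Write a HU volume to NIfTI-1 or MetaImage
#'
#' Values are stored as float32; the affine is written as the NIfTI sform
#' (code 2) or as the MetaImage TransformMatrix/Offset/ElementSpacing triple.
#'
#' @param vol an [hu_volume].
#' @param path output path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "hu_volume"))
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) {
    write_nifti(vol, path)
  } else if (grepl("\\.(mha|mhd)$", lp)) {
    write_metaimage(vol, path)
  } else {
    stop("unrecognized volume extension: ", path, call. = FALSE)
  }
  invisible(path)
}

# ---- NIfTI-1 ----------------------------------------------------------------

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  rd_i16 <- function(off, n = 1L)
    readBin(hdr_raw[(off + 1):(off + 2L * n)], "integer", n = n, size = 2L,
            endian = endian)
  rd_f32 <- function(off, n = 1L)
    readBin(hdr_raw[(off + 1):(off + 4L * n)], "double", n = n, size = 4L,
            endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("missing NIfTI magic in ", path, call. = FALSE)
  dims <- rd_i16(40L, 8L)
  if (dims[1] < 3L) stop("NIfTI volume must be 3D: ", path, call. = FALSE)
  nd <- dims[2:4]
  ntail <- if (dims[1] > 3L) prod(pmax(dims[5:(dims[1] + 1L)], 1L)) else 1L
  if (ntail != 1L) stop("4D+ NIfTI not supported: ", path, call. = FALSE)
  datatype <- rd_i16(70L)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L)
  scl_slope <- rd_f32(112L)
  scl_inter <- rd_f32(116L)
  qform_code <- rd_i16(252L)
  sform_code <- rd_i16(254L)

  if (sform_code > 0L) {
    affine <- rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L),
                    c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    b <- rd_f32(256L); cc <- rd_f32(260L); d <- rd_f32(264L)
    a2 <- 1 - b * b - cc * cc - d * d
    a <- if (a2 > 0) sqrt(a2) else 0
    R <- matrix(c(
      a*a + b*b - cc*cc - d*d, 2*(b*cc - a*d),          2*(b*d + a*cc),
      2*(b*cc + a*d),          a*a + cc*cc - b*b - d*d, 2*(cc*d - a*b),
      2*(b*d - a*cc),          2*(cc*d + a*b),          a*a + d*d - b*b - cc*cc
    ), nrow = 3L, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    sp <- abs(pixdim[2:4]); sp[sp == 0] <- 1
    R <- R %*% diag(c(sp[1], sp[2], qfac * sp[3]))
    affine <- rbind(cbind(R, c(rd_f32(268L), rd_f32(272L), rd_f32(276L))),
                    c(0, 0, 0, 1))
  } else {
    sp <- abs(pixdim[2:4]); sp[sp == 0] <- 1
    affine <- diag(c(sp, 1))
  }

  # skip from byte 348 to vox_offset (sequential: connection may be gzipped)
  skip <- round(vox_offset) - 348L
  if (skip < 0L) skip <- 4L  # minimum legal offset is 352
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(nd)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data: ", path, call. = FALSE)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  hu_volume(array(vals, dim = nd), affine)
}

write_nifti <- function(vol, path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- vol$dim
  wr_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wr_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wr_raw <- function(n) writeBin(raw(n), con)

  wr_i32(348L)                       # sizeof_hdr
  wr_raw(36L)                        # data_type, db_name, extents, session_error, regular, dim_info
  wr_i16(c(3L, d, 1L, 1L, 1L, 1L))   # dim[8]
  wr_f32(c(0, 0, 0))                 # intent_p1..p3
  wr_i16(0L)                         # intent_code
  wr_i16(16L)                        # datatype = float32
  wr_i16(32L)                        # bitpix
  wr_i16(0L)                         # slice_start
  wr_f32(c(1, vol$spacing, 0, 0, 0, 0))  # pixdim[8], qfac = 1
  wr_f32(352)                        # vox_offset
  wr_f32(1)                          # scl_slope
  wr_f32(0)                          # scl_inter
  wr_i16(0L); wr_raw(1L); wr_raw(1L) # slice_end, slice_code, xyzt_units
  wr_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  wr_i32(c(0L, 0L))                  # glmax, glmin
  wr_raw(80L); wr_raw(24L)           # descrip, aux_file
  wr_i16(0L)                         # qform_code
  wr_i16(2L)                         # sform_code = aligned
  wr_f32(c(0, 0, 0))                 # quatern b, c, d
  wr_f32(c(0, 0, 0))                 # qoffset x, y, z
  wr_f32(vol$affine[1, ])            # srow_x
  wr_f32(vol$affine[2, ])            # srow_y
  wr_f32(vol$affine[3, ])            # srow_z
  wr_raw(16L)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wr_raw(4L)                         # extension flag
  wr_f32(as.double(vol$values))
}

# ---- MetaImage --------------------------------------------------------------

MET_TYPES <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "double",  size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "double",  size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("no ElementDataFile in ", path, call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", line))[[1]]
    if (length(kv) != 3L) next
    hdr[[kv[2]]] <- kv[3]
    if (kv[2] == "ElementDataFile") break
  }
  need <- function(k) {
    if (is.null(hdr[[k]])) stop("MetaImage header missing ", k, call. = FALSE)
    hdr[[k]]
  }
  if (as.integer(need("NDims")) != 3L)
    stop("MetaImage volume must be 3D: ", path, call. = FALSE)
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage not supported: ", path, call. = FALSE)
  d <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(need("ElementSpacing"), "\\s+")[[1]])
  off <- if (!is.null(hdr$Offset)) as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  tm <- if (!is.null(hdr$TransformMatrix))
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3L, 3L,
           byrow = TRUE) else diag(3)
  dt <- MET_TYPES[[need("ElementType")]]
  if (is.null(dt)) stop("unsupported ElementType ", hdr$ElementType, call. = FALSE)
  big <- !is.null(hdr$BinaryDataByteOrderMSB) &&
    toupper(hdr$BinaryDataByteOrderMSB) == "TRUE"
  endian <- if (big) "big" else "little"
  n <- prod(d)
  datafile <- hdr$ElementDataFile
  if (toupper(datafile) == "LOCAL") {
    vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                    endian = endian)
  } else {
    dpath <- file.path(dirname(path), datafile)
    if (!file.exists(dpath)) stop("missing raw data file ", dpath, call. = FALSE)
    dcon <- file(dpath, "rb")
    on.exit(close(dcon), add = TRUE)
    vals <- readBin(dcon, dt$what, n = n, size = dt$size, signed = dt$signed,
                    endian = endian)
  }
  if (length(vals) != n) stop("truncated MetaImage data: ", path, call. = FALSE)
  # ITK convention: direction cosines in columns, affine = TM %*% diag(spacing)
  affine <- rbind(cbind(tm %*% diag(sp), off), c(0, 0, 0, 1))
  hu_volume(array(as.double(vals), dim = d), affine)
}

write_metaimage <- function(vol, path) {
  A <- vol$affine
  sp <- vol$spacing
  tm <- A[1:3, 1:3] %*% diag(1 / sp)
  is_mha <- grepl("\\.mha$", tolower(path))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", paste(format(t(tm), trim = TRUE), collapse = " ")),
    paste("Offset =", paste(format(A[1:3, 4], trim = TRUE), collapse = " ")),
    paste("ElementSpacing =", paste(format(sp, trim = TRUE), collapse = " ")),
    paste("DimSize =", paste(vol$dim, collapse = " ")),
    "ElementType = MET_FLOAT",
    paste("ElementDataFile =",
          if (is_mha) "LOCAL" else paste0(basename(tools::file_path_sans_ext(path)), ".raw"))
  )
  if (is_mha) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.double(vol$values), con, size = 4L, endian = "little")
  } else {
    writeLines(hdr, path)
    raw_path <- file.path(dirname(path),
                          paste0(basename(tools::file_path_sans_ext(path)), ".raw"))
    con <- file(raw_path, "wb")
    on.exit(close(con))
    writeBin(as.double(vol$values), con, size = 4L, endian = "little")
  }
}
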