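#' HU-calibrated image volume
#'
#' A minimal container for an isotropic 3D scalar volume: a numeric (or
#' logical, for masks) array plus the isotropic voxel size in micrometres and
#' the world position (mm) of the center of voxel `[1, 1, 1]`. World
#' coordinates follow RAS axis order; voxel indices are 1-based in R.
#'
#' @param data 3D array (numeric HU values, or logical for masks).
#' @param voxel_um isotropic voxel size in micrometres (> 0).
#' @param origin_mm numeric length-3: world coordinates (mm) of the first
#'   voxel center.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, voxel_um, origin_mm = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_um) || length(voxel_um) != 1L || voxel_um <= 0)
    stop("`voxel_um` must be a single positive number")
  if (length(origin_mm) != 3L)
    stop("`origin_mm` must have length 3")
  structure(list(data = data, voxel_um = as.numeric(voxel_um),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %.3g um isotropic\n",
              d[1], d[2], d[3], x$voxel_um))
  cat(sprintf("  origin (mm): [%.3f, %.3f, %.3f]  range: [%.4g, %.4g]\n",
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

voxel_mm <- function(vol) vol$voxel_um / 1000

# world (mm) coordinates of voxel centers given 1-based ijk matrix
vox_to_world <- function(vol, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep((ijk - 1) * voxel_mm(vol), 2, vol$origin_mm, "+")
}

assert_volume <- function(x, arg = deparse(substitute(x))) {
  if (!inherits(x, "ct_volume"))
    stop(sprintf("`%s` must be a ct_volume", arg))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Volume I/O. The sandbox has no imaging I/O package, so the two simplest
# standard containers are implemented directly: NIfTI-1 (.nii, .nii.gz,
# float32, no transform beyond voxel spacing + origin offset) and MetaImage
# (.mha local raw, .mhd + .raw). Round-trips are bit-exact for float32 data.

#' Read an image volume
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mha`,
#' `.mhd`). The pipeline assumes isotropic voxels; files with anisotropic
#' spacing are rejected with a descriptive error.
#'
#' @param path file path.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return(read_nifti(path))
  if (grepl("\\.(mha|mhd)$", lp)) return(read_metaimage(path))
  stop("unsupported volume format (expected .nii, .nii.gz, .mha or .mhd): ",
       path)
}

#' Write an image volume
#'
#' @param vol a [ct_volume()].
#' @param path destination; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  assert_volume(vol)
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) write_nifti(vol, path)
  else if (grepl("\\.mha$", lp)) write_metaimage(vol, path)
  else stop("unsupported volume format (expected .nii, .nii.gz or .mha): ",
            path)
  invisible(path)
}

write_nifti <- function(vol, path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "wb")
         else file(path, "wb")
  on.exit(close(con))
  d <- dim(vol$data)
  sp <- rep(voxel_mm(vol), 3)
  writeBin(348L, con, size = 4)                      # sizeof_hdr
  writeBin(raw(36), con)                             # unused
  writeBin(as.integer(c(3, d, 1, 1, 1, 1)), con, size = 2)  # dim
  writeBin(raw(14), con)                             # intent params etc.
  writeBin(16L, con, size = 2)                       # datatype: float32
  writeBin(32L, con, size = 2)                       # bitpix
  writeBin(0L, con, size = 2)                        # slice_start
  writeBin(c(0, sp, 0, 0, 0, 0), con, size = 4)      # pixdim[0..7]
  writeBin(352, con, size = 4)                       # vox_offset (float!)
  writeBin(c(1, 0), con, size = 4)                   # scl_slope, scl_inter
  writeBin(raw(132), con)  # bytes 120..251: slice_end/code, xyzt_units,
                           # cal_max/min, slice_duration, toffset,
                           # glmax/glmin, descrip(80), aux_file(24)
  writeBin(c(0L, 1L), con, size = 2)                 # qform=0, sform=1
  writeBin(rep(0, 6), con, size = 4)                 # quatern b,c,d + qoffsets
  srow <- rbind(c(sp[1], 0, 0, vol$origin_mm[1]),
                c(0, sp[2], 0, vol$origin_mm[2]),
                c(0, 0, sp[3], vol$origin_mm[3]))
  writeBin(as.numeric(t(srow)), con, size = 4)       # srow_x/y/z
  writeBin(raw(16), con)                             # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)      # magic
  writeBin(raw(4), con)                              # extension flags
  writeBin(as.numeric(vol$data), con, size = 4)
  invisible(path)
}

read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb")
         else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  dimv <- readBin(hdr[41:56], "integer", size = 2, n = 8, endian = endian)
  if (dimv[1] < 3) stop("expected a 3D NIfTI volume: ", path)
  d <- dimv[2:4]
  if (dimv[1] > 3 && any(dimv[5:(1 + dimv[1])] > 1))
    stop("expected a single 3D NIfTI volume: ", path)
  datatype <- readBin(hdr[71:72], "integer", size = 2, endian = endian)
  pixdim <- readBin(hdr[77:108], "numeric", size = 4, n = 8, endian = endian)
  vox_offset <- readBin(hdr[109:112], "numeric", size = 4, endian = endian)
  scl_slope <- readBin(hdr[113:116], "numeric", size = 4, endian = endian)
  scl_inter <- readBin(hdr[117:120], "numeric", size = 4, endian = endian)
  sform <- readBin(hdr[255:256], "integer", size = 2, endian = endian)
  srow <- readBin(hdr[281:328], "numeric", size = 4, n = 12, endian = endian)
  sp_mm <- pixdim[2:4]
  if (max(sp_mm) - min(sp_mm) > 1e-6 * max(sp_mm))
    stop("anisotropic voxel spacing (", paste(signif(sp_mm, 6), collapse = " x "),
         " mm) is not supported: the pipeline assumes isotropic voxels")
  origin <- if (sform > 0) srow[c(4, 8, 12)] else c(0, 0, 0)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(d)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", size = 1, n = n, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", size = 2, n = n, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", size = 4, n = n, endian = endian)),
    "16" = readBin(con, "numeric", size = 4, n = n, endian = endian),
    "64" = readBin(con, "numeric", size = 8, n = n, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(vals) < n) stop("truncated NIfTI data block: ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  ct_volume(array(vals, dim = d), voxel_um = sp_mm[1] * 1000,
            origin_mm = origin)
}

write_metaimage <- function(vol, path) {
  sp <- voxel_mm(vol)
  d <- dim(vol$data)
  hdr <- paste0(
    "ObjectType = Image\n", "NDims = 3\n", "BinaryData = True\n",
    "BinaryDataByteOrderMSB = False\n",
    "CompressedData = False\n",
    sprintf("TransformMatrix = 1 0 0 0 1 0 0 0 1\n"),
    sprintf("Offset = %.9g %.9g %.9g\n", vol$origin_mm[1], vol$origin_mm[2],
            vol$origin_mm[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g\n", sp, sp, sp),
    sprintf("DimSize = %d %d %d\n", d[1], d[2], d[3]),
    "ElementType = MET_FLOAT\n", "ElementDataFile = LOCAL\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(as.numeric(vol$data), con, size = 4)
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ASCII lines terminated by ElementDataFile
  lines <- character()
  repeat {
    line <- character()
    repeat {
      ch <- readBin(con, "raw", n = 1)
      if (length(ch) == 0) stop("truncated MetaImage header: ", path)
      if (ch == charToRaw("\n")) break
      line <- c(line, rawToChar(ch))
    }
    line <- paste(line, collapse = "")
    lines <- c(lines, line)
    if (grepl("^ElementDataFile", line)) break
  }
  field <- function(key) {
    hit <- grep(paste0("^", key, " *="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^[^=]*=", "", hit[1]))
  }
  d <- as.integer(strsplit(field("DimSize"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(field("ElementSpacing") %||% "1 1 1", "\\s+")[[1]])
  off <- as.numeric(strsplit(field("Offset") %||% "0 0 0", "\\s+")[[1]])
  type <- field("ElementType")
  datafile <- field("ElementDataFile")
  if (max(sp) - min(sp) > 1e-6 * max(sp))
    stop("anisotropic voxel spacing (", paste(signif(sp, 6), collapse = " x "),
         " mm) is not supported: the pipeline assumes isotropic voxels")
  n <- prod(d)
  read_block <- function(cn) {
    switch(type,
      MET_FLOAT = readBin(cn, "numeric", size = 4, n = n,
                          endian = "little"),
      MET_DOUBLE = readBin(cn, "numeric", size = 8, n = n,
                           endian = "little"),
      MET_SHORT = as.numeric(readBin(cn, "integer", size = 2, n = n,
                                     endian = "little")),
      MET_UCHAR = as.numeric(readBin(cn, "integer", size = 1, n = n,
                                     signed = FALSE)),
      stop("unsupported MetaImage ElementType: ", type))
  }
  if (identical(datafile, "LOCAL")) {
    vals <- read_block(con)
  } else {
    raw_path <- file.path(dirname(path), datafile)
    cn2 <- file(raw_path, "rb")
    on.exit(close(cn2), add = TRUE)
    vals <- read_block(cn2)
  }
  if (length(vals) < n) stop("truncated MetaImage data block: ", path)
  ct_volume(array(vals, dim = d), voxel_um = sp[1] * 1000, origin_mm = off)
}
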