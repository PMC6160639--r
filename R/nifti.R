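# Minimal single-file NIfTI-1 I/O (float32, sform only).
#
# No NIfTI package ships with the target environment, so the small subset
# of the format the pipeline needs is implemented here: enough to round-trip
# the volumes this package itself writes and to read externally produced
# uncompressed or gzipped .nii files with a standard header.

#' Write a 3D array or `volume4d` as a NIfTI-1 file
#'
#' Data are stored as float32 with the affine in the sform (code 2).
#' Paths ending in `.gz` are gzip-compressed.
#'
#' @param x a `volume4d`, or a 3D/4D numeric array
#' @param path output path (`.nii` or `.nii.gz`)
#' @param affine 4x4 voxel-to-mm matrix (ignored when `x` is a `volume4d`)
#' @param tr_seconds repetition time stored in pixdim\[4\]
#' @return `path`, invisibly
#' @export
write_nifti <- function(x, path, affine = diag(4), tr_seconds = 0) {
  if (inherits(x, "volume4d")) {
    affine <- x$affine; tr_seconds <- x$tr_seconds; x <- x$data
  }
  dm <- dim(x)
  if (is.null(dm) || !(length(dm) %in% c(3, 4))) stopf("need a 3D or 4D array")
  ndim <- length(dm)
  dim8 <- c(ndim, dm, rep(1L, 7 - ndim))
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim8 <- c(1, vox, tr_seconds, 0, 0, 0)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_f32 <- function(v) writeBin(as.double(v), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348)                      # sizeof_hdr
  w_raw(36)                       # data_type, db_name, extents, session_error, regular, dim_info
  w_i16(dim8)                     # dim[8]
  w_f32(c(0, 0, 0))               # intent_p1..p3
  w_i16(0)                        # intent_code
  w_i16(16)                       # datatype = FLOAT32
  w_i16(32)                       # bitpix
  w_i16(0)                        # slice_start
  w_f32(pixdim8)                  # pixdim[8]
  w_f32(352)                      # vox_offset
  w_f32(c(1, 0))                  # scl_slope, scl_inter
  w_i16(0)                        # slice_end
  w_raw(2)                        # slice_code, xyzt_units
  w_f32(c(0, 0, 0))               # cal_max, cal_min, slice_duration
  w_f32(0)                        # toffset
  w_i32(c(0, 0))                  # glmax, glmin
  w_raw(80 + 24)                  # descrip, aux_file
  w_i16(c(0, 2))                  # qform_code, sform_code
  w_f32(rep(0, 6))                # quatern b,c,d, qoffset x,y,z
  w_f32(t(affine[1:3, ]))         # srow_x, srow_y, srow_z
  w_raw(16)                       # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); w_raw(1)
  w_i32(0)                        # extension flag
  w_f32(as.vector(x))
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()] (or any float32/int16
#' single-file NIfTI with little-endian encoding)
#'
#' @param path input path (`.nii` or `.nii.gz`)
#' @return a list with `data` (array), `affine`, `tr_seconds`
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  r_i32 <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  r_i16 <- function(n) readBin(con, "integer", n, size = 2, endian = "little")
  r_f32 <- function(n) readBin(con, "double", n, size = 4, endian = "little")
  hdr_size <- r_i32(1)
  if (!identical(hdr_size, 348L)) stopf("%s: unsupported NIfTI header", path)
  readBin(con, "raw", 36)
  dim8 <- r_i16(8)
  r_f32(3); r_i16(1)
  datatype <- r_i16(1); r_i16(2)
  pixdim8 <- r_f32(8)
  vox_offset <- r_f32(1)
  slope <- r_f32(1); inter <- r_f32(1)
  r_i16(1); readBin(con, "raw", 2); r_f32(4); r_i32(2)
  readBin(con, "raw", 104)
  r_i16(2); r_f32(6)
  srow <- matrix(r_f32(12), 3, 4, byrow = TRUE)
  readBin(con, "raw", 16 + 4 + 4)
  extra <- vox_offset - 352
  if (extra > 0) readBin(con, "raw", extra)
  dm <- dim8[seq_len(dim8[1]) + 1]
  nvox <- prod(dm)
  vals <- switch(as.character(datatype),
    "16" = r_f32(nvox),
    "4"  = as.double(r_i16(nvox)),
    "64" = readBin(con, "double", nvox, size = 8, endian = "little"),
    stopf("%s: unsupported datatype %d", path, datatype))
  if (slope != 0 && !(slope == 1 && inter == 0)) vals <- vals * slope + inter
  affine <- rbind(srow, c(0, 0, 0, 1))
  list(data = array(vals, dm), affine = affine, tr_seconds = pixdim8[5])
}
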