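#' Minimal NIfTI-1 reader and writer
#'
#' Self-contained single-file NIfTI-1 I/O (.nii, optionally gzipped as
#' .nii.gz) for 3D volumes, storing voxel spacing in pixdim. Written
#' because no NIfTI package exists in this R stack; covers exactly what
#' the pipeline needs (float32/int16 data, no extensions, qform identity).
#'
#' @name nifti-io
NULL

#' Write a 3D volume as NIfTI-1
#'
#' @param volume a `ct_volume`, `thorax_volume`, or 3D array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing voxel spacing in mm (taken from the volume if present).
#' @export
write_nifti <- function(volume, path, spacing = NULL) {
  v <- if (is.list(volume)) volume$voxels else volume
  if (is.null(spacing))
    spacing <- if (is.list(volume) && !is.null(volume$spacing))
      volume$spacing else c(1, 1, 1)
  d <- dim(v)
  if (length(d) != 3) stop_invalid("only 3D volumes are supported")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  # header written strictly sequentially (gzip connections cannot seek)
  wi(348, 4)                                   # 0   sizeof_hdr
  writeBin(raw(36), con)                       # 4   unused legacy fields
  wi(c(3, d, 1, 1, 1, 1), 2)                   # 40  dim[8]
  wf(c(0, 0, 0))                               # 56  intent params
  wi(0, 2)                                     # 68  intent_code
  wi(16, 2)                                    # 70  datatype: float32
  wi(32, 2)                                    # 72  bitpix
  wi(0, 2)                                     # 74  slice_start
  wf(c(1, spacing, 1, 1, 1, 1))                # 76  pixdim[8]
  wf(352)                                      # 108 vox_offset
  wf(c(1, 0))                                  # 112 scl_slope, scl_inter
  wi(0, 2)                                     # 120 slice_end
  writeBin(raw(1), con)                        # 122 slice_code
  writeBin(as.raw(2), con)                     # 123 xyzt_units: mm
  wf(c(0, 0, 0, 0))                            # 124 cal_max/min, dur, toffset
  wi(c(0, 0), 4)                               # 140 glmax, glmin
  writeBin(raw(104), con)                      # 148 descrip + aux_file
  wi(c(0, 1), 2)                               # 252 qform_code, sform_code
  wf(rep(0, 6))                                # 256 quaternion + offsets
  wf(c(spacing[1], 0, 0, 0))                   # 280 srow_x
  wf(c(0, spacing[2], 0, 0))                   # 296 srow_y
  wf(c(0, 0, spacing[3], 0))                   # 312 srow_z
  writeBin(raw(16), con)                       # 328 intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # 344 magic
  writeBin(raw(4), con)                        # 348 extension flag
  writeBin(as.numeric(v), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param acquisition_day day tag to place on the returned volume.
#' @return a `ct_volume`.
#' @export
read_nifti <- function(path, acquisition_day = 0L) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348) stop_invalid("not a NIfTI-1 file: ", path)
  dims <- ri(40, 2, 8)
  if (dims[1] != 3) stop_invalid("only 3D NIfTI volumes are supported")
  d <- dims[2:4]
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  readBin(con, "raw", vox_offset - 352)
  n <- prod(d)
  v <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "8" = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop_invalid("unsupported NIfTI datatype ", datatype))
  scl <- rf(112, 2)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) v <- v * scl[1] + scl[2]
  ct_volume(array(v, dim = d), spacing = pixdim[2:4],
            acquisition_day = acquisition_day)
}
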