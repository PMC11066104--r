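# Minimal NIfTI-1 I/O.
#
# The toolkit exchanges volumes as single-file NIfTI-1 (.nii / .nii.gz),
# float32, little-endian, with a diagonal sform affine. No NIfTI reader is
# available in the installed R stack, so a compact reader/writer for exactly
# this profile lives here; it round-trips with nibabel.

#' Write a 3D volume as NIfTI-1
#'
#' @param vol 3D numeric array.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param pixdim voxel sizes in mm (length 3).
#' @param description free-text tag stored in the header (max 79 bytes).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, pixdim = c(1, 1, 1), description = "relmap3d") {
  stopifnot(length(dim(vol)) == 3, length(pixdim) == 3)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  d <- dim(vol)

  pad_raw <- function(s, n) {
    r <- charToRaw(as.character(s))
    if (length(r) >= n) r <- r[seq_len(n - 1)]
    c(r, raw(n - length(r)))
  }
  wi32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wi16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wf32 <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")

  wi32(348)                              # sizeof_hdr
  writeBin(raw(10 + 18 + 4 + 2 + 1 + 1), con)  # unused legacy fields
  wi16(c(3, d, 1, 1, 1, 1))              # dim[8]
  wf32(c(0, 0, 0))                       # intent_p1..p3
  wi16(0)                                # intent_code
  wi16(16)                               # datatype: float32
  wi16(32)                               # bitpix
  wi16(0)                                # slice_start
  wf32(c(1, pixdim, 1, 1, 1, 1))         # pixdim[8] (qfac = 1)
  wf32(352)                              # vox_offset
  wf32(c(1, 0))                          # scl_slope, scl_inter
  wi16(0)                                # slice_end
  writeBin(as.raw(c(0, 10)), con)        # slice_code, xyzt_units (mm)
  wf32(c(0, 0, 0, 0))                    # cal_max, cal_min, slice_duration, toffset
  wi32(c(0, 0))                          # glmax, glmin
  writeBin(pad_raw(description, 80), con)
  writeBin(raw(24), con)                 # aux_file
  wi16(c(0, 1))                          # qform_code, sform_code
  wf32(c(0, 0, 0, 0, 0, 0))              # quatern b,c,d + qoffset x,y,z
  wf32(c(pixdim[1], 0, 0, 0))            # srow_x
  wf32(c(0, pixdim[2], 0, 0))            # srow_y
  wf32(c(0, 0, pixdim[3], 0))            # srow_z
  writeBin(raw(16), con)                 # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)
  writeBin(raw(4), con)                  # extension flag
  wf32(as.double(vol))
  invisible(path)
}

#' Read a NIfTI-1 volume written by this toolkit
#'
#' Supports single-file little-endian NIfTI-1 with float32 or float64 data.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return 3D numeric array with attribute `"pixdim"`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri32 <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  ri16 <- function(n) readBin(con, "integer", n, size = 2, endian = "little")
  rf32 <- function(n) readBin(con, "double", n, size = 4, endian = "little")

  if (ri32(1) != 348) stop("not a little-endian NIfTI-1 file")
  readBin(con, "raw", 36)
  dm <- ri16(8)
  if (dm[1] != 3) stop("only 3-d volumes are supported")
  d <- dm[2:4]
  rf32(3); ri16(1)
  datatype <- ri16(1)
  ri16(2)
  pixdim <- rf32(8)[2:4]
  vox_offset <- rf32(1)
  scl <- rf32(2)
  # 120 header bytes consumed so far; skip the rest of header + extensions
  seek_skip <- vox_offset - 120
  if (seek_skip > 0) readBin(con, "raw", seek_skip)
  nvox <- prod(d)
  vals <- switch(as.character(datatype),
    "16" = readBin(con, "double", nvox, size = 4, endian = "little"),
    "64" = readBin(con, "double", nvox, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype))
  if (!isTRUE(all.equal(scl, c(1, 0))) && scl[1] != 0)
    vals <- vals * scl[1] + scl[2]
  out <- array(vals, d)
  attr(out, "pixdim") <- pixdim
  out
}
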