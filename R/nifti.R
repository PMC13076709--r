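# Minimal NIfTI-1 I/O (single-file .nii, float32 or float64, little-endian).
#
# No NIfTI library is available in the target R environment, so the package
# carries a deliberately small reader/writer covering exactly what the
# pipeline needs: 3D/4D arrays with voxel spacing, a description string,
# and a diagonal sform. Compressed (.nii.gz) files are handled via gzfile.

#' Write an array as a NIfTI-1 file
#'
#' @param data numeric array (2-4 dimensions).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param pixdim numeric voxel spacings, one per dimension (mm; recycled/
#'   padded with 1).
#' @param descrip description string (<= 79 bytes) stored in the header.
#' @param datatype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1), descrip = "",
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dm <- dim(data) %||% length(data)
  if (length(dm) > 7) stopf("too many dimensions")
  ndim <- length(dm)
  dim8 <- c(ndim, dm, rep(1L, 7 - ndim))
  pd <- c(0, pixdim, rep(1, 7 - length(pixdim)))[1:8]
  dt_code <- if (datatype == "float32") 16L else 64L
  bitpix <- if (datatype == "float32") 32L else 64L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw_s <- charToRaw(substr(s, 1, len - 1))
    writeBin(c(raw_s, raw(len - length(raw_s))), con)
  }
  wi(348L, 4)                       # sizeof_hdr
  wc("", 10); wc("", 18)            # data_type, db_name
  wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(dim8, 2)                       # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)         # intent_p1-3, intent_code
  wi(dt_code, 2); wi(bitpix, 2); wi(0L, 2)     # datatype, bitpix, slice_start
  wf(pd)                            # pixdim[8]
  wf(352); wf(1); wf(0)             # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc("", 1); wc("", 1)   # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  wc(descrip, 80); wc("", 24)       # descrip, aux_file
  wi(c(0L, 1L), 2)                  # qform_code, sform_code
  wf(rep(0, 6))                     # quaternion b,c,d + qoffset x,y,z
  wf(c(pd[2], 0, 0, 0))             # srow_x
  wf(c(0, pd[3], 0, 0))             # srow_y
  wf(c(0, 0, pd[4], 0))             # srow_z
  wc("", 16); wc("n+1", 4)          # intent_name, magic
  writeBin(raw(4), con)             # extension flag
  writeBin(as.numeric(data), con, size = bitpix / 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file written by [write_nifti()] (or compatible)
#'
#' Supports uncompressed or gzipped single-file NIfTI-1 with float32,
#' float64, or int16 data, little-endian.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (array), `pixdim` (per-dimension spacing) and
#'   `descrip`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stopf("truncated NIfTI header in %s", path)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348) stopf("%s is not a little-endian NIfTI-1 file", path)
  dim8 <- ri(40, 2, 8)
  ndim <- dim8[1]
  dm <- dim8[2:(1 + ndim)]
  dtype <- ri(70, 2)
  pixdim <- rf(76, 8)[2:(1 + ndim)]
  vox_offset <- rf(108)
  scl_slope <- rf(112)
  scl_inter <- rf(116)
  descrip_raw <- hdr[149:228]
  nul <- which(descrip_raw == 0)[1]
  descrip <- rawToChar(descrip_raw[seq_len(if (is.na(nul)) 80 else nul - 1)])
  nvox <- prod(dm)
  readBin(con, "raw", max(0, vox_offset - 348))
  data <- switch(as.character(dtype),
    "16" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = nvox, size = 8, endian = "little"),
    "4" = readBin(con, "integer", n = nvox, size = 2, endian = "little"),
    stopf("unsupported NIfTI datatype code %d", dtype))
  if (length(data) < nvox) stopf("truncated NIfTI data in %s", path)
  if (scl_slope != 0 && (scl_slope != 1 || scl_inter != 0))
    data <- data * scl_slope + scl_inter
  list(data = array(as.numeric(data), dim = dm), pixdim = pixdim,
       descrip = descrip)
}

#' Write a simulated DWI stack as NIfTI plus b-value sidecar
#'
#' @param stack a `dwi_stack`.
#' @param prefix output path prefix; writes `<prefix>.nii` and
#'   `<prefix>.json` (field `bvalues`, ascending).
#' @return The NIfTI path, invisibly.
#' @export
write_dwi_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "dwi_stack"))
  p <- stack$protocol
  nii <- paste0(prefix, ".nii")
  write_nifti(stack$data, nii,
              pixdim = c(p$pixel_mm, p$pixel_mm, p$slice_mm, 1),
              descrip = sprintf("DWI %s level=%s", p$sequence, stack$level))
  jsonlite::write_json(
    list(bvalues = p$b_values, sequence = p$sequence, level = stack$level,
         session = stack$session_id, repeat_id = stack$repeat_id,
         averages_per_b = p$averages_per_b, noise_sigma = p$noise_sigma),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(nii)
}

#' Read a DWI stack from NIfTI plus b-value sidecar
#'
#' Entry point for real scanner data: per-b-value magnitude volumes in one
#' 4D NIfTI with a JSON sidecar carrying at least `bvalues`.
#'
#' @param prefix path prefix as used by [write_dwi_stack()], or the `.nii`
#'   path itself.
#' @return A `dwi_stack`.
#' @export
read_dwi_stack <- function(prefix) {
  prefix <- sub("\\.nii(\\.gz)?$", "", prefix)
  nii <- read_nifti(if (file.exists(paste0(prefix, ".nii"))) paste0(prefix, ".nii")
                    else paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  b <- as.numeric(side$bvalues)
  dm <- dim(nii$data)
  if (length(dm) != 4 || dm[4] != length(b))
    stopf("4D volume with %d b-values expected", length(b))
  proto <- default_protocol(side$sequence %||% "fFOV",
                            b_values = b,
                            averages_per_b = as.integer(side$averages_per_b %||%
                                                          rep(1L, length(b))),
                            pixel_mm = nii$pixdim[1], slice_mm = nii$pixdim[3],
                            matrix = dm[1], n_slices = dm[3],
                            noise_sigma = as.numeric(side$noise_sigma %||% 0))
  structure(list(data = nii$data, protocol = proto,
                 level = side$level %||% "OFF",
                 repeat_id = side$repeat_id %||% 1L,
                 session_id = side$session %||% "S1",
                 temperature_c = side$temperature_c %||% NA_real_,
                 ground_truth = NULL),
            class = "dwi_stack")
}
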