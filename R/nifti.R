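## Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
## Little-endian files are written; reading auto-detects byte order. Only the
## scalar datatypes the pipeline emits are supported (uint8, int16, int32,
## float32, float64). The sform (srow_*) carries the voxel-to-world affine;
## qform is left unset. No reason to pull in a full neuroimaging stack for
## this: the pipeline only ever round-trips dense scalar grids it wrote
## itself, and the writer is cross-checked against nibabel in the tests.

NIFTI_DT <- data.frame(
  name = c("uint8", "int16", "int32", "float32", "float64"),
  code = c(2L, 4L, 8L, 16L, 64L),
  bitpix = c(8L, 16L, 32L, 32L, 64L),
  stringsAsFactors = FALSE)

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' @param img numeric/integer array with 3 or 4 dimensions.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size scalar or length-3 voxel edges in mm (ignored when
#'   `affine` is given).
#' @param affine optional 4x4 voxel-to-world matrix, stored as the sform.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return the path, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size = 1, affine = NULL,
                        datatype = "float64") {
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(3, 4)))
    stop_config("img must be a 3D or 4D array")
  dt <- NIFTI_DT[NIFTI_DT$name == datatype, ]
  if (nrow(dt) != 1) stop_config("unsupported datatype: %s", datatype)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  dims <- rep(1L, 8); dims[1] <- length(d); dims[1 + seq_along(d)] <- d
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:4] <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (length(d) == 4) pixdim[5] <- 1

  con <- nifti_con(path, "wb")
  on.exit(close(con))
  w_i4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_i2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_f4 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i4(348L)                       # sizeof_hdr
  w_raw(35)                        # data_type, db_name, extents, ...
  writeBin(as.raw(0L), con)        # dim_info
  w_i2(dims)                       # dim[8]
  w_f4(c(0, 0, 0)); w_i2(0L)       # intent_p1..3, intent_code
  w_i2(dt$code); w_i2(dt$bitpix)   # datatype, bitpix
  w_i2(0L)                         # slice_start
  w_f4(pixdim)                     # pixdim[8]
  w_f4(352)                        # vox_offset
  w_f4(1); w_f4(0)                 # scl_slope, scl_inter
  w_i2(0L); w_raw(2)               # slice_end, slice_code, xyzt_units
  w_f4(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i4(c(0L, 0L))                  # glmax, glmin
  w_raw(104)                       # descrip, aux_file
  w_i2(0L); w_i2(2L)               # qform_code = 0, sform_code = 2
  w_f4(c(0, 0, 0, 0, 0, 0))        # quaternion, qoffsets
  w_f4(t(affine[1:3, ]))           # srow_x, srow_y, srow_z
  w_raw(16)                        # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(as.raw(0L), con)        # magic terminator
  w_raw(4)                         # extension flag

  v <- as.vector(img)
  if (datatype %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(v)), con, size = dt$bitpix / 8, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = dt$bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or any uncompressed/gzipped
#' single-file NIfTI-1 with a supported datatype)
#'
#' @param path `.nii` or `.nii.gz` path.
#' @return array with attributes `affine` (4x4) and `voxel_size` (length 3).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_config("file not found: %s", path)
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop_config("truncated NIfTI header: %s", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", 1, size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", 1, size = 4, endian = endian)
    if (sz != 348L) stop_config("not a NIfTI-1 file: %s", path)
  }
  geti2 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 2 * n)],
                                        "integer", n, size = 2, endian = endian)
  getf4 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)],
                                        "numeric", n, size = 4, endian = endian)
  dims <- geti2(40, 8)
  nd <- dims[1]
  if (!(nd %in% c(3, 4))) stop_config("unsupported dimensionality: %d", nd)
  d <- dims[2:(1 + nd)]
  datatype <- geti2(70)
  dt <- NIFTI_DT[NIFTI_DT$code == datatype, ]
  if (nrow(dt) != 1) stop_config("unsupported NIfTI datatype code %d", datatype)
  pixdim <- getf4(76, 8)
  vox_offset <- getf4(108)
  scl_slope <- getf4(112); scl_inter <- getf4(116)
  sform_code <- geti2(254)
  srow <- matrix(getf4(280, 12), 3, 4, byrow = TRUE)
  affine <- if (sform_code > 0) rbind(srow, c(0, 0, 0, 1)) else
    diag(c(pixdim[2:4], 1))

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  img <- if (dt$name == "uint8") {
    readBin(con, "integer", n, size = 1, signed = FALSE)
  } else if (dt$name %in% c("int16", "int32")) {
    readBin(con, "integer", n, size = dt$bitpix / 8, endian = endian)
  } else {
    readBin(con, "numeric", n, size = dt$bitpix / 8, endian = endian)
  }
  if (length(img) != n) stop_config("truncated NIfTI data: %s", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    img <- img * scl_slope + scl_inter
  }
  dim(img) <- d
  attr(img, "affine") <- affine
  attr(img, "voxel_size") <- pixdim[2:4]
  img
}

#' Write an in-mask statistic vector (or 3D array) as a NIfTI map
#'
#' @param map numeric vector over in-mask voxels, or a 3D array.
#' @param mask logical 3D array (required for vectors).
#' @param affine 4x4 voxel-to-world matrix.
#' @param path output path.
#' @param datatype storage type (default `"float64"`).
#' @return the path, invisibly.
#' @export
write_map <- function(map, affine, path, mask = NULL, datatype = "float64") {
  if (!is.array(map) || length(dim(map)) != 3) {
    if (is.null(mask)) stop_config("mask required for vector maps")
    map <- inflate(as.numeric(map), mask)
  }
  write_nifti(map, path, affine = affine, datatype = datatype)
}

#' Read aligned subject volumes into a volume stack
#'
#' Accepts either one 4D NIfTI file or one 3D file per subject. Subject order
#' is taken from the covariate table; grids and affines must agree across
#' files and with the mask, and mismatches are reported per offender.
#'
#' @param volume_paths character vector: a single 4D file or one 3D file per
#'   cohort row.
#' @param mask_path NIfTI mask (nonzero = in mask).
#' @param cohort cohort table defining the subject order.
#' @return a [volume_stack()].
#' @export
read_volumes <- function(volume_paths, mask_path, cohort) {
  validate_cohort(cohort)
  mask_img <- read_nifti(mask_path)
  mask <- array(mask_img != 0, dim(mask_img))
  affine <- attr(mask_img, "affine")
  n <- nrow(cohort)
  offenders <- character(0)
  check <- function(img, label) {
    if (!identical(dim(img)[1:3], dim(mask))) {
      offenders <<- c(offenders, sprintf("%s: grid %s vs mask %s", label,
                                         paste(dim(img)[1:3], collapse = "x"),
                                         paste(dim(mask), collapse = "x")))
    } else if (max(abs(attr(img, "affine") - affine)) > 1e-4) {
      offenders <<- c(offenders, sprintf("%s: affine differs from mask", label))
    }
  }
  if (length(volume_paths) == 1) {
    img <- read_nifti(volume_paths)
    if (length(dim(img)) != 4)
      stop_config("expected a 4D file or one 3D file per subject")
    check(img, basename(volume_paths))
    if (length(offenders)) stop_config("%s", paste(offenders, collapse = "; "))
    if (dim(img)[4] != n)
      stop_config("4D file has %d volumes but the covariate table has %d rows",
                  dim(img)[4], n)
    data <- t(apply(img, 4, function(v) v[mask]))
  } else {
    if (length(volume_paths) != n)
      stop_config("%d volume files for %d covariate rows (missing volume for: %s)",
                  length(volume_paths), n,
                  paste(utils::tail(cohort$subject_id, n - length(volume_paths)),
                        collapse = ", "))
    data <- matrix(0, n, sum(mask))
    for (i in seq_len(n)) {
      img <- read_nifti(volume_paths[i])
      check(img, cohort$subject_id[i])
      if (!length(offenders)) data[i, ] <- img[mask]
    }
    if (length(offenders)) stop_config("%s", paste(offenders, collapse = "; "))
  }
  rownames(data) <- cohort$subject_id
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  volume_stack(data, mask, voxel_size = vs[1], subject_id = cohort$subject_id,
               affine = affine)
}
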