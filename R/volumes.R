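#' Construct a volume stack
#'
#' The package's in-memory container for a set of spatially aligned 3D
#' volumes: an `n_subjects x n_voxels` matrix holding the in-mask values,
#' the binary analysis mask, and the voxel geometry. All voxelwise modelling
#' operates on this matrix; NIfTI inflation happens only at I/O time.
#'
#' @param data numeric matrix, subjects in rows, in-mask voxels in columns
#'   (column order = `which(mask)`).
#' @param mask logical 3D array.
#' @param voxel_size voxel edge in mm.
#' @param subject_id character vector, one id per row.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a scaled
#'   identity built from `voxel_size`.
#' @return an object of class `volume_stack`.
#' @export
volume_stack <- function(data, mask, voxel_size = 1, subject_id = rownames(data),
                         affine = NULL) {
  stopifnot(is.matrix(data), is.logical(mask), length(dim(mask)) == 3)
  if (ncol(data) != sum(mask))
    stop_config("data has %d columns but mask has %d voxels", ncol(data), sum(mask))
  if (is.null(subject_id)) subject_id <- sprintf("S%04d", seq_len(nrow(data)))
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size, 3), 1))
  }
  structure(list(data = data, mask = mask, voxel_size = voxel_size,
                 subject_id = subject_id, affine = affine),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf("volume_stack: %d subjects x %d in-mask voxels (grid %s, %g mm)\n",
              nrow(x$data), ncol(x$data), paste(dim(x$mask), collapse = "x"),
              x$voxel_size))
  invisible(x)
}

# voxel indices (into the full grid) within euclidean radius r of a centre
sphere_indices <- function(center, radius, grid_shape) {
  r <- max(0, floor(radius))
  rng <- function(c, n) max(1L, c - r):min(n, c + r)
  xs <- rng(center[1], grid_shape[1])
  ys <- rng(center[2], grid_shape[2])
  zs <- rng(center[3], grid_shape[3])
  g <- expand.grid(x = xs, y = ys, z = zs)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  g <- g[d2 <= radius^2, , drop = FALSE]
  as.integer(g$x + (g$y - 1L) * grid_shape[1] +
               (g$z - 1L) * grid_shape[1] * grid_shape[2])
}

# deterministic fields of the generator: analysis mask, baseline volume,
# per-voxel age slope (octant regions), shared ROI indices
generator_fields <- function(config) {
  gs <- config$grid_shape
  m <- config$mask_margin
  mask <- array(FALSE, gs)
  mask[(1 + m):(gs[1] - m), (1 + m):(gs[2] - m), (1 + m):(gs[3] - m)] <- TRUE

  cx <- (seq_len(gs[1]) - (gs[1] + 1) / 2) / (gs[1] / 2)
  cy <- (seq_len(gs[2]) - (gs[2] + 1) / 2) / (gs[2] / 2)
  cz <- (seq_len(gs[3]) - (gs[3] + 1) / 2) / (gs[3] / 2)
  rho2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  baseline <- 0.6 - 0.2 * rho2

  octant <- function(v, n) as.integer(v > n / 2)
  ox <- octant(seq_len(gs[1]), gs[1])
  oy <- octant(seq_len(gs[2]), gs[2])
  oz <- octant(seq_len(gs[3]), gs[3])
  region <- 1L + outer(outer(ox, 2L * oy, `+`), 4L * oz, `+`)
  slope <- array(config$regional_age_slopes[region], gs)

  shared_roi <- integer(0)
  if (!is.null(config$shared_roi_center) && config$shared_roi_radius > 0) {
    shared_roi <- sphere_indices(config$shared_roi_center,
                                 config$shared_roi_radius, gs)
    shared_roi <- shared_roi[mask[shared_roi]]
    if (!all(mask[shared_roi]))
      stop_config("shared ROI extends outside the analysis mask")
  }
  list(mask = mask, baseline = baseline, slope = slope, region = region,
       shared_roi = shared_roi)
}

#' Generate synthetic tissue-volume maps with known ground truth
#'
#' Each subject's volume is `baseline + age * slope + sex_offset * male +`
#' spatially smoothed noise (renormalised so the marginal per-voxel sd equals
#' `noise_sd` exactly). Patients additionally receive
#' `n_idiosyncratic_lesions` spherical lesions of amplitude
#' `lesion_effect * noise_sd` at locations drawn independently per patient
#' (uniform over the mask excluding the shared region), plus a shared-region
#' effect `shared_effect * g_i * noise_sd` where `g_i` is a mean-1 gamma
#' multiplier with coefficient of variation `shared_heterogeneity`.
#'
#' @param cohort a cohort table from [generate_cohort()].
#' @param config the same [simulation_config()] used for the cohort.
#' @return a list with elements `volumes` (a [volume_stack()]) and `truth`
#'   (class `ground_truth`): per-patient lesion voxel indices and signs,
#'   shared-ROI indices and per-patient multipliers, and the true trend
#'   fields.
#' @export
generate_volumes <- function(cohort, config) {
  stopifnot(inherits(config, "simulation_config"))
  validate_cohort(cohort)
  if (nrow(cohort) == 0) stop_config("cohort is empty")
  fields <- generator_fields(config)
  gs <- config$grid_shape
  mask_idx <- which(fields$mask)
  V <- length(mask_idx)
  n <- nrow(cohort)

  sd_field <- smoothing_sd_field(gs, config$smoothing_fwhm, config$voxel_size)
  base_v <- fields$baseline[mask_idx]
  slope_v <- fields$slope[mask_idx]
  male <- as.numeric(cohort$sex == "male")
  is_patient <- cohort$diagnosis == "patient"
  patients <- which(is_patient)

  # map grid index -> column of the data matrix
  col_of <- integer(prod(gs))
  col_of[mask_idx] <- seq_len(V)
  shared_cols <- col_of[fields$shared_roi]

  with_seed(config$seed + 1L, {
    data <- matrix(0, n, V)
    for (i in seq_len(n)) {
      noise <- array(rnorm(prod(gs)), gs)
      if (config$smoothing_fwhm > 0) {
        noise <- gaussian_smooth(noise, config$smoothing_fwhm, config$voxel_size)
        noise <- noise / sd_field
      }
      data[i, ] <- base_v + cohort$age[i] * slope_v +
        config$sex_offset * male[i] + config$noise_sd * noise[mask_idx]
    }

    lesion_voxels <- vector("list", n)
    effect_sign <- vector("list", n)
    multiplier <- rep(NA_real_, n)
    candidates <- setdiff(mask_idx, fields$shared_roi)
    grid_xyz <- arrayInd(seq_len(prod(gs)), gs)
    for (i in patients) {
      vox <- integer(0)
      if (config$n_idiosyncratic_lesions > 0) {
        centers <- sample(candidates, config$n_idiosyncratic_lesions)
        for (cc in centers) {
          sp <- sphere_indices(grid_xyz[cc, ], config$lesion_radius, gs)
          sp <- sp[fields$mask[sp] & !(sp %in% fields$shared_roi)]
          vox <- union(vox, sp)
        }
        data[i, col_of[vox]] <- data[i, col_of[vox]] +
          config$lesion_effect * config$noise_sd
      }
      lesion_voxels[[i]] <- sort(vox)
      effect_sign[[i]] <- rep(ifelse(config$lesion_effect >= 0, "positive",
                                     "negative"), length(vox))
      if (length(shared_cols)) {
        g <- if (config$shared_heterogeneity > 0) {
          cv2 <- config$shared_heterogeneity^2
          rgamma(1, shape = 1 / cv2, scale = cv2)
        } else 1
        multiplier[i] <- g
        data[i, shared_cols] <- data[i, shared_cols] +
          config$shared_effect * g * config$noise_sd
      }
    }
    rownames(data) <- cohort$subject_id
    vols <- volume_stack(data, fields$mask, config$voxel_size,
                         cohort$subject_id)
    truth <- structure(list(
      lesion_voxels = lesion_voxels, effect_sign = effect_sign,
      shared_roi = fields$shared_roi, shared_multiplier = multiplier,
      slope_field = fields$slope, sex_offset = config$sex_offset,
      baseline = fields$baseline, mask = fields$mask,
      subject_id = cohort$subject_id, diagnosis = cohort$diagnosis),
      class = "ground_truth")
    list(volumes = vols, truth = truth)
  })
}

#' @importFrom stats rgamma
NULL

#' Noise-free expected volume for given covariates
#'
#' The generator's own deterministic field (baseline + age trend + sex
#' offset), used as an oracle in tests.
#'
#' @param truth a `ground_truth` object.
#' @param age,sex scalar covariates.
#' @param config the generating [simulation_config()].
#' @return numeric vector over in-mask voxels.
#' @export
expected_volume <- function(truth, age, sex, config) {
  idx <- which(truth$mask)
  truth$baseline[idx] + age * truth$slope_field[idx] +
    config$sex_offset * as.numeric(sex == "male")
}
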