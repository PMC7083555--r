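#' Simulation configuration for the synthetic VBM cohort
#'
#' Collects every knob of the synthetic-data generator into a validated list.
#' The defaults describe the package's reference world: a cohort matched in
#' age and sex (146 reference subjects, 153 patients, mirroring a typical
#' single-site adult case-control sample), a coarse 20x20x20 grid of 4 mm
#' voxels standing in for down-sampled whole-brain VBM maps, 8 mm FWHM
#' spatially correlated noise, three single-voxel idiosyncratic lesions per
#' patient at -4 standard deviations, and one shared spherical region with a
#' heterogeneous negative effect (mean 0.5 sd). See the methods vignette for
#' the rationale behind each default.
#'
#' @param n_controls,n_patients group sizes (non-negative integers, total >= 1).
#' @param grid_shape integer vector (nx, ny, nz) of the voxel grid.
#' @param voxel_size isotropic voxel edge in mm.
#' @param smoothing_fwhm full width at half maximum of the Gaussian kernel
#'   applied to the noise field, in mm.
#' @param mask_margin voxels trimmed from each face to form the analysis mask.
#' @param age_min,age_max support of the uniform age distribution (years).
#' @param p_male probability of sex "male" (identical in both groups).
#' @param regional_age_slopes named numeric vector of per-year volume slopes,
#'   one per octant of the grid (length 8).
#' @param sex_offset additive volume offset for males, volume units.
#' @param noise_sd marginal standard deviation of the smoothed noise field.
#' @param n_idiosyncratic_lesions lesions implanted per patient.
#' @param lesion_radius lesion radius in voxels (0.5 = single voxel).
#' @param lesion_effect lesion amplitude in multiples of `noise_sd` (signed).
#' @param shared_roi_center,shared_roi_radius centre (voxel indices) and
#'   radius (voxels) of the shared-effect sphere; `NULL` centre disables it.
#' @param shared_effect shared-region amplitude in multiples of `noise_sd`
#'   (signed); per-patient magnitude is `shared_effect * g_i`.
#' @param shared_heterogeneity coefficient of variation of the per-patient
#'   gamma multiplier `g_i` (mean 1); 0 gives a constant effect, the default 1
#'   gives exponential heterogeneity.
#' @param hyperactivity_means,inattention_means length-2 numeric vectors
#'   `c(patient, control)` of symptom-score means (truncated Poisson, 0-9).
#' @param medication_p_patient probability a patient is medicated.
#' @param comorbidity_means length-2 `c(patient, control)` Poisson means.
#' @param seed integer seed; fully determines cohort, volumes and ground truth.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_controls = 146L,
                              n_patients = 153L,
                              grid_shape = c(20L, 20L, 20L),
                              voxel_size = 4,
                              smoothing_fwhm = 8,
                              mask_margin = 1L,
                              age_min = 18,
                              age_max = 65,
                              p_male = 0.42,
                              regional_age_slopes = c(
                                frontal_l = -0.0050, frontal_r = -0.0045,
                                temporal_l = -0.0040, temporal_r = -0.0035,
                                parietal_l = -0.0030, parietal_r = -0.0025,
                                occipital_l = -0.0020, occipital_r = -0.0015),
                              sex_offset = 0.02,
                              noise_sd = 0.05,
                              n_idiosyncratic_lesions = 3L,
                              lesion_radius = 0.5,
                              lesion_effect = -4,
                              shared_roi_center = c(7L, 13L, 11L),
                              shared_roi_radius = 4,
                              shared_effect = -0.5,
                              shared_heterogeneity = 1,
                              hyperactivity_means = c(5.45, 0.63),
                              inattention_means = c(7.27, 0.55),
                              medication_p_patient = 0.7,
                              comorbidity_means = c(0.8, 0.1),
                              seed = 1L) {
  n_controls <- as.integer(n_controls)
  n_patients <- as.integer(n_patients)
  if (is.na(n_controls) || is.na(n_patients) || n_controls < 0 || n_patients < 0)
    stop_config("group sizes must be non-negative integers")
  if (n_controls + n_patients < 1)
    stop_config("cohort must contain at least one subject")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 4))
    stop_config("grid_shape must be three integers >= 4")
  if (voxel_size <= 0) stop_config("voxel_size must be positive")
  if (smoothing_fwhm < 0) stop_config("smoothing_fwhm must be >= 0")
  if (age_max <= age_min) stop_config("age_max must exceed age_min")
  if (length(regional_age_slopes) != 8)
    stop_config("regional_age_slopes must have one slope per octant (8)")
  if (!is.finite(lesion_effect) || !is.finite(shared_effect))
    stop_config("lesion_effect and shared_effect must be finite")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (lesion_radius >= min(grid_shape) / 2)
    stop_config("lesion_radius (%g voxels) exceeds the grid", lesion_radius)
  if (n_idiosyncratic_lesions < 0)
    stop_config("n_idiosyncratic_lesions must be >= 0")
  cfg <- list(
    n_controls = n_controls, n_patients = n_patients,
    grid_shape = grid_shape, voxel_size = voxel_size,
    smoothing_fwhm = smoothing_fwhm, mask_margin = as.integer(mask_margin),
    age_min = age_min, age_max = age_max, p_male = p_male,
    regional_age_slopes = regional_age_slopes, sex_offset = sex_offset,
    noise_sd = noise_sd,
    n_idiosyncratic_lesions = as.integer(n_idiosyncratic_lesions),
    lesion_radius = lesion_radius, lesion_effect = lesion_effect,
    shared_roi_center = if (is.null(shared_roi_center)) NULL else as.integer(shared_roi_center),
    shared_roi_radius = shared_roi_radius,
    shared_effect = shared_effect,
    shared_heterogeneity = shared_heterogeneity,
    hyperactivity_means = hyperactivity_means,
    inattention_means = inattention_means,
    medication_p_patient = medication_p_patient,
    comorbidity_means = comorbidity_means,
    seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: %d controls + %d patients, grid %s @ %g mm, seed %d\n",
    x$n_controls, x$n_patients, paste(x$grid_shape, collapse = "x"),
    x$voxel_size, x$seed))
  invisible(x)
}
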