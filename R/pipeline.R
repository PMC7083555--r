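#' Pipeline configuration
#'
#' Assembles and validates the full-run configuration: either a simulation
#' block (synthetic mode) or input paths (real mode), model options,
#' thresholds and per-stage seeds. The object round-trips losslessly through
#' YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param simulate generate data with the synthetic cohort module (`TRUE`) or
#'   read `volumes`/`covariates`/`mask` paths (`FALSE`).
#' @param sim a [simulation_config()] or a list of its arguments.
#' @param volumes,covariates,mask input paths (real mode).
#' @param kfold folds for the reference cross-validation.
#' @param shared_hyperparameters shared-kernel fast path (see
#'   [crossval_reference()]).
#' @param subsample voxels for the pooled hyperparameter fit.
#' @param separate_sexes fit normative models per sex.
#' @param threshold fixed Z threshold for extreme deviations.
#' @param fdr_q per-subject FDR level (also used for the group contrast).
#' @param overlap_cut overlap exceedance cut.
#' @param n_perm permutations for group inference.
#' @param tfce list with `H`, `E`, `connectivity` (and optional `dh`).
#' @param seed master seed; per-stage seeds are derived deterministically.
#' @param out default output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = TRUE, sim = list(),
                            volumes = NULL, covariates = NULL, mask = NULL,
                            kfold = 10, shared_hyperparameters = TRUE,
                            subsample = 256, separate_sexes = FALSE,
                            threshold = 2.6, fdr_q = 0.05, overlap_cut = 0.02,
                            n_perm = 500,
                            tfce = list(H = 2, E = 0.5, connectivity = 26),
                            seed = 1L, out = NULL) {
  if (simulate) {
    if (!inherits(sim, "simulation_config")) {
      sim$seed <- sim$seed %||% seed
      sim <- do.call(simulation_config, sim)
    }
  } else {
    if (is.null(volumes) || is.null(covariates) || is.null(mask))
      stop_config("real mode needs volumes, covariates and mask paths")
  }
  cfg <- list(simulate = simulate, sim = sim, volumes = volumes,
              covariates = covariates, mask = mask, kfold = kfold,
              shared_hyperparameters = shared_hyperparameters,
              subsample = subsample, separate_sexes = separate_sexes,
              threshold = threshold, fdr_q = fdr_q, overlap_cut = overlap_cut,
              n_perm = n_perm, tfce = tfce,
              seed = as.integer(seed),
              seeds = list(simulate = as.integer(seed),
                           folds = as.integer(seed) + 1000L,
                           perm = as.integer(seed) + 2000L,
                           scoretests = as.integer(seed) + 3000L),
              out = out)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- if (inherits(x$sim, "simulation_config")) unclass(x$sim) else x$sim
  # named atomic vectors must become maps to survive the YAML round trip
  if (!is.null(x$sim$regional_age_slopes))
    x$sim$regional_age_slopes <- as.list(x$sim$regional_age_slopes)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  x <- yaml::read_yaml(path)
  x$seeds <- NULL
  if (!is.null(x$sim) && length(x$sim)) {
    x$sim$grid_shape <- as.integer(unlist(x$sim$grid_shape))
    x$sim$regional_age_slopes <- unlist(x$sim$regional_age_slopes)
    x$sim$shared_roi_center <-
      if (is.null(x$sim$shared_roi_center)) NULL else
        as.integer(unlist(x$sim$shared_roi_center))
    x$sim$hyperactivity_means <- unlist(x$sim$hyperactivity_means)
    x$sim$inattention_means <- unlist(x$sim$inattention_means)
    x$sim$comorbidity_means <- unlist(x$sim$comorbidity_means)
  }
  do.call(pipeline_config, x)
}

stack_to_4d <- function(stack_mat, mask) {
  arr <- array(0, c(dim(mask), nrow(stack_mat)))
  for (i in seq_len(nrow(stack_mat))) {
    v <- array(0, dim(mask)); v[mask] <- stack_mat[i, ]
    arr[, , , i] <- v
  }
  arr
}

#' Run the full five-stage pipeline
#'
#' simulate (optional) -> fit/crossval -> score -> deviations/overlap ->
#' group inference -> score tests, writing every artifact plus a manifest
#' with parameters, seeds and per-file MD5 checksums. Re-running with the
#' same config reproduces byte-identical numeric outputs. A stage failure
#' halts with a stage-tagged error and leaves a `FAILED` marker in the run
#' directory.
#'
#' @param config a [pipeline_config()].
#' @param out run directory (overrides `config$out`).
#' @return the run directory, invisibly; the result objects are attached as
#'   the attribute `"results"`.
#' @export
run_pipeline <- function(config, out = config$out) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(out)) stop_config("no output directory given")
  if (!config$simulate) {
    for (p in c(config$volumes, config$covariates, config$mask)) {
      if (!file.exists(p)) stop_config("input path does not exist: %s", p)
    }
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out, "FAILED"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s: %s", name, conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  res <- list(config = config)

  stage("simulate/load", {
    if (config$simulate) {
      cohort <- generate_cohort(config$sim)
      gen <- generate_volumes(cohort, config$sim)
      vols <- gen$volumes
      res$truth <- gen$truth
      write_cohort_csv(cohort, file.path(out, "cohort.csv"))
      write_nifti(array(as.integer(vols$mask), dim(vols$mask)),
                  file.path(out, "mask.nii.gz"), affine = vols$affine,
                  datatype = "uint8")
      write_nifti(stack_to_4d(vols$data, vols$mask),
                  file.path(out, "volumes.nii.gz"), affine = vols$affine)
      pat <- which(cohort$diagnosis == "patient")
      if (length(pat)) {
        gt <- array(0L, c(dim(vols$mask), length(pat)))
        for (j in seq_along(pat)) {
          m <- array(0L, dim(vols$mask))
          m[res$truth$lesion_voxels[[pat[j]]]] <- 1L
          m[res$truth$shared_roi] <- 2L
          gt[, , , j] <- m
        }
        write_nifti(gt, file.path(out, "ground_truth.nii.gz"),
                    affine = vols$affine, datatype = "uint8")
      }
      jsonlite::write_json(
        list(shared_roi = res$truth$shared_roi,
             shared_multiplier = res$truth$shared_multiplier,
             lesion_voxels = res$truth$lesion_voxels,
             subject_id = res$truth$subject_id),
        file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
        null = "null")
    } else {
      cohort <- read_cohort_csv(config$covariates)
      vols <- read_volumes(config$volumes, config$mask, cohort)
    }
    res$cohort <- cohort
    res$volumes <- vols
  })
  cohort <- res$cohort; vols <- res$volumes

  stage("fit/crossval", {
    res$dev_controls <- crossval_reference(
      vols, cohort, k = config$kfold, seed = config$seeds$folds,
      shared_hyperparameters = config$shared_hyperparameters,
      subsample = config$subsample, separate_sexes = config$separate_sexes)
    write_nifti(stack_to_4d(res$dev_controls$z, vols$mask),
                file.path(out, "z_controls.nii.gz"), affine = vols$affine)
  })

  stage("score", {
    res$dev_patients <- score_targets(
      vols, cohort, shared_hyperparameters = config$shared_hyperparameters,
      subsample = config$subsample, separate_sexes = config$separate_sexes)
    if (nrow(res$dev_patients$z))
      write_nifti(stack_to_4d(res$dev_patients$z, vols$mask),
                  file.path(out, "z_patients.nii.gz"), affine = vols$affine)
  })

  stage("deviations", {
    sc <- rbind(extreme_scores(res$dev_controls, threshold = config$threshold),
                if (nrow(res$dev_patients$z))
                  extreme_scores(res$dev_patients, threshold = config$threshold))
    sc_fdr <- rbind(
      extreme_scores(res$dev_controls, "per-subject-FDR", q = config$fdr_q),
      if (nrow(res$dev_patients$z))
        extreme_scores(res$dev_patients, "per-subject-FDR", q = config$fdr_q))
    res$scores <- sc
    write.csv(rbind(sc, sc_fdr), file.path(out, "scores.csv"),
              row.names = FALSE, quote = FALSE)
    groups <- list(controls = res$dev_controls)
    if (nrow(res$dev_patients$z)) groups$patients <- res$dev_patients
    ov <- list()
    for (g in names(groups)) {
      pairs <- extreme_mask_pairs(groups[[g]], threshold = config$threshold)
      for (dirn in c("negative", "positive")) {
        om <- overlap_map(pairs, dirn, cut = config$overlap_cut)
        ov[[paste(g, dirn, sep = "_")]] <- om
        write_map(om$proportion, vols$affine,
                  file.path(out, sprintf("overlap_%s_%s.nii.gz", g, dirn)),
                  mask = vols$mask)
        write_map(as.numeric(om$exceed), vols$affine,
                  file.path(out, sprintf("exceed_%s_%s.nii.gz", g, dirn)),
                  mask = vols$mask, datatype = "uint8")
      }
    }
    res$overlap <- ov
  })

  stage("inference", {
    res$mean_controls <- group_mean_map(res$dev_controls, config$n_perm,
                                         config$seeds$perm,
                                         display_z = config$threshold)
    write_map(res$mean_controls$z_equivalent, vols$affine,
              file.path(out, "mean_z_controls.nii.gz"), mask = vols$mask)
    if (nrow(res$dev_patients$z) >= 2) {
      res$mean_patients <- group_mean_map(res$dev_patients, config$n_perm,
                                           config$seeds$perm + 1L,
                                           display_z = config$threshold)
      write_map(res$mean_patients$z_equivalent, vols$affine,
                file.path(out, "mean_z_patients.nii.gz"), mask = vols$mask)
      tf <- do.call(tfce_params, config$tfce)
      res$contrast <- group_contrast_map(res$dev_controls, res$dev_patients,
                                          tfce = tf, q = config$fdr_q,
                                          n_perm = config$n_perm,
                                          seed = config$seeds$perm + 2L)
      write_map(res$contrast$stat, vols$affine,
                file.path(out, "contrast_t.nii.gz"), mask = vols$mask)
      write_map(res$contrast$p_corrected, vols$affine,
                file.path(out, "contrast_p_fdr.nii.gz"), mask = vols$mask)
      write_map(as.numeric(res$contrast$significant_mask), vols$affine,
                file.path(out, "contrast_significant.nii.gz"),
                mask = vols$mask, datatype = "uint8")
    }
  })

  stage("scoretests", {
    if (any(cohort$diagnosis == "patient") && any(cohort$diagnosis == "control")) {
      st <- score_group_tests(res$scores, cohort, n_perm = 0,
                              seed = config$seeds$scoretests)
      assoc <- tryCatch(association_tests(res$scores, cohort),
                        error = function(e) NULL)
      res$score_tests <- st
      res$associations <- assoc
      jsonlite::write_json(
        list(score_tests = lapply(st, function(x)
          list(measure = x$measure, statistic = x$statistic, df = x$df,
               p = x$p, p_corrected = x$p_corrected,
               effect_direction = x$effect_direction,
               group_estimates = as.data.frame(x$group_estimates))),
          associations = assoc,
          seeds = config$seeds, n_perm = config$n_perm),
        file.path(out, "results.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "rows", null = "null")
    }
  })

  stage("manifest", {
    files <- sort(setdiff(list.files(out), c("manifest.json", "FAILED")))
    manifest <- list(
      package = "normdev",
      version = as.character(utils::packageVersion("normdev")),
      parameters = serializable_config(config),
      seeds = config$seeds,
      files = data.frame(
        file = files,
        md5 = unname(tools::md5sum(file.path(out, files))),
        stringsAsFactors = FALSE))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })

  out <- structure(out, results = res)
  invisible(out)
}

serializable_config <- function(config) {
  x <- unclass(config)
  x$sim <- if (inherits(x$sim, "simulation_config")) unclass(x$sim) else x$sim
  x
}
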