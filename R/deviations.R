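#' Threshold a Z deviation map into extreme-deviation masks
#'
#' Strict fixed-threshold rule: positive mask is `Z > threshold`, negative
#' mask is `Z < -threshold`; voxels exactly at the threshold are excluded.
#'
#' @param z_map numeric vector of in-mask Z-scores, or a 3D array with `mask`.
#' @param threshold positive Z cutoff (default 2.6).
#' @param mask logical 3D array (required when `z_map` is an array).
#' @return list of class `extreme_mask_pair`: logical vectors `positive`,
#'   `negative` over in-mask voxels, plus `threshold` and `method`.
#' @export
threshold_map <- function(z_map, threshold = 2.6, mask = NULL) {
  if (threshold <= 0) stop_config("threshold must be > 0")
  z <- extract_in_mask(z_map, mask)
  if (any(!is.finite(z))) stop("non-finite Z inside mask")
  structure(list(positive = z > threshold, negative = z < -threshold,
                 threshold = threshold, method = "fixed-threshold"),
            class = "extreme_mask_pair")
}

#' Threshold a Z map by per-subject Benjamini-Hochberg FDR
#'
#' Two-sided normal p-values `p = 2 * pnorm(-|Z|)` are corrected across the
#' subject's in-mask voxels with the Benjamini-Hochberg step-up procedure;
#' surviving voxels are split by the sign of Z.
#'
#' @inheritParams threshold_map
#' @param q FDR level in (0, 1).
#' @return an `extreme_mask_pair` (method `"per-subject-FDR"`); the realized
#'   BH Z cutoff is attached as `z_cutoff` (`Inf` if nothing survives).
#' @export
threshold_map_fdr <- function(z_map, q = 0.05, mask = NULL) {
  if (q <= 0 || q >= 1) stop_config("q must be in (0, 1)")
  z <- extract_in_mask(z_map, mask)
  if (any(!is.finite(z))) stop("non-finite Z inside mask")
  p <- 2 * pnorm(-abs(z))
  rej <- p.adjust(p, method = "BH") <= q
  z_cut <- if (any(rej)) min(abs(z)[rej]) else Inf
  structure(list(positive = rej & z > 0, negative = rej & z < 0,
                 threshold = q, method = "per-subject-FDR", z_cutoff = z_cut),
            class = "extreme_mask_pair")
}

extract_in_mask <- function(z_map, mask) {
  if (is.array(z_map) && length(dim(z_map)) == 3) {
    if (is.null(mask)) stop_config("mask is required with a 3D z_map")
    z_map[mask]
  } else {
    as.numeric(z_map)
  }
}

#' One extreme-deviation mask pair per subject of a deviation stack
#'
#' @param deviations a [deviation_stack()].
#' @param method,threshold,q see [extreme_scores()].
#' @return list of `extreme_mask_pair`s in subject order.
#' @export
extreme_mask_pairs <- function(deviations, method = c("fixed-threshold",
                                                      "per-subject-FDR"),
                               threshold = 2.6, q = 0.05) {
  method <- match.arg(method)
  lapply(seq_len(nrow(deviations$z)), function(i) {
    if (method == "fixed-threshold") threshold_map(deviations$z[i, ], threshold)
    else threshold_map_fdr(deviations$z[i, ], q)
  })
}

#' Percentage of extreme positive/negative deviations per subject
#'
#' For each subject, the percentage of in-mask voxels whose deviation is
#' extreme: `pct = 100 * (# extreme voxels) / (# in-mask voxels)`.
#'
#' @param deviations a [deviation_stack()].
#' @param method `"fixed-threshold"` (|Z| > `threshold`) or
#'   `"per-subject-FDR"` (BH at level `q`).
#' @param threshold,q parameters of the two methods.
#' @return data.frame with `subject_id`, `pct_positive`, `pct_negative`,
#'   `n_mask_voxels`, `method`, `threshold`.
#' @export
extreme_scores <- function(deviations, method = "fixed-threshold",
                           threshold = 2.6, q = 0.05) {
  stopifnot(inherits(deviations, "deviation_stack"))
  n_mask <- ncol(deviations$z)
  if (n_mask == 0) stop_config("empty analysis mask")
  pairs <- extreme_mask_pairs(deviations, method, threshold, q)
  data.frame(
    subject_id = deviations$subject_id,
    pct_positive = 100 * vapply(pairs, function(p) sum(p$positive), 0) / n_mask,
    pct_negative = 100 * vapply(pairs, function(p) sum(p$negative), 0) / n_mask,
    n_mask_voxels = n_mask,
    method = method,
    threshold = if (method == "fixed-threshold") threshold else q,
    stringsAsFactors = FALSE)
}

#' Voxelwise overlap of extreme-deviation masks within a group
#'
#' `proportion(v)` is the fraction of the group's subjects whose extreme mask
#' (in the requested direction) includes voxel `v`. The denominator is the
#' full group size, including subjects with empty masks. The derived binary
#' map `exceed` flags voxels with `proportion > cut` (strict), the reading
#' level used for "overlap in more than 2% of individuals".
#'
#' @param pairs list of `extreme_mask_pair` objects, one per subject of one
#'   group (all on the same grid).
#' @param direction `"negative"` or `"positive"`.
#' @param cut exceedance cut on the proportion (default 0.02).
#' @return list of class `overlap_map`: `proportion` (numeric vector over
#'   in-mask voxels), `exceed` (logical), `n_subjects`, `direction`, `cut`.
#' @export
overlap_map <- function(pairs, direction = c("negative", "positive"),
                        cut = 0.02) {
  direction <- match.arg(direction)
  if (!length(pairs)) stop_config("overlap_map needs at least one subject")
  lens <- vapply(pairs, function(p) length(p[[direction]]), 0L)
  if (length(unique(lens)) != 1)
    stop_config("extreme masks live on different grids")
  counts <- Reduce(`+`, lapply(pairs, function(p) as.numeric(p[[direction]])))
  prop <- counts / length(pairs)
  structure(list(proportion = prop, exceed = prop > cut,
                 n_subjects = length(pairs), direction = direction, cut = cut),
            class = "overlap_map")
}
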