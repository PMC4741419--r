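# Per-subject, per-region feature extraction.
#
# Both analysis arms use the same normal-appearing (lesion-excluded) voxel
# set, so they differ only in the statistic: the PV arm summarizes a region
# by (mu_gm, mu_wm, C_GM/C_WM), the global arm by the plain mean T1.

#' Restrict a region mask to normal-appearing tissue
#'
#' Returns `region AND NOT lesion`. Removing lesion voxels before any
#' statistic is computed keeps both analysis arms on normal-appearing
#' tissue only.
#'
#' @param region_mask,lesion_mask [binary_mask] objects on one grid.
#' @return A [binary_mask].
#' @export
exclude_lesions <- function(region_mask, lesion_mask) {
  stop_if_grid_mismatch(region_mask, lesion_mask, "masks")
  binary_mask(region_mask$mask & !lesion_mask$mask, affine = region_mask$affine)
}

#' Region concentration ratio C_GM / C_WM
#'
#' The ratio of the region-mean GM concentration to the region-mean WM
#' concentration, `mean(c_gm) / mean(1 - c_gm)` - one scalar per region
#' per subject. (Ratios of means, not means of voxelwise ratios: voxelwise
#' ratios blow up wherever `c_wm` approaches 0.)
#'
#' @param c A [concentration_field] or numeric vector of GM fractions.
#' @return The dimensionless ratio.
#' @export
concentration_ratio <- function(c) {
  cc <- as_cgm(c)
  if (length(cc) == 0) stop("empty concentration field", call. = FALSE)
  m <- mean(cc)
  if (m >= 1 - 1e-12)
    stop("undefined concentration ratio: mean GM concentration is 1",
         call. = FALSE)
  m / (1 - m)
}

#' Mean T1 over a mask (the global-averaging statistic)
#'
#' @param volume A [t1_volume].
#' @param mask A [binary_mask] on the same grid; must be non-empty.
#' @return Mean T1 (ms) over the masked voxels.
#' @export
global_mean_t1 <- function(volume, mask) {
  stop_if_grid_mismatch(volume, mask)
  if (!any(mask$mask)) stop("empty mask", call. = FALSE)
  mean(volume$values[mask$mask])
}

region_feature_names <- function(regions) {
  as.vector(t(outer(regions, c("mu_gm", "mu_wm", "ratio", "mean_t1", "n_voxels"),
                    paste, sep = "_")))
}

#' Extract the per-region feature vector of one subject
#'
#' For each requested region: fit the partial-volume model on
#' normal-appearing voxels ([fit_region]) and record
#' `mu_gm`, `mu_wm`, the concentration ratio, the lesion-excluded mean T1,
#' and the voxel count. A region that cannot be fitted (absent, too small,
#' degenerate) yields missing values and a logged reason instead of an
#' error; subjects are dropped pairwise per region downstream.
#'
#' @param volume A [t1_volume].
#' @param labels A [label_volume] on the same grid.
#' @param lesions Optional [binary_mask] of lesions.
#' @param config A run configuration (see [default_run_config]); its
#'   `regions` element selects the regions.
#' @return A one-row data.frame: `subject_id`, then
#'   `<region>_{mu_gm,mu_wm,ratio,mean_t1,n_voxels}` for each region.
#' @export
extract_subject_features <- function(volume, labels, lesions = NULL,
                                     config = default_run_config()) {
  regions <- config$regions
  if (length(regions) == 0) stop("no regions requested", call. = FALSE)
  present <- intersect(regions, names(labels$dictionary))
  if (length(present) == 0) stop("no requested region found in labels",
                                 call. = FALSE)
  out <- as.list(rep(NA_real_, 5L * length(regions)))
  names(out) <- region_feature_names(regions)
  for (r in regions) {
    fit <- tryCatch(
      fit_region(volume, labels, r, lesions = lesions, config = config$pve),
      error = function(e) {
        message("subject ", volume$subject_id, ", region ", r,
                ": skipped (", conditionMessage(e), ")")
        NULL
      })
    if (is.null(fit)) next
    out[[paste0(r, "_mu_gm")]] <- fit$intensities$mu_gm
    out[[paste0(r, "_mu_wm")]] <- fit$intensities$mu_wm
    out[[paste0(r, "_ratio")]] <- concentration_ratio(fit$concentrations)
    out[[paste0(r, "_mean_t1")]] <- mean(volume$values[fit$voxels])
    out[[paste0(r, "_n_voxels")]] <- fit$n_voxels
  }
  cbind(data.frame(subject_id = volume$subject_id, stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' Extract features for every subject of a cohort
#'
#' Reads each subject's volumes from the paths in the cohort table (or
#' takes them from `volumes`, a named list of
#' `list(t1 =, labels =, lesions =)` keyed by subject id, as produced by
#' [generate_cohort] when no output directory is given) and stacks the
#' per-subject feature rows. Per-subject failures are logged and recorded
#' as missing rows rather than aborting the run.
#'
#' @param cohort A cohort data.frame (see [read_cohort_table]) with columns
#'   `t1_path`, `labels_path` and optionally `lesion_path` unless `volumes`
#'   is given.
#' @param config A run configuration (see [default_run_config]).
#' @param volumes Optional in-memory volumes, keyed by subject id.
#' @return A data.frame, one row per subject.
#' @export
extract_cohort_features <- function(cohort, config = default_run_config(),
                                    volumes = NULL) {
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[i]
    rows[[i]] <- tryCatch({
      if (!is.null(volumes)) {
        v <- volumes[[sid]]
        extract_subject_features(v$t1, v$labels, v$lesions, config)
      } else {
        vol <- read_t1_volume(cohort$t1_path[i], subject_id = sid)
        lab <- read_label_volume(cohort$labels_path[i])
        les <- NULL
        if ("lesion_path" %in% names(cohort) &&
            !is.na(cohort$lesion_path[i]) && nzchar(cohort$lesion_path[i]))
          les <- read_mask(cohort$lesion_path[i])
        extract_subject_features(vol, lab, les, config)
      }
    }, error = function(e) {
      warning("subject ", sid, " failed: ", conditionMessage(e),
              call. = FALSE)
      cbind(data.frame(subject_id = sid, stringsAsFactors = FALSE),
            as.data.frame(as.list(
              stats::setNames(rep(NA_real_, 5L * length(config$regions)),
                              region_feature_names(config$regions)))))
    })
  }
  do.call(rbind, rows)
}
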