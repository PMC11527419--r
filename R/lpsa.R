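#' Local pattern similarity within a parcel
#'
#' Per subject, the Pearson correlation between the two tasks' unsmoothed
#' contrast maps over the parcel's voxels; the group test is a one-sample t
#' of the per-subject r values against zero (the null of unrelated
#' patterns). Subjects with a constant pattern in either map have undefined
#' r and are excluded (recorded in `n_excluded`).
#'
#' @param vols_a,vols_b Per-subject unsmoothed [stat_volume] lists, paired
#'   by position (task A and task B).
#' @param voxels Linear voxel indices of the parcel (length >= 3).
#' @param parcel_id Identifier carried into the result.
#' @return A `similarity_result`: `parcel_id`, `per_subject_r`, `mean_r`,
#'   `t_stat`, `df`, `p_two_tailed`, `n_excluded`.
#' @export
parcel_similarity <- function(vols_a, vols_b, voxels, parcel_id = NA) {
  stopifnot(length(vols_a) == length(vols_b), length(voxels) >= 3)
  r <- vapply(seq_along(vols_a), function(s) {
    a <- vols_a[[s]]$data[voxels]
    b <- vols_b[[s]]$data[voxels]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }, 0)
  n_excluded <- sum(is.na(r))
  r <- r[!is.na(r)]
  if (length(r) < 2) stop("fewer than 2 subjects with defined correlations")
  tt <- paired_contrast(r, rep(0, length(r)))
  structure(list(parcel_id = parcel_id, per_subject_r = r, mean_r = mean(r),
                 t_stat = tt$t, df = tt$df, p_two_tailed = tt$p_two_tailed,
                 n_excluded = n_excluded),
            class = "similarity_result")
}

#' Pattern similarity for every parcel of a set
#'
#' @param ps A `parcel_set`.
#' @param vols_a,vols_b Per-subject unsmoothed contrast maps for each task.
#' @return Data frame with one row per parcel (`parcel_id`, `mean_r`,
#'   `t_stat`, `df`, `p_two_tailed`, `n_subjects`).
#' @export
parcel_set_similarity <- function(ps, vols_a, vols_b) {
  rows <- lapply(ps$parcels$parcel_id, function(id) {
    sr <- parcel_similarity(vols_a, vols_b, parcel_voxels(ps, id), id)
    data.frame(parcel_id = id, mean_r = sr$mean_r, t_stat = sr$t_stat,
               df = sr$df, p_two_tailed = sr$p_two_tailed,
               n_subjects = length(sr$per_subject_r))
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(parcel_id = integer(), mean_r = numeric(), t_stat = numeric(),
               df = integer(), p_two_tailed = numeric(),
               n_subjects = integer())
}

# Integer lattice offsets of the Euclidean ball of `radius` voxels.
sphere_offsets <- function(radius) {
  r <- floor(radius)
  g <- as.matrix(expand.grid(di = -r:r, dj = -r:r, dk = -r:r))
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

#' Whole-brain searchlight correlation between two maps
#'
#' Centers a sphere of `radius_vox` voxels (Euclidean, center included) on
#' each in-mask voxel and assigns the center the Pearson correlation between
#' the two maps over the in-mask sphere voxels. Boundary spheres use the
#' available voxels; centers with fewer than 3 usable voxels or zero
#' variance in either map are undefined (`NA`), never zero-filled.
#'
#' @param vol_a,vol_b Unsmoothed [stat_volume]s for one subject, both tasks.
#' @param mask A [brain_mask] on the same grid.
#' @param radius_vox Sphere radius in voxel units (default 3; the full
#'   sphere holds 123 voxels).
#' @return A `searchlight_map`: `r_map` (3D, `NA` where undefined),
#'   `radius_vox`, grid and subject metadata; `z_map` is filled by
#'   [fisher_normalize].
#' @export
searchlight <- function(vol_a, vol_b, mask, radius_vox = 3) {
  check_common_grid(list(vol_a, vol_b, mask))
  offs <- sphere_offsets(radius_vox)
  r_map <- .searchlight_core(as.numeric(vol_a$data), as.numeric(vol_b$data),
                             as.logical(mask$data), as.integer(dim(mask$data)),
                             offs, 3L)
  dim(r_map) <- dim(mask$data)
  structure(list(r_map = r_map, z_map = NULL, radius_vox = radius_vox,
                 voxel_size = vol_a$voxel_size, affine = vol_a$affine,
                 subject_id = vol_a$subject_id),
            class = "searchlight_map")
}

#' Fisher-transform and normalize a searchlight map
#'
#' Applies `atanh` per defined voxel (|r| = 1 is clipped to 1 - 1e-7 in
#' magnitude first) and then, by default, standardizes the transformed map
#' to zero mean and unit variance over the defined voxels, yielding a
#' z-score correlation map.
#'
#' @param slmap A `searchlight_map` with `r_map` computed.
#' @param normalize Standardize after the transform (default `TRUE`).
#' @return The map with `z_map` filled.
#' @export
fisher_normalize <- function(slmap, normalize = TRUE) {
  stopifnot(inherits(slmap, "searchlight_map"))
  r <- slmap$r_map
  r[!is.na(r) & r >= 1] <- 1 - 1e-7
  r[!is.na(r) & r <= -1] <- -(1 - 1e-7)
  z <- atanh(r)
  if (normalize) {
    ok <- !is.na(z)
    z[ok] <- (z[ok] - mean(z[ok])) / stats::sd(z[ok])
  }
  slmap$z_map <- z
  slmap
}

#' GCSS aggregation of searchlight z-maps
#'
#' Binarizes each subject's z-scored correlation map at `z_thresh`
#' (undefined voxels count as sub-threshold) and runs the unchanged GCSS
#' pipeline, locating regions of consistently high cross-task pattern
#' similarity.
#'
#' @param slmaps List of `searchlight_map`s with `z_map` filled (>= 2).
#' @param mask A [brain_mask] on the shared grid.
#' @param z_thresh Threshold on the z-scored maps (default 2.3, p < 0.01).
#' @inheritParams gcss_parcellate
#' @return A `parcel_set`.
#' @export
lpsa_gcss <- function(slmaps, mask, z_thresh = 2.3, fwhm_mm = 6,
                      fraction = 0.6, min_separation = 3) {
  if (length(slmaps) < 2L) stop("need at least 2 subjects")
  binmaps <- lapply(slmaps, function(sl) {
    if (is.null(sl$z_map)) stop("searchlight map has no z_map; ",
                                "run fisher_normalize() first")
    vol <- stat_volume(sl$z_map, voxel_size = sl$voxel_size,
                       affine = sl$affine, subject_id = sl$subject_id,
                       contrast = "similarity_z")
    binarize(vol, mask, z_thresh)
  })
  gcss_parcellate(binmaps, fwhm_mm = fwhm_mm, fraction = fraction,
                  min_separation = min_separation)
}
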