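#' Subject-level conjunction of two binarized contrast maps
#'
#' Voxelwise logical AND of one subject's thresholded activation maps from
#' the two tasks: true only where both tasks are active.
#'
#' @param binA,binB `binary_activation_map`s for the same subject on one
#'   grid (typically syllable and tone structured > random).
#' @return A `binary_activation_map` with `contrast = "conjunction"`.
#' @export
subject_conjunction <- function(binA, binB) {
  if (!identical(binA$subject_id, binB$subject_id))
    stop("conjunction requires maps from one subject, got '",
         binA$subject_id, "' and '", binB$subject_id, "'")
  check_common_grid(list(binA, binB))
  structure(list(data = binA$data & binB$data, voxel_size = binA$voxel_size,
                 affine = binA$affine, subject_id = binA$subject_id,
                 task = NA_character_, contrast = "conjunction",
                 threshold_used = binA$threshold_used),
            class = "binary_activation_map")
}

#' GCSS aggregation of subject conjunction maps
#'
#' Runs the identical parcellation pipeline (sum, smooth, overlap-threshold,
#' local maxima, watershed) on the per-subject conjunction maps, locating
#' regions jointly active in both tasks across the criterion fraction of
#' subjects.
#'
#' @param conj_maps List of conjunction `binary_activation_map`s (>= 2).
#' @inheritParams gcss_parcellate
#' @return A `parcel_set` (empty when no location is shared by the criterion
#'   fraction of subjects).
#' @export
conjunction_gcss <- function(conj_maps, fwhm_mm = 6, fraction = 0.6,
                             min_separation = 3) {
  gcss_parcellate(conj_maps, fwhm_mm = fwhm_mm, fraction = fraction,
                  min_separation = min_separation)
}

#' Top-fraction voxels of a subject T-map within a parcel
#'
#' Selects the `ceiling(fraction * n)` voxels with the highest statistic
#' among the parcel's voxels; ties broken by smaller linear index.
#'
#' @param tmap A [stat_volume] (subject statistic map).
#' @param voxels Integer vector of the parcel's linear voxel indices.
#' @param fraction Fraction in (0, 1], default 0.10.
#' @return Linear indices of the selected voxels.
#' @export
top_fraction_voxels <- function(tmap, voxels, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (length(voxels) == 0L) stop("parcel is empty")
  k <- ceiling(fraction * length(voxels))
  vals <- tmap$data[voxels]
  voxels[order(-vals, voxels)][seq_len(k)]
}

# Per-subject correlation of two block maps over a fixed voxel set, then a
# group one-sample t of the r values against zero.
consistency_row <- function(maps_x, maps_y, voxel_sets) {
  r <- vapply(seq_along(maps_x), function(s) {
    v <- voxel_sets[[s]]
    a <- maps_x[[s]]$data[v]
    b <- maps_y[[s]]$data[v]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
  }, 0)
  r <- r[!is.na(r)]
  if (length(r) < 2)
    return(list(r = NA_real_, p = NA_real_, n = length(r),
                note = "fewer than 2 subjects with non-degenerate patterns"))
  tt <- paired_contrast(r, rep(0, length(r)))
  list(r = mean(r), p = tt$p_two_tailed, n = length(r), per_subject = r)
}

#' Block-wise within- and between-task pattern consistency
#'
#' For each parcel and subject, a voxel set is fixed once as the top
#' `fraction` of the subject's overall source-task T-map within the parcel,
#' and reused for every block comparison. Within-task rows correlate the
#' activation pattern of structured block pairs (1,2), (1,3), (2,3) of each
#' task; between-task rows correlate matching block indices across tasks.
#' Per-subject correlations are aggregated by a one-sample t against zero.
#'
#' @param ps A `parcel_set`.
#' @param overall_tmaps Per-subject overall T-maps of the parcel's source
#'   task (list of [stat_volume]), used only for voxel selection.
#' @param blocks_a,blocks_b Per-subject lists of the 3 structured-block
#'   T-maps for task A and task B (`blocks_x[[subject]][[block]]`).
#' @param fraction Voxel-selection fraction (default 0.10).
#' @return A `data.frame` (`parcel_id`, `comparison`, `r`, `p`,
#'   `n_subjects`); attribute `per_subject` holds the per-subject r values.
#' @export
block_consistency <- function(ps, overall_tmaps, blocks_a, blocks_b,
                              fraction = 0.10) {
  n <- length(overall_tmaps)
  stopifnot(length(blocks_a) == n, length(blocks_b) == n)
  rows <- list()
  per_subj <- list()
  for (id in ps$parcels$parcel_id) {
    vox <- parcel_voxels(ps, id)
    sets <- lapply(overall_tmaps, top_fraction_voxels, voxels = vox,
                   fraction = fraction)
    cmp <- list()
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      cmp[[paste0("within_A_b", pair[1], pair[2])]] <-
        consistency_row(lapply(blocks_a, `[[`, pair[1]),
                        lapply(blocks_a, `[[`, pair[2]), sets)
      cmp[[paste0("within_B_b", pair[1], pair[2])]] <-
        consistency_row(lapply(blocks_b, `[[`, pair[1]),
                        lapply(blocks_b, `[[`, pair[2]), sets)
    }
    for (b in 1:3)
      cmp[[paste0("between_b", b)]] <-
        consistency_row(lapply(blocks_a, `[[`, b),
                        lapply(blocks_b, `[[`, b), sets)
    for (nm in names(cmp)) {
      rows[[length(rows) + 1L]] <-
        data.frame(parcel_id = id, comparison = nm, r = cmp[[nm]]$r,
                   p = cmp[[nm]]$p, n_subjects = cmp[[nm]]$n)
      per_subj[[paste(id, nm, sep = ":")]] <- cmp[[nm]]$per_subject
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parcel_id = integer(), comparison = character(),
               r = numeric(), p = numeric(), n_subjects = integer())
  attr(out, "per_subject") <- per_subj
  out
}
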