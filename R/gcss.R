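#' Group-constrained subject-specific (GCSS) parcellation
#'
#' Subject contrast maps are thresholded and binarized, summed into a
#' probability-of-activation map, smoothed, restricted to voxels where at
#' least a criterion fraction of subjects is active, and segmented into
#' parcels by growing watershed basins around the retained local maxima.
#'
#' @name gcss
NULL

# All 26 neighbor offsets on the 3D lattice.
neighbor_offsets_26 <- function() {
  o <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  o[rowSums(o == 0) < 3, , drop = FALSE]
}

# shifted[v] = x[v + off] with out-of-range positions set to `fill`.
shift_array <- function(x, off, fill) {
  d <- dim(x)
  out <- array(fill, d)
  dst <- lapply(1:3, function(a) seq.int(max(1L, 1L - off[a]),
                                         min(d[a], d[a] - off[a])))
  if (any(vapply(dst, length, 0L) == 0L)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    x[dst[[1]] + off[1], dst[[2]] + off[2], dst[[3]] + off[3]]
  out
}

#' Threshold and binarize a subject contrast map
#'
#' @param vol A [stat_volume] of statistic values.
#' @param mask A [brain_mask] on the same grid.
#' @param z_thresh Statistic cutoff; the default 2.326 is the one-tailed
#'   p < 0.01 point of the standard normal.
#' @return A `binary_activation_map`: logical array, true where
#'   `data > z_thresh` inside the mask, plus grid and identity metadata.
#' @export
binarize <- function(vol, mask, z_thresh = 2.326) {
  check_common_grid(list(vol, mask))
  b <- !is.na(vol$data) & vol$data > z_thresh & mask$data
  structure(list(data = b, voxel_size = vol$voxel_size, affine = vol$affine,
                 subject_id = vol$subject_id, task = vol$task,
                 contrast = vol$contrast, threshold_used = z_thresh),
            class = "binary_activation_map")
}

#' Sum binary maps into a probability map
#'
#' @param binmaps List (length >= 2) of `binary_activation_map` on one grid.
#' @return A `probability_map`: integer `counts` (voxelwise number of active
#'   subjects), `n_subjects`, grid metadata; `smoothed` is filled by
#'   [smooth_probability_map].
#' @export
probability_map <- function(binmaps) {
  if (length(binmaps) < 2L) stop("need at least 2 binary maps")
  check_common_grid(binmaps)
  counts <- Reduce(`+`, lapply(binmaps, function(b) array(as.integer(b$data),
                                                          dim(b$data))))
  structure(list(counts = counts, n_subjects = length(binmaps),
                 voxel_size = binmaps[[1]]$voxel_size,
                 affine = binmaps[[1]]$affine,
                 smoothed = NULL, fwhm_mm = NULL),
            class = "probability_map")
}

#' Smooth a probability map
#'
#' Gaussian smoothing of the subject counts (FWHM in mm); smoothing
#' approximately preserves the counts scale, so the overlap criterion can
#' still be expressed as a fraction of `n_subjects`.
#'
#' @param pm A `probability_map`.
#' @param fwhm_mm Kernel FWHM in mm (default 6).
#' @return The map with `smoothed` and `fwhm_mm` filled.
#' @export
smooth_probability_map <- function(pm, fwhm_mm = 6) {
  stopifnot(inherits(pm, "probability_map"))
  pm$smoothed <- gaussian_smooth_3d(pm$counts, fwhm_mm, pm$voxel_size)
  pm$fwhm_mm <- fwhm_mm
  pm
}

#' Apply the subject-overlap criterion
#'
#' Zeroes voxels of the smoothed map below `fraction * n_subjects`, keeping
#' only locations where at least that fraction of subjects shows significant
#' activation.
#'
#' @param pm A smoothed `probability_map`.
#' @param fraction Criterion fraction in (0, 1], default 0.6.
#' @return 3D numeric field (smoothed values, sub-criterion voxels zeroed).
#' @export
overlap_threshold <- function(pm, fraction = 0.6) {
  stopifnot(inherits(pm, "probability_map"))
  if (is.null(pm$smoothed)) stop("probability map has not been smoothed")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  field <- pm$smoothed
  field[field < fraction * pm$n_subjects] <- 0
  field
}

#' Local maxima with a minimum-separation constraint
#'
#' Finds voxels strictly greater than all 26 neighbours (and positive), then
#' enforces the separation rule: among peaks closer than `min_separation`
#' (Euclidean), only the highest survives, ties broken by smaller linear
#' index. Suppressed maxima are retained as an attribute mapping each to the
#' retained peak that suppressed it, so watershed basins can be merged.
#'
#' @param field Non-negative 3D field (e.g. from [overlap_threshold]).
#' @param min_separation Minimum peak separation, default 3.
#' @param units `"vox"` (Euclidean distance in voxel units, default) or
#'   `"mm"` (requires `voxel_size`).
#' @param voxel_size Voxel size in mm, used only when `units = "mm"`.
#' @return Object of class `local_maxima`: data.frame `index` (linear),
#'   `i`, `j`, `k`, `value`, ordered by decreasing value; attribute
#'   `suppressed` maps suppressed maxima to retained peaks.
#' @export
local_maxima <- function(field, min_separation = 3, units = c("vox", "mm"),
                         voxel_size = NULL) {
  units <- match.arg(units)
  d <- dim(field)
  nb_max <- array(-Inf, d)
  for (r in seq_len(nrow(offs <- neighbor_offsets_26())))
    nb_max <- pmax(nb_max, shift_array(field, offs[r, ], -Inf))
  is_peak <- field > 0 & field > nb_max
  idx <- which(is_peak)
  ijk <- arrayInd(idx, d)
  scale <- if (units == "mm") {
    if (is.null(voxel_size)) stop("voxel_size required for units = 'mm'")
    voxel_size
  } else c(1, 1, 1)
  ord <- order(-field[idx], idx)
  idx <- idx[ord]; ijk <- ijk[ord, , drop = FALSE]
  kept <- logical(length(idx))
  sup_by <- rep(NA_integer_, length(idx))
  for (p in seq_along(idx)) {
    if (!any(kept)) { kept[p] <- TRUE; next }
    kpos <- which(kept)
    dd <- sqrt(colSums((t(ijk[kpos, , drop = FALSE]) - ijk[p, ])^2 * scale^2))
    if (all(dd >= min_separation)) kept[p] <- TRUE
    else sup_by[p] <- idx[kpos[which.min(dd)]]
  }
  peaks <- data.frame(index = idx[kept], i = ijk[kept, 1], j = ijk[kept, 2],
                      k = ijk[kept, 3], value = field[idx[kept]])
  structure(peaks, class = c("local_maxima", "data.frame"),
            suppressed = data.frame(index = idx[!kept],
                                    suppressed_by = sup_by[!kept]))
}

# Steepest-ascent pointer for every voxel: the max-valued voxel among itself
# and its 26 neighbours, ties to the smallest linear index.
ascent_pointers <- function(field) {
  d <- dim(field)
  lin <- array(seq_along(field), d)
  best_val <- field
  best_idx <- lin
  offs <- neighbor_offsets_26()
  for (r in seq_len(nrow(offs))) {
    sv <- shift_array(field, offs[r, ], -Inf)
    si <- shift_array(lin, offs[r, ], .Machine$integer.max)
    upd <- sv > best_val | (sv == best_val & si < best_idx)
    best_val[upd] <- sv[upd]
    best_idx[upd] <- si[upd]
  }
  best_idx
}

#' Grow watershed parcels around retained peaks
#'
#' Hill-climbing watershed: every positive voxel follows steepest 26-neighbour
#' ascent (ties to the smaller linear index) to its governing maximum, and
#' the basin of each retained peak becomes one parcel. Basins of maxima that
#' were suppressed by the minimum-separation rule are merged into the
#' retained peak that suppressed them. Zero-valued voxels are never assigned,
#' so growth stops at zeros and at local minima (basin boundaries).
#'
#' @param field Non-negative 3D field, the same one passed to [local_maxima].
#' @param peaks A `local_maxima` object for `field`.
#' @param voxel_size,affine Optional grid metadata stored in the result.
#' @return A `parcel_set`: integer `labels` array (0 = unassigned), and
#'   `parcels` data.frame (`parcel_id`, `peak_index`, `peak_i/j/k`,
#'   `peak_value`, `n_voxels`), parcels ordered by decreasing peak value.
#' @export
watershed_parcels <- function(field, peaks, voxel_size = NULL, affine = NULL) {
  stopifnot(inherits(peaks, "local_maxima"))
  d <- dim(field)
  labels <- array(0L, d)
  parcels <- data.frame(parcel_id = integer(), peak_index = integer(),
                        peak_i = integer(), peak_j = integer(),
                        peak_k = integer(), peak_value = numeric(),
                        n_voxels = integer())
  ps <- structure(list(labels = labels, parcels = parcels,
                       voxel_size = voxel_size, affine = affine,
                       provenance = list()),
                  class = "parcel_set")
  if (nrow(peaks) == 0L) return(ps)
  ptr <- ascent_pointers(field)
  pos <- which(field > 0)
  pos <- pos[order(-field[pos], pos)]
  term <- integer(length(field))
  for (v in pos) {
    p <- ptr[v]
    term[v] <- if (p == v) v else term[p]
  }
  seed_label <- integer(length(field))
  seed_label[peaks$index] <- seq_len(nrow(peaks))
  sup <- attr(peaks, "suppressed")
  if (!is.null(sup) && nrow(sup))
    seed_label[sup$index] <- seed_label[sup$suppressed_by]
  lab <- ifelse(term[pos] > 0L, seed_label[term[pos]], 0L)
  labels[pos] <- lab
  n_vox <- tabulate(labels, nbins = nrow(peaks))
  ps$labels <- labels
  ps$parcels <- data.frame(parcel_id = seq_len(nrow(peaks)),
                           peak_index = peaks$index, peak_i = peaks$i,
                           peak_j = peaks$j, peak_k = peaks$k,
                           peak_value = peaks$value, n_voxels = n_vox)
  ps
}

#' Linear voxel indices of one parcel
#'
#' @param ps A `parcel_set`.
#' @param parcel_id Parcel identifier.
#' @return Integer vector of linear indices into the label array.
#' @export
parcel_voxels <- function(ps, parcel_id) which(ps$labels == parcel_id)

#' Full GCSS parcellation pipeline
#'
#' Sum -> smooth -> overlap-threshold -> local maxima -> watershed, with
#' provenance recorded. Subject overlap counts are recomputed afterwards
#' from the unsmoothed binary maps via [parcel_overlap_stats].
#'
#' @param binmaps List of `binary_activation_map` objects on one grid.
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 6).
#' @param fraction Subject-overlap criterion (default 0.6).
#' @param min_separation Minimum peak separation in voxels (default 3).
#' @return A `parcel_set` with overlap statistics and provenance.
#' @export
gcss_parcellate <- function(binmaps, fwhm_mm = 6, fraction = 0.6,
                            min_separation = 3) {
  pm <- smooth_probability_map(probability_map(binmaps), fwhm_mm)
  field <- overlap_threshold(pm, fraction)
  peaks <- local_maxima(field, min_separation)
  ps <- watershed_parcels(field, peaks, voxel_size = pm$voxel_size,
                          affine = pm$affine)
  ps <- parcel_overlap_stats(ps, binmaps)
  ps$provenance <- list(threshold_used = binmaps[[1]]$threshold_used,
                        fwhm_mm = fwhm_mm, fraction = fraction,
                        min_separation = min_separation,
                        n_subjects = pm$n_subjects)
  ps
}

#' Subject overlap per parcel
#'
#' A subject overlaps a parcel if it has at least one suprathreshold voxel
#' inside it; the fraction is that count over the number of subjects.
#'
#' @param ps A `parcel_set`.
#' @param binmaps The subject binary maps.
#' @return `ps` with `n_overlap_subjects` and `overlap_fraction` columns.
#' @export
parcel_overlap_stats <- function(ps, binmaps) {
  n <- length(binmaps)
  ps$parcels$n_overlap_subjects <- vapply(ps$parcels$parcel_id, function(id) {
    vox <- parcel_voxels(ps, id)
    sum(vapply(binmaps, function(b) any(b$data[vox]), FALSE))
  }, 0L)
  ps$parcels$overlap_fraction <- ps$parcels$n_overlap_subjects / n
  ps
}

#' Parcel-level effect size and power
#'
#' For each parcel, each subject's mean unthresholded contrast over the
#' parcel voxels gives one observation; Cohen's d is mean/SD of those
#' (one-sample vs 0) and power is that of a two-tailed one-sample t test at
#' `alpha`, via the noncentral-t distribution.
#'
#' @param ps A `parcel_set`.
#' @param contrast_vols List of unthresholded [stat_volume]s, one per subject.
#' @param alpha Test level for the power computation (default 0.05).
#' @return `ps` with `cohen_d` and `power` columns.
#' @export
parcel_effect_size <- function(ps, contrast_vols, alpha = 0.05) {
  n <- length(contrast_vols)
  if (n < 2) stop("need at least 2 subjects")
  es <- t(vapply(ps$parcels$parcel_id, function(id) {
    vox <- parcel_voxels(ps, id)
    x <- vapply(contrast_vols, function(v) mean(v$data[vox], na.rm = TRUE), 0)
    d <- if (stats::sd(x) == 0) {
      if (mean(x) == 0) 0 else NA_real_ # constant nonzero signal: d undefined
    } else mean(x) / stats::sd(x)
    pw <- if (is.na(d)) NA_real_
    else if (abs(d) > 0)
      stats::power.t.test(n = n, delta = abs(d), sd = 1, sig.level = alpha,
                          type = "one.sample")$power
    else alpha
    c(d = d, power = pw)
  }, c(d = 0, power = 0)))
  ps$parcels$cohen_d <- es[, "d"]
  ps$parcels$power <- es[, "power"]
  ps
}

#' Write parcel labels and table
#'
#' @param ps A `parcel_set` with grid metadata.
#' @param label_path NIfTI path for the integer label volume.
#' @param table_path TSV path for the parcel table.
#' @export
write_parcel_set <- function(ps, label_path = NULL, table_path = NULL) {
  if (!is.null(label_path)) {
    vol <- stat_volume(array(as.numeric(ps$labels), dim(ps$labels)),
                       voxel_size = ps$voxel_size, affine = ps$affine)
    write_stat_volume(vol, label_path)
  }
  if (!is.null(table_path))
    utils::write.table(ps$parcels, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(ps)
}
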