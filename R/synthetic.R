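#' Synthetic cohort generation with known ground truth
#'
#' The generator emulates the inputs the group analyses consume: one
#' unsmoothed z-contrast volume per subject and task on a common 2.5 mm
#' grid, built as spatially smooth unit-variance noise plus planted active
#' regions, and button-press logs from parameterized responders. The
#' planted geometry and effect sizes are retained as ground truth so
#' recovery can be scored.
#'
#' @name synthetic_data
NULL

#' Define a planted region
#'
#' @param center_mm Length-3 world coordinates (mm) of the region center.
#' @param radius_mm Region radius in mm (flat-amplitude ball, default 10).
#' @param role One of `"shared"` (activation bump in both tasks),
#'   `"taskA_only"`, `"taskB_only"` (bump in one task), or
#'   `"anticorrelated_pattern"` (zero-mean voxel patterns in both tasks with
#'   a negative cross-task correlation).
#' @param peak_effect_z Bump amplitude, or pattern SD for the
#'   anticorrelated role, in z units (default 4).
#' @param participation Fraction of subjects in which the region is present
#'   (default 1); the realized count is exactly `round(participation * n)`.
#' @return A one-row data.frame describing the region.
#' @export
synth_region <- function(center_mm, radius_mm = 10,
                         role = c("shared", "taskA_only", "taskB_only",
                                  "anticorrelated_pattern"),
                         peak_effect_z = 4, participation = 1) {
  role <- match.arg(role)
  stopifnot(length(center_mm) == 3, radius_mm > 0,
            participation >= 0, participation <= 1)
  data.frame(cx = center_mm[1], cy = center_mm[2], cz = center_mm[3],
             radius_mm = radius_mm, role = role,
             peak_effect_z = peak_effect_z, participation = participation)
}

#' Assemble the ground-truth description of a synthetic cohort
#'
#' @param regions Data frame of regions ([synth_region] rows, rbind-ed);
#'   may be empty for pure-noise cohorts.
#' @param jitter_sd_vox SD (voxels) of the per-subject integer-rounded
#'   spatial jitter applied to region centers (default 0.5, so shifts are
#'   essentially within one voxel).
#' @param noise_fwhm_mm Spatial smoothness (FWHM, mm) of the noise fields
#'   (default 6).
#' @param anticorr_r Target cross-task pattern correlation for
#'   anticorrelated regions (default -0.5).
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(regions = NULL, jitter_sd_vox = 0.5,
                            noise_fwhm_mm = 6, anticorr_r = -0.5) {
  if (is.null(regions))
    regions <- synth_region(c(0, 0, 0))[0, ]
  stopifnot(jitter_sd_vox >= 0, noise_fwhm_mm > 0,
            anticorr_r > -1, anticorr_r < 1)
  structure(list(regions = regions, jitter_sd_vox = jitter_sd_vox,
                 noise_fwhm_mm = noise_fwhm_mm, anticorr_r = anticorr_r),
            class = "synthetic_truth")
}

#' Build a brain mask for synthetic volumes
#'
#' @param shape Length-3 grid shape (>= 16 per axis recommended).
#' @param kind `"ellipsoid"` (inscribed in the box, ~pi/6 of its volume) or
#'   `"box"` (full interior).
#' @param voxel_size Voxel size in mm.
#' @return A [brain_mask].
#' @export
make_mask <- function(shape, kind = c("ellipsoid", "box"),
                      voxel_size = c(2.5, 2.5, 2.5)) {
  kind <- match.arg(kind)
  if (kind == "box") {
    m <- array(TRUE, shape)
  } else {
    ctr <- (shape + 1) / 2
    semi <- shape / 2
    i <- (seq_len(shape[1]) - ctr[1]) / semi[1]
    j <- (seq_len(shape[2]) - ctr[2]) / semi[2]
    k <- (seq_len(shape[3]) - ctr[3]) / semi[3]
    m <- outer(outer(i^2, j^2, `+`), k^2, `+`) <= 1
  }
  brain_mask(m, voxel_size = voxel_size)
}

# World mm -> (fractional) voxel index, using the inverse affine.
mm_to_voxel <- function(xyz_mm, affine) {
  v <- solve(affine, c(xyz_mm, 1))[1:3]
  v + 1 # 0-based voxel coordinates -> R's 1-based array index
}

# Linear indices of the ball of radius_mm around a (1-based) voxel center.
ball_indices <- function(center_vox, radius_mm, shape, voxel_size) {
  r_vox <- ceiling(radius_mm / voxel_size)
  rng <- lapply(1:3, function(a)
    seq.int(max(1L, floor(center_vox[a] - r_vox[a])),
            min(shape[a], ceiling(center_vox[a] + r_vox[a]))))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  d2 <- colSums((t(g) - center_vox)^2 * voxel_size^2)
  idx <- g[d2 <= radius_mm^2, , drop = FALSE]
  if (nrow(idx) == 0L) return(integer(0))
  idx[, 1] + shape[1] * (idx[, 2] - 1L) + shape[1] * shape[2] * (idx[, 3] - 1L)
}

#' Simulate per-subject contrast volumes for both tasks
#'
#' Each subject-task volume is smooth Gaussian noise (stated smoothness,
#' unit variance in the mask interior) plus, for every region in which the
#' subject participates, a flat additive bump of the stated peak z effect
#' over the region ball, centered at the region center plus the subject's
#' integer-voxel jitter. Anticorrelated-pattern regions instead add
#' zero-mean voxel patterns to both tasks whose cross-task correlation is
#' `anticorr_r` in expectation. Deterministic for a fixed seed.
#'
#' @param truth A [synthetic_truth].
#' @param n_subjects Number of subjects (default 27).
#' @param shape Grid shape (default `c(32, 38, 32)`).
#' @param voxel_size Voxel size in mm (default 2.5 isotropic).
#' @param seed Integer seed.
#' @param mask Optional [brain_mask]; default ellipsoid via [make_mask].
#' @return A `synthetic_cohort`: `vols` (`$syllable`, `$tone`: lists of
#'   [stat_volume]), `mask`, `truth`, `participation` (region x subject
#'   logical matrix), `jitters`, `seed`. Task A is `syllable`, task B
#'   `tone`.
#' @export
simulate_contrast_maps <- function(truth, n_subjects = 27,
                                   shape = c(32, 38, 32),
                                   voxel_size = c(2.5, 2.5, 2.5), seed = 1,
                                   mask = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), n_subjects >= 2)
  if (is.null(mask)) mask <- make_mask(shape, "ellipsoid", voxel_size)
  shape <- dim(mask$data)
  affine <- mask$affine
  regs <- truth$regions
  nR <- nrow(regs)
  centers_vox <- if (nR) t(apply(regs[, c("cx", "cy", "cz")], 1, mm_to_voxel,
                                 affine = affine)) else matrix(0, 0, 3)
  for (r in seq_len(nR)) {
    cv <- round(centers_vox[r, ])
    if (any(cv < 1) || any(cv > shape) ||
        !mask$data[cv[1], cv[2], cv[3]])
      stop("region ", r, " center lies outside the mask")
  }
  norm_sd <- smoothed_noise_sd(truth$noise_fwhm_mm, voxel_size)
  with_seed(seed, {
    participation <- matrix(FALSE, nR, n_subjects)
    for (r in seq_len(nR)) {
      k <- round(regs$participation[r] * n_subjects)
      if (k > 0) participation[r, sample.int(n_subjects, k)] <- TRUE
    }
    jitters <- array(0L, c(nR, n_subjects, 3))
    if (nR)
      jitters[] <- as.integer(round(stats::rnorm(nR * n_subjects * 3,
                                                 0, truth$jitter_sd_vox)))
    make_noise <- function() {
      x <- gaussian_smooth_3d(array(stats::rnorm(prod(shape)), shape),
                              truth$noise_fwhm_mm, voxel_size) / norm_sd
      x
    }
    vols <- list(syllable = vector("list", n_subjects),
                 tone = vector("list", n_subjects))
    for (s in seq_len(n_subjects)) {
      a <- make_noise()
      b <- make_noise()
      for (r in seq_len(nR)) {
        if (!participation[r, s]) next
        ctr <- centers_vox[r, ] + jitters[r, s, ]
        vox <- ball_indices(ctr, regs$radius_mm[r], shape, voxel_size)
        if (length(vox) == 0L) next
        role <- regs$role[r]
        amp <- regs$peak_effect_z[r]
        if (role == "anticorrelated_pattern") {
          u <- stats::rnorm(length(vox))
          w <- stats::rnorm(length(vox))
          rho <- truth$anticorr_r
          a[vox] <- a[vox] + amp * u
          b[vox] <- b[vox] + amp * (rho * u + sqrt(1 - rho^2) * w)
        } else {
          if (role %in% c("shared", "taskA_only")) a[vox] <- a[vox] + amp
          if (role %in% c("shared", "taskB_only")) b[vox] <- b[vox] + amp
        }
      }
      sid <- sprintf("sub-%02d", s)
      vols$syllable[[s]] <- stat_volume(a, voxel_size, affine, sid,
                                        "syllable", "structured_gt_random")
      vols$tone[[s]] <- stat_volume(b, voxel_size, affine, sid,
                                    "tone", "structured_gt_random")
    }
    structure(list(vols = vols, mask = mask, truth = truth,
                   participation = participation, jitters = jitters,
                   centers_vox = centers_vox, seed = seed,
                   n_subjects = n_subjects),
              class = "synthetic_cohort")
  })
}

#' Simulate a responder's button presses for one run
#'
#' In every block the responder presses after each target onset with
#' probability `p_hit`, at the onset plus a Normal RT truncated to the valid
#' window, and after each non-target onset with probability `p_fa` at a
#' uniform lag in the window. In structured blocks `learning_slope` (ms per
#' block) shifts the RT mean linearly with the within-condition block
#' number, emulating RT facilitation as triplets are learned.
#'
#' @param run A `run_design` from [assemble_run].
#' @param responder List with `p_hit`, `p_fa`, `rt_mean_ms`, `rt_sd_ms`,
#'   `learning_slope` (ms/block, default 0).
#' @param targets Named list with the tracked `syllable` and `tone` tokens
#'   (see [assign_targets]).
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @param window_ms Valid-response window used to truncate RTs.
#' @return List of [response_log], one per block in presentation order.
#' @export
simulate_responses <- function(run, responder, targets, seed = 1,
                               subject_id = "sub-01", window_ms = c(0, 960)) {
  stopifnot(inherits(run, "run_design"),
            responder$p_hit >= 0, responder$p_hit <= 1,
            responder$p_fa >= 0, responder$p_fa <= 1)
  slope <- if (is.null(responder$learning_slope)) 0 else
    responder$learning_slope
  with_seed(seed, lapply(seq_along(run$blocks), function(i) {
    b <- run$blocks[[i]]
    target <- targets[[b$domain]]
    is_t <- b$tokens == target
    mu <- responder$rt_mean_ms +
      if (b$condition == "structured") slope * (run$block_index[i] - 1) else 0
    presses <- numeric(0)
    for (on in b$onsets_ms[is_t]) {
      if (stats::runif(1) < responder$p_hit) {
        rt <- stats::rnorm(1, mu, responder$rt_sd_ms)
        rt <- min(max(rt, window_ms[1]), window_ms[2])
        presses <- c(presses, on + rt)
      }
    }
    for (on in b$onsets_ms[!is_t]) {
      if (stats::runif(1) < responder$p_fa)
        presses <- c(presses, on + stats::runif(1, window_ms[1],
                                                window_ms[2]))
    }
    response_log(subject_id, b, presses, target,
                 block_index = run$block_index[i])
  }))
}

dice_coef <- function(a_idx, b_idx) {
  if (length(a_idx) == 0L && length(b_idx) == 0L) return(NA_real_)
  2 * length(intersect(a_idx, b_idx)) / (length(a_idx) + length(b_idx))
}

#' Score parcel recovery against the planted ground truth
#'
#' For each planted region: whether any parcel peak lies inside the region
#' ball (a hit), and the Dice overlap of the best-matching parcel with the
#' region support (clipped to the mask).
#'
#' @param cohort A `synthetic_cohort`.
#' @param ps A `parcel_set` from any of the aggregation analyses.
#' @return Data frame: `region`, `role`, `hit`, `best_dice`,
#'   `best_parcel`.
#' @export
ground_truth_report <- function(cohort, ps) {
  regs <- cohort$truth$regions
  shape <- dim(cohort$mask$data)
  vs <- cohort$mask$voxel_size
  rows <- lapply(seq_len(nrow(regs)), function(r) {
    ctr <- cohort$centers_vox[r, ]
    support <- intersect(ball_indices(ctr, regs$radius_mm[r], shape, vs),
                         which(cohort$mask$data))
    hit <- FALSE
    best_dice <- 0
    best_parcel <- NA_integer_
    for (id in ps$parcels$parcel_id) {
      pk <- ps$parcels[ps$parcels$parcel_id == id, ]
      pk_idx <- pk$peak_index
      if (pk_idx %in% support) hit <- TRUE
      dc <- dice_coef(parcel_voxels(ps, id), support)
      if (!is.na(dc) && dc > best_dice) { best_dice <- dc; best_parcel <- id }
    }
    data.frame(region = r, role = regs$role[r], hit = hit,
               best_dice = best_dice, best_parcel = best_parcel)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(region = integer(), role = character(), hit = logical(),
               best_dice = numeric(), best_parcel = integer())
}
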