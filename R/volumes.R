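#' Statistic volumes on a voxel grid
#'
#' A `stat_volume` is a 3D scalar field (z or T statistic units) on a voxel
#' grid with physical voxel size and a 4x4 voxel-to-world affine, carrying
#' subject/task/contrast identity. Voxel indices are interpreted 0-based in
#' world-coordinate computations; world coordinates are obtained only through
#' the affine. Volumes entering a group analysis must already share one grid:
#' no resampling or reorientation is ever performed.
#'
#' @param data 3D numeric array. Must not contain infinities; `NA` is the
#'   missing-voxel sentinel and may only occur outside the brain mask.
#' @param voxel_size Length-3 numeric, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world matrix; if `NULL`, a diagonal RAS affine
#'   centred on the volume is built from `voxel_size`.
#' @param subject_id,task,contrast Identity metadata. `task` is one of
#'   `"syllable"`, `"tone"`; `contrast` one of `"structured_gt_random"`,
#'   `"random_gt_structured"`, `"conjunction"`, `"similarity_z"`.
#' @return An object of class `stat_volume`.
#' @export
stat_volume <- function(data, voxel_size = c(2.5, 2.5, 2.5), affine = NULL,
                        subject_id = NA_character_, task = NA_character_,
                        contrast = NA_character_) {
  if (length(dim(data)) != 3L)
    stop("stat_volume data must be a 3D array, got ", length(dim(data)), "D")
  if (any(dim(data) < 1L)) stop("all voxel dimensions must be positive")
  if (any(is.infinite(data))) stop("stat_volume data contains infinities")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths (mm)")
  if (is.null(affine)) affine <- default_affine(dim(data), voxel_size)
  affine <- unclass(affine)[1:4, 1:4]
  col_norms <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(abs(col_norms - voxel_size) > 1e-3))
    stop("affine column norms (", paste(signif(col_norms, 6), collapse = ", "),
         ") inconsistent with voxel_size beyond 1e-3 mm")
  if (!is.na(task) && !task %in% c("syllable", "tone"))
    stop("task must be 'syllable' or 'tone'")
  ok_con <- c("structured_gt_random", "random_gt_structured", "conjunction",
              "similarity_z")
  if (!is.na(contrast) && !contrast %in% ok_con)
    stop("contrast must be one of: ", paste(ok_con, collapse = ", "))
  structure(list(data = data, voxel_size = voxel_size, affine = affine,
                 subject_id = subject_id, task = task, contrast = contrast),
            class = "stat_volume")
}

default_affine <- function(shape, voxel_size) {
  m <- diag(4)
  diag(m)[1:3] <- voxel_size
  m[1:3, 4] <- -voxel_size * (shape - 1) / 2
  m
}

#' @export
print.stat_volume <- function(x, ...) {
  cat("stat_volume:", paste(dim(x$data), collapse = " x "),
      "voxels @", paste(x$voxel_size, collapse = " x "), "mm\n")
  cat("  subject:", x$subject_id, " task:", x$task, " contrast:", x$contrast,
      "\n")
  invisible(x)
}

#' Brain mask on the shared voxel grid
#'
#' @param data 3D logical (or coercible) array; must be non-empty.
#' @inheritParams stat_volume
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(data, voxel_size = c(2.5, 2.5, 2.5), affine = NULL) {
  if (length(dim(data)) != 3L) stop("brain_mask data must be a 3D array")
  m <- array(as.logical(data), dim(data))
  if (anyNA(m)) stop("brain_mask may not contain NA")
  if (!any(m)) stop("brain_mask is empty")
  if (is.null(affine)) affine <- default_affine(dim(m), voxel_size)
  structure(list(data = m, voxel_size = as.numeric(voxel_size),
                 affine = unclass(affine)[1:4, 1:4]),
            class = "brain_mask")
}

#' Read a statistic volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii` / `.nii.gz` file holding a 3D image.
#' @inheritParams stat_volume
#' @return A [stat_volume].
#' @export
read_stat_volume <- function(path, subject_id = NA_character_,
                             task = NA_character_, contrast = NA_character_) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    stop("expected a 3D image in '", path, "', got ", length(dim(a)), "D")
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  vs <- RNifti::pixdim(img)[1:3]
  stat_volume(a, voxel_size = vs, affine = aff, subject_id = subject_id,
              task = task, contrast = contrast)
}

#' Write a statistic volume to a NIfTI-1 file
#'
#' Round-trips through [read_stat_volume] preserve data and affine to 1e-6.
#'
#' @param vol A [stat_volume].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stat_volume <- function(vol, path) {
  stopifnot(inherits(vol, "stat_volume") || inherits(vol, "brain_mask"))
  dat <- vol$data
  if (is.logical(dat)) dat <- array(as.integer(dat), dim(dat))
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stop("cannot write NIfTI file '", path, "': ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a brain mask from a NIfTI-1 file
#'
#' @param path Path to a 3D NIfTI file; nonzero voxels are in-mask.
#' @return A [brain_mask].
#' @export
read_brain_mask <- function(path) {
  v <- read_stat_volume(path)
  brain_mask(v$data != 0, voxel_size = v$voxel_size, affine = v$affine)
}

grid_of <- function(v) {
  list(shape = dim(v$data), voxel_size = v$voxel_size, affine = v$affine)
}

grids_equal <- function(a, b, tol = 1e-3) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) <= tol) &&
    all(abs(a$affine - b$affine) <= tol)
}

#' Assert that volumes share one voxel grid
#'
#' Downstream group analyses require all inputs on a single grid; grid
#' mismatches are an error (resampling is out of scope), with the offending
#' subject named.
#'
#' @param vols Non-empty list of [stat_volume] / [brain_mask] objects.
#' @param tol Tolerance (mm / affine entries) for metadata agreement.
#' @return The shared grid descriptor: `list(shape, voxel_size, affine)`.
#' @export
check_common_grid <- function(vols, tol = 1e-3) {
  if (length(vols) == 0L) stop("check_common_grid: empty volume list")
  ref <- grid_of(vols[[1]])
  for (i in seq_along(vols)) {
    g <- grid_of(vols[[i]])
    if (!grids_equal(ref, g, tol)) {
      who <- vols[[i]]$subject_id
      stop("grid mismatch at volume ", i,
           if (!is.null(who) && !is.na(who)) paste0(" (subject ", who, ")"),
           ": shape ", paste(g$shape, collapse = "x"),
           " vs ", paste(ref$shape, collapse = "x"))
    }
  }
  ref
}

#' Read / write a cohort table
#'
#' The cohort table holds one row per subject: `subject_id`, `age_years`,
#' `sex`, `mean_fd_mm` (mean framewise displacement across runs, mm) and
#' `included`. TSV with a header row.
#'
#' @param path TSV file path.
#' @return `read_cohort_table`: a `data.frame`.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject_id", "mean_fd_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in cohort table")
  if (any(df$mean_fd_mm < 0)) stop("mean_fd_mm must be non-negative")
  df
}

#' @rdname read_cohort_table
#' @param cohort Data frame with the cohort columns.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
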