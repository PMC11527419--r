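#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' subject-map threshold `z_subject = 2.326` (one-tailed p < 0.01),
#' LPSA z-map threshold `z_lpsa = 2.3`, overlap criterion `fraction = 0.6`,
#' smoothing `fwhm = 6` mm, peak separation `min_sep = 3` voxels,
#' searchlight `radius = 3` voxels, behavioral inclusion `min_valid = 6`
#' presses, FD rule `fd_k = 1.5` SD, and response window `rt_window =
#' c(0, 960)` ms.
#'
#' @param ... Named overrides of the defaults listed above, plus the
#'   simulation settings `n_subjects`, `shape`, `voxel_size`, `regions`
#'   (a [synthetic_truth]) and `seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(z_subject = 2.326, z_lpsa = 2.3, fraction = 0.6, fwhm = 6,
              min_sep = 3, radius = 3, min_valid = 6, fd_k = 1.5,
              rt_window = c(0, 960), n_subjects = 27, shape = c(32, 38, 32),
              voxel_size = c(2.5, 2.5, 2.5), truth = synthetic_truth(),
              seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$fraction <= 0 || cfg$fraction > 1) stop("fraction must be in (0,1]")
  for (f in c("z_subject", "z_lpsa", "fwhm", "min_sep", "radius", "fd_k"))
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis on a simulated cohort
#'
#' Executes the stages in order — simulate, behavioral scoring, per-task
#' GCSS, conjunction, parcel pattern similarity, searchlight LPSA, recovery
#' report — writing outputs under `out_dir` and returning a manifest that
#' lists every file, the configuration and the seed. Reruns with the same
#' config reproduce all statistics.
#'
#' @param config A [pipeline_config].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param searchlight_lpsa Run the whole-brain searchlight stage (the most
#'   expensive one), default `TRUE`.
#' @return List with `cohort`, `behavior`, `gcss` (per task), `conjunction`,
#'   `similarity`, `lpsa`, `recovery`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         searchlight_lpsa = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  outputs <- character(0)
  emit_vol <- function(obj, name) {
    if (is.null(out_dir)) return()
    p <- file.path(out_dir, name)
    write_stat_volume(obj, p)
    outputs[[length(outputs) + 1L]] <<- p
  }
  emit_tsv <- function(df, name) {
    if (is.null(out_dir)) return()
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[length(outputs) + 1L]] <<- p
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  message("[simulate] n=", config$n_subjects, " grid=",
          paste(config$shape, collapse = "x"))
  cohort <- simulate_contrast_maps(config$truth, config$n_subjects,
                                   config$shape, config$voxel_size,
                                   seed = config$seed)

  message("[behavior] scoring simulated responders")
  targets <- assign_targets(seed = config$seed)
  logs <- unlist(lapply(seq_len(config$n_subjects), function(s) {
    run <- assemble_run("syllable", seed = config$seed + s)
    simulate_responses(run, list(p_hit = 0.7, p_fa = 0.05, rt_mean_ms = 420,
                                 rt_sd_ms = 150),
                       targets, seed = config$seed + 1000L + s,
                       subject_id = sprintf("sub-%02d", s),
                       window_ms = config$rt_window)
  }), recursive = FALSE)
  behavior <- score_behavior(logs, config$rt_window)
  pooled <- behavior[is.na(behavior$block_index), ]
  incl <- exclude_low_response(pooled, config$min_valid)
  message("[behavior] ", nrow(incl$kept), " condition-rows kept, ",
          nrow(incl$removed), " removed (<", config$min_valid, " presses)")
  emit_tsv(behavior, "behavior_scores.tsv")

  gcss_res <- list()
  binmaps <- list()
  for (task in c("syllable", "tone")) {
    message("[gcss] task=", task)
    binmaps[[task]] <- lapply(cohort$vols[[task]], binarize,
                              mask = cohort$mask,
                              z_thresh = config$z_subject)
    gcss_res[[task]] <- gcss_parcellate(binmaps[[task]], config$fwhm,
                                        config$fraction, config$min_sep)
    gcss_res[[task]] <- parcel_effect_size(gcss_res[[task]],
                                           cohort$vols[[task]])
    message("[gcss] task=", task, ": ", nrow(gcss_res[[task]]$parcels),
            " parcel(s)")
    if (!is.null(out_dir)) {
      write_parcel_set(gcss_res[[task]],
                       file.path(out_dir, paste0("gcss_", task,
                                                 "_labels.nii.gz")),
                       file.path(out_dir, paste0("gcss_", task,
                                                 "_parcels.tsv")))
      outputs <- c(outputs,
                   file.path(out_dir, paste0("gcss_", task,
                                             "_labels.nii.gz")),
                   file.path(out_dir, paste0("gcss_", task, "_parcels.tsv")))
    }
  }

  message("[conjunction] subject-level AND + GCSS")
  conj_maps <- lapply(seq_len(config$n_subjects), function(s)
    subject_conjunction(binmaps$syllable[[s]], binmaps$tone[[s]]))
  conjunction <- conjunction_gcss(conj_maps, config$fwhm, config$fraction,
                                  config$min_sep)
  message("[conjunction] ", nrow(conjunction$parcels), " parcel(s)")

  similarity <- do.call(rbind, lapply(c("syllable", "tone"), function(task) {
    ps <- gcss_res[[task]]
    keep <- ps$parcels$n_voxels >= 3
    ps$parcels <- ps$parcels[keep, , drop = FALSE]
    if (nrow(ps$parcels) == 0L) return(NULL)
    out <- parcel_set_similarity(ps, cohort$vols$syllable, cohort$vols$tone)
    out$source_task <- task
    out
  }))
  if (!is.null(similarity)) emit_tsv(similarity, "parcel_similarity.tsv")

  lpsa_res <- NULL
  if (searchlight_lpsa) {
    message("[lpsa] searchlight radius=", config$radius, " vox")
    slmaps <- lapply(seq_len(config$n_subjects), function(s)
      fisher_normalize(searchlight(cohort$vols$syllable[[s]],
                                   cohort$vols$tone[[s]], cohort$mask,
                                   config$radius)))
    lpsa_res <- lpsa_gcss(slmaps, cohort$mask, config$z_lpsa, config$fwhm,
                          config$fraction, config$min_sep)
    message("[lpsa] ", nrow(lpsa_res$parcels), " parcel(s)")
  }

  recovery <- ground_truth_report(cohort, gcss_res$syllable)

  manifest <- list(package_version = as.character(utils::packageVersion("slgcss")),
                   seed = config$seed, config = unclass(config)[
                     c("z_subject", "z_lpsa", "fraction", "fwhm", "min_sep",
                       "radius", "min_valid", "fd_k", "rt_window",
                       "n_subjects", "shape", "voxel_size")],
                   outputs = unlist(outputs))
  if (!is.null(out_dir)) {
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    manifest$outputs <- c(manifest$outputs, mp)
  }
  list(cohort = cohort, behavior = behavior, gcss = gcss_res,
       conjunction = conjunction, similarity = similarity, lpsa = lpsa_res,
       recovery = recovery, manifest = manifest)
}
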