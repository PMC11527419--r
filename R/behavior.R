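#' Button-press log for one block
#'
#' @param subject_id Subject identifier.
#' @param block A `block_sequence` (supplies tokens and onsets).
#' @param press_times_ms Non-negative press timestamps (ms, block-local);
#'   stored sorted.
#' @param target_id The token the participant was tracking.
#' @param block_index Within-condition block number (1-3).
#' @return An object of class `response_log`.
#' @export
response_log <- function(subject_id, block, press_times_ms, target_id,
                         block_index = 1L) {
  stopifnot(inherits(block, "block_sequence"))
  press_times_ms <- as.numeric(press_times_ms)
  if (any(press_times_ms < 0)) stop("press times must be non-negative")
  structure(list(subject_id = subject_id, task = block$domain,
                 condition = block$condition, block_index = block_index,
                 press_times_ms = sort(press_times_ms), target_id = target_id,
                 block = block),
            class = "response_log")
}

#' Match presses to target windows
#'
#' A press is a valid response to the earliest not-yet-matched target whose
#' response window (`onset + window_ms[1]` to `onset + window_ms[2]`,
#' inclusive) contains it; each press matches at most one target and each
#' target takes at most one press (the first). RT is press time minus target
#' onset. Presses matching no target window are false-alarm candidates.
#'
#' @param log A [response_log].
#' @param window_ms Valid-response window relative to target onset, default
#'   `c(0, 960)` (the stimulus and one stimulus after).
#' @return A list: `matches` (data.frame `target_onset`, `rt_ms` with `NA`
#'   for misses, one row per target), `unmatched_presses` (times of presses
#'   matched to no target).
#' @export
match_presses <- function(log, window_ms = c(0, 960)) {
  stopifnot(inherits(log, "response_log"), length(window_ms) == 2L)
  onsets <- log$block$onsets_ms[log$block$tokens == log$target_id]
  rt <- rep(NA_real_, length(onsets))
  unmatched <- numeric(0)
  for (p in log$press_times_ms) {
    open <- which(is.na(rt) & onsets + window_ms[1] <= p &
                    p <= onsets + window_ms[2])
    if (length(open)) rt[open[1]] <- p - onsets[open[1]]
    else unmatched <- c(unmatched, p)
  }
  list(matches = data.frame(target_onset = onsets, rt_ms = rt),
       unmatched_presses = unmatched)
}

#' Signal-detection counts and A-prime for one block
#'
#' Hit rate is matched targets over targets. Each unmatched press is
#' assigned to the most recent non-target stimulus onset at or before it;
#' the false-alarm count is the number of distinct non-target onsets that
#' received at least one such press, over the number of non-target stimuli,
#' keeping both rates in \[0, 1\].
#'
#' @param log A [response_log].
#' @param matches Result of [match_presses] on the same log.
#' @return A list with `n_targets`, `n_hits`, `n_false_alarms`,
#'   `n_nontarget_opportunities`, `hit_rate`, `fa_rate`, `aprime`.
#' @export
detection_stats <- function(log, matches = match_presses(log)) {
  n_targets <- nrow(matches$matches)
  if (n_targets == 0L)
    stop("no target stimuli in block: hit rate undefined")
  n_hits <- sum(!is.na(matches$matches$rt_ms))
  nt_onsets <- log$block$onsets_ms[log$block$tokens != log$target_id]
  alarmed <- unique(vapply(matches$unmatched_presses, function(p) {
    prior <- nt_onsets[nt_onsets <= p]
    if (length(prior)) max(prior) else NA_real_
  }, 0))
  n_fa <- sum(!is.na(alarmed))
  hit_rate <- n_hits / n_targets
  fa_rate <- if (length(nt_onsets)) n_fa / length(nt_onsets) else 0
  list(n_targets = n_targets, n_hits = n_hits, n_false_alarms = n_fa,
       n_nontarget_opportunities = length(nt_onsets),
       hit_rate = hit_rate, fa_rate = fa_rate,
       aprime = aprime(hit_rate, fa_rate))
}

#' A-prime nonparametric sensitivity
#'
#' Piecewise formula: when fa < hit,
#' `A' = 1/2 + ((hit - fa) * (1 + hit - fa)) / (4 * hit * (1 - fa))`;
#' when fa > hit,
#' `A' = 1/2 - ((fa - hit) * (1 + fa - hit)) / (4 * fa * (1 - hit))`;
#' and `A' = 0.5` when the rates are equal (the common limit of both
#' branches, chance-level detection). 1.0 indicates perfect discriminability.
#'
#' @param hit,fa Hit and false-alarm rates in \[0, 1\]. Vectorized.
#' @return A-prime in \[0, 1\].
#' @export
aprime <- function(hit, fa) {
  if (any(hit < 0 | hit > 1 | fa < 0 | fa > 1))
    stop("hit and fa rates must lie in [0, 1]")
  out <- rep(0.5, length(hit <- rep_len(hit, max(length(hit), length(fa)))))
  fa <- rep_len(fa, length(hit))
  up <- fa < hit
  dn <- fa > hit
  out[up] <- 0.5 + ((hit[up] - fa[up]) * (1 + hit[up] - fa[up])) /
    (4 * hit[up] * (1 - fa[up]))
  out[dn] <- 0.5 - ((fa[dn] - hit[dn]) * (1 + fa[dn] - hit[dn])) /
    (4 * fa[dn] * (1 - hit[dn]))
  out
}

#' Reaction-time summary over valid responses
#'
#' @param matches Result of [match_presses] (or a data.frame with `rt_ms`).
#' @param log_transform Also summarize natural-log RTs (accounts for
#'   between-subject baseline differences).
#' @return A list with `n_valid`, `mean_rt_ms`, `sd_rt_ms`, and (when
#'   requested) `mean_log_rt`, `sd_log_rt`; all summaries are `NA` when
#'   there are no valid RTs.
#' @export
rt_summary <- function(matches, log_transform = TRUE) {
  rt <- if (is.data.frame(matches)) matches$rt_ms else matches$matches$rt_ms
  rt <- rt[!is.na(rt)]
  out <- list(n_valid = length(rt),
              mean_rt_ms = if (length(rt)) mean(rt) else NA_real_,
              sd_rt_ms = if (length(rt)) stats::sd(rt) else NA_real_)
  if (log_transform) {
    lrt <- log(rt)
    out$mean_log_rt <- if (length(rt)) mean(lrt) else NA_real_
    out$sd_log_rt <- if (length(rt)) stats::sd(lrt) else NA_real_
  }
  out
}

#' Exclude subjects with too few valid responses
#'
#' Subjects with fewer than `min_valid` valid key presses in a condition are
#' removed from that condition's behavioral analysis (they remain eligible
#' for imaging analyses).
#'
#' @param summaries Data frame with at least `subject_id` and `n_valid`.
#' @param min_valid Exclusion threshold (default 6; `n_valid < 6` removed).
#' @return List with `kept` and `removed` data frames.
#' @export
exclude_low_response <- function(summaries, min_valid = 6) {
  keep <- summaries$n_valid >= min_valid
  list(kept = summaries[keep, , drop = FALSE],
       removed = summaries[!keep, , drop = FALSE])
}

#' Classical paired t contrast
#'
#' Paired t on the pairwise differences, df = n - 1, two-tailed p. When the
#' differences have zero spread the t statistic is degenerate: all-zero
#' differences give `t = 0, p = 1`; a constant nonzero difference gives an
#' `NA` sentinel with a note.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2;
#'   pairs with any `NA` are dropped.
#' @return List with `t`, `df`, `p_two_tailed`, `mean_diff`, `n`, and
#'   optionally `note`.
#' @export
paired_contrast <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    stop("paired vectors must have equal length")
  ok <- !is.na(values_a) & !is.na(values_b)
  d <- values_a[ok] - values_b[ok]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs")
  md <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    if (md == 0)
      return(list(t = 0, df = n - 1, p_two_tailed = 1, mean_diff = 0, n = n))
    return(list(t = NA_real_, df = n - 1, p_two_tailed = NA_real_,
                mean_diff = md, n = n,
                note = "zero-variance nonzero differences: t undefined"))
  }
  t <- md / (s / sqrt(n))
  list(t = t, df = n - 1,
       p_two_tailed = 2 * stats::pt(-abs(t), df = n - 1), mean_diff = md,
       n = n)
}

#' Framewise-displacement exclusion
#'
#' Removes subjects whose mean FD exceeds the group mean plus `k_sd` group
#' standard deviations, both computed over all subjects before exclusion.
#'
#' @param cohort Data frame with `subject_id` and `mean_fd_mm`.
#' @param k_sd Multiplier on the group SD (default 1.5).
#' @return List with `kept`, `removed`, `group_mean_fd`, `cutoff`.
#' @export
fd_exclude <- function(cohort, k_sd = 1.5) {
  if (nrow(cohort) < 2) stop("need at least 2 subjects to estimate the SD")
  mu <- mean(cohort$mean_fd_mm)
  cutoff <- mu + k_sd * stats::sd(cohort$mean_fd_mm)
  out <- cohort$mean_fd_mm > cutoff
  list(kept = cohort[!out, , drop = FALSE],
       removed = cohort[out, , drop = FALSE],
       group_mean_fd = mu, cutoff = cutoff)
}

#' Score a set of response logs
#'
#' Convenience wrapper producing one row per (subject, task, condition,
#' block) plus pooled per-condition rows (`block_index = NA`, windows
#' matched per block, counts pooled before computing rates and A-prime).
#'
#' @param logs List of [response_log] objects.
#' @param window_ms Valid-response window, default `c(0, 960)`.
#' @return Data frame of detection and RT summaries.
#' @export
score_behavior <- function(logs, window_ms = c(0, 960)) {
  per_block <- lapply(logs, function(lg) {
    m <- match_presses(lg, window_ms)
    ds <- detection_stats(lg, m)
    rs <- rt_summary(m)
    data.frame(subject_id = lg$subject_id, task = lg$task,
               condition = lg$condition, block_index = lg$block_index,
               n_targets = ds$n_targets, n_hits = ds$n_hits,
               n_false_alarms = ds$n_false_alarms,
               n_nontarget_opportunities = ds$n_nontarget_opportunities,
               hit_rate = ds$hit_rate, fa_rate = ds$fa_rate,
               aprime = ds$aprime, n_valid = rs$n_valid,
               mean_rt_ms = rs$mean_rt_ms, mean_log_rt = rs$mean_log_rt)
  })
  tab <- do.call(rbind, per_block)
  pooled <- do.call(rbind, lapply(
    split(tab, tab[c("subject_id", "task", "condition")], drop = TRUE),
    function(g) {
      hit <- sum(g$n_hits) / sum(g$n_targets)
      fa <- if (sum(g$n_nontarget_opportunities) > 0)
        sum(g$n_false_alarms) / sum(g$n_nontarget_opportunities) else 0
      data.frame(subject_id = g$subject_id[1], task = g$task[1],
                 condition = g$condition[1], block_index = NA_integer_,
                 n_targets = sum(g$n_targets), n_hits = sum(g$n_hits),
                 n_false_alarms = sum(g$n_false_alarms),
                 n_nontarget_opportunities = sum(g$n_nontarget_opportunities),
                 hit_rate = hit, fa_rate = fa, aprime = aprime(hit, fa),
                 n_valid = sum(g$n_valid),
                 mean_rt_ms = NA_real_, mean_log_rt = NA_real_)
    }))
  rownames(pooled) <- NULL
  rbind(tab, pooled)
}

#' Read / write response logs as TSV
#'
#' Columns: `subject_id`, `task`, `condition`, `block_index`,
#' `press_time_ms`, `target_id` — one row per press.
#'
#' @param logs List of [response_log] objects.
#' @param path TSV path.
#' @export
write_response_logs <- function(logs, path) {
  rows <- do.call(rbind, lapply(logs, function(lg) {
    if (length(lg$press_times_ms) == 0L) return(NULL)
    data.frame(subject_id = lg$subject_id, task = lg$task,
               condition = lg$condition, block_index = lg$block_index,
               press_time_ms = lg$press_times_ms, target_id = lg$target_id)
  }))
  if (is.null(rows))
    rows <- data.frame(subject_id = character(), task = character(),
                       condition = character(), block_index = integer(),
                       press_time_ms = numeric(), target_id = character())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
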