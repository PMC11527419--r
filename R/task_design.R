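#' Stimulus inventories for the auditory statistical-learning task
#'
#' An inventory holds the 12 distinct tokens of one domain and the 4 ordered
#' triplets built from them; the 12 triplet positions use each token exactly
#' once. The built-in defaults are the standard 12 consonant-vowel syllables
#' grouped into tri-syllabic pseudowords (pi-tu-bi, bu-pa-da, di-ba-pu,
#' ta-ti-du) and 12 pure tones of one octave grouped into tri-tonal melodies
#' (F#-D-E, A-B-C, C#-A#-F, G-D#-G#).
#'
#' @param domain `"syllable"` or `"tone"`.
#' @param items Character vector of 12 distinct token ids.
#' @param triplets List of 4 character vectors of length 3.
#' @return An object of class `stimulus_inventory`.
#' @export
stimulus_inventory <- function(domain = c("syllable", "tone"), items = NULL,
                               triplets = NULL) {
  domain <- match.arg(domain)
  if (is.null(items) || is.null(triplets)) {
    if (domain == "syllable") {
      items <- c("pi", "pa", "pu", "ti", "ta", "tu",
                 "di", "da", "du", "bi", "ba", "bu")
      triplets <- list(c("pi", "tu", "bi"), c("bu", "pa", "da"),
                       c("di", "ba", "pu"), c("ta", "ti", "du"))
    } else {
      items <- c("F", "G", "D", "G#", "C#", "B",
                 "C", "F#", "D#", "E", "A", "A#")
      triplets <- list(c("F#", "D", "E"), c("A", "B", "C"),
                       c("C#", "A#", "F"), c("G", "D#", "G#"))
    }
  }
  if (length(items) != 12L || anyDuplicated(items))
    stop("inventory needs exactly 12 distinct items")
  if (length(triplets) != 4L || any(lengths(triplets) != 3L))
    stop("inventory needs exactly 4 triplets of 3 tokens")
  used <- unlist(triplets)
  if (!setequal(used, items) || anyDuplicated(used))
    stop("the 12 triplet positions must use each item exactly once")
  structure(list(domain = domain, items = items, triplets = triplets),
            class = "stimulus_inventory")
}

# Evaluate expr under a local RNG seeded with `seed`, restoring global state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

new_block_sequence <- function(domain, condition, tokens, stim_ms, isi_ms) {
  soa <- stim_ms + isi_ms
  structure(list(domain = domain, condition = condition, tokens = tokens,
                 onsets_ms = (seq_along(tokens) - 1) * soa,
                 stim_ms = stim_ms, isi_ms = isi_ms),
            class = "block_sequence")
}

#' Generate a structured block of repeating triplets
#'
#' Draws a triplet order by repeated random choice under the rule that no
#' identical triplets are adjacent, with each of the 4 triplets appearing
#' exactly `reps_per_triplet` times, then concatenates the triplets into the
#' token stream. Onsets advance by `stim_ms + isi_ms` (the 480 ms stimulus
#' onset asynchrony at the default 460/20 ms timing).
#'
#' @param inv A [stimulus_inventory].
#' @param reps_per_triplet Repetitions of each triplet (default 8, giving a
#'   96-token block containing 32 triplet runs).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param stim_ms,isi_ms Stimulus duration and inter-stimulus interval (ms).
#' @return A `block_sequence` with `condition = "structured"`.
#' @export
generate_structured_block <- function(inv, reps_per_triplet = 8, seed = 1,
                                      stim_ms = 460, isi_ms = 20) {
  stopifnot(inherits(inv, "stimulus_inventory"), reps_per_triplet >= 1)
  order <- with_seed(seed, draw_triplet_order(4L, reps_per_triplet))
  tokens <- unlist(inv$triplets[order])
  new_block_sequence(inv$domain, "structured", tokens, stim_ms, isi_ms)
}

# Sample a sequence over 1..n_triplets with exact counts and no immediate
# repetition; restarts on dead ends (rare for 4 triplets).
draw_triplet_order <- function(n_triplets, reps) {
  for (attempt in 1:10000) {
    remaining <- rep(reps, n_triplets)
    out <- integer(n_triplets * reps)
    prev <- 0L
    ok <- TRUE
    for (i in seq_along(out)) {
      cand <- which(remaining > 0L)
      cand <- cand[cand != prev]
      if (length(cand) == 0L) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      out[i] <- pick
      remaining[pick] <- remaining[pick] - 1L
      prev <- pick
    }
    if (ok) return(out)
  }
  stop("could not draw a non-repeating triplet order") # unreachable for n >= 2
}

#' Generate a pseudo-random block with unique trigrams
#'
#' Emits `length` tokens from the 12-item inventory such that no ordered
#' trigram of consecutive tokens (overlapping windows) occurs more than once
#' within the block. Built token-by-token with rejection of trigram repeats
#' and bounded restarts.
#'
#' @inheritParams generate_structured_block
#' @param length Number of tokens (default 96).
#' @param max_retries Restart bound before giving up.
#' @return A `block_sequence` with `condition = "random"`.
#' @export
generate_random_block <- function(inv, length = 96, seed = 1,
                                  stim_ms = 460, isi_ms = 20,
                                  max_retries = 10000) {
  stopifnot(inherits(inv, "stimulus_inventory"), length >= 3)
  tokens <- with_seed(seed, draw_unique_trigram_seq(inv$items, length,
                                                    max_retries))
  new_block_sequence(inv$domain, "random", tokens, stim_ms, isi_ms)
}

draw_unique_trigram_seq <- function(items, n, max_retries) {
  for (attempt in seq_len(max_retries)) {
    out <- character(n)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    ok <- TRUE
    for (i in seq_len(n)) {
      cand <- sample(items)
      placed <- FALSE
      for (tok in cand) {
        if (i >= 3L) {
          key <- paste(out[i - 2L], out[i - 1L], tok, sep = "\r")
          if (!is.null(seen[[key]])) next
        }
        out[i] <- tok
        if (i >= 3L) seen[[paste(out[i - 2L], out[i - 1L], tok,
                                 sep = "\r")]] <- TRUE
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(out)
  }
  stop("no trigram-unique sequence of length ", n, " found after ",
       max_retries, " attempts")
}

#' Duration of a k-token triplet
#'
#' @param stim_ms Stimulus duration (ms).
#' @param isi_ms Inter-stimulus interval (ms).
#' @param k Tokens per triplet.
#' @return `k * (stim_ms + isi_ms)` in ms; 1,440 ms at the default
#'   460/20 ms timing with k = 3.
#' @export
triplet_duration_ms <- function(stim_ms = 460, isi_ms = 20, k = 3) {
  stopifnot(stim_ms > 0, isi_ms >= 0, k >= 1)
  k * (stim_ms + isi_ms)
}

#' Assemble one run of the auditory SL task
#'
#' A run interleaves, in random order, 3 structured blocks of one domain and
#' 3 random blocks of the other domain, with a rest marker after every block.
#' Across the run each structured triplet is presented 24 times (3 blocks x 8
#' repetitions) and the random domain contributes 288 tokens (3 x 96).
#'
#' @param structured_domain Domain of the structured blocks; the random
#'   blocks use the other domain.
#' @param reps Triplet repetitions per structured block (default 8).
#' @param random_length Tokens per random block (default 96).
#' @param seed Integer seed.
#' @param rest_ms Rest-block duration (ms); it only affects block start
#'   times, default 0.
#' @param stim_ms,isi_ms Timing parameters (ms).
#' @return An object of class `run_design`: `blocks` (list of
#'   `block_sequence` in presentation order), `block_start_ms`, `rest_ms`,
#'   `structured_domain`, `seed`.
#' @export
assemble_run <- function(structured_domain = c("syllable", "tone"), reps = 8,
                         random_length = 96, seed = 1, rest_ms = 0,
                         stim_ms = 460, isi_ms = 20) {
  structured_domain <- match.arg(structured_domain)
  random_domain <- setdiff(c("syllable", "tone"), structured_domain)
  inv_s <- stimulus_inventory(structured_domain)
  inv_r <- stimulus_inventory(random_domain)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 7L))
  structured <- lapply(1:3, function(b)
    generate_structured_block(inv_s, reps, seed = sub_seeds[b],
                              stim_ms = stim_ms, isi_ms = isi_ms))
  random <- lapply(1:3, function(b)
    generate_random_block(inv_r, random_length, seed = sub_seeds[3 + b],
                          stim_ms = stim_ms, isi_ms = isi_ms))
  order <- with_seed(sub_seeds[7], sample(c("structured", "structured",
                                            "structured", "random", "random",
                                            "random")))
  si <- ri <- 0L
  blocks <- vector("list", 6L)
  within_idx <- integer(6L)
  for (i in 1:6) {
    if (order[i] == "structured") {
      si <- si + 1L; blocks[[i]] <- structured[[si]]; within_idx[i] <- si
    } else {
      ri <- ri + 1L; blocks[[i]] <- random[[ri]]; within_idx[i] <- ri
    }
  }
  block_ms <- vapply(blocks, function(b)
    length(b$tokens) * (b$stim_ms + b$isi_ms), 0)
  start <- cumsum(c(0, head(block_ms + rest_ms, -1L)))
  structure(list(blocks = blocks, block_order = order,
                 block_index = within_idx, block_start_ms = start,
                 rest_ms = rest_ms, structured_domain = structured_domain,
                 seed = seed),
            class = "run_design")
}

#' Assign the tracked targets for a participant
#'
#' Each participant tracks one syllable and one tone; the target is always
#' the final token of one of the four triplets of its domain.
#'
#' @param inv_syllable,inv_tone Inventories (defaults used when `NULL`).
#' @param seed Integer seed.
#' @return Named list `list(syllable = <token>, tone = <token>)`.
#' @export
assign_targets <- function(inv_syllable = NULL, inv_tone = NULL, seed = 1) {
  if (is.null(inv_syllable)) inv_syllable <- stimulus_inventory("syllable")
  if (is.null(inv_tone)) inv_tone <- stimulus_inventory("tone")
  picks <- with_seed(seed, c(sample.int(4L, 1L), sample.int(4L, 1L)))
  list(syllable = inv_syllable$triplets[[picks[1]]][3],
       tone = inv_tone$triplets[[picks[2]]][3])
}

#' Write an onset log for a run as TSV
#'
#' Columns: `block_index` (presentation position), `condition`, `domain`,
#' `token`, `onset_ms` (block-local).
#'
#' @param run A `run_design`.
#' @param path Output TSV path.
#' @export
write_onset_log <- function(run, path) {
  rows <- do.call(rbind, lapply(seq_along(run$blocks), function(i) {
    b <- run$blocks[[i]]
    data.frame(block_index = i, condition = b$condition, domain = b$domain,
               token = b$tokens, onset_ms = b$onsets_ms)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
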