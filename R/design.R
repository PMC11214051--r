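#' Construct a balanced stimulus set
#'
#' Builds the stimulus table for a voice experiment: every speaker
#' contributes one recording per vowel, genders and age groups are
#' balanced across speakers (and crossed when counts allow).  The
#' default reproduces the full design of 32 speakers x 3 vowels = 96
#' stimuli with 16 speakers per gender and per age group.
#'
#' @param n_speakers number of speakers (even)
#' @param vowels character vector of vowel categories
#' @return data.frame with columns `stimulus_id`, `speaker_id`,
#'   `vowel`, `speaker_gender`, `speaker_age_group`
#' @export
make_stimulus_set <- function(n_speakers = 32, vowels = c("a", "i", "u")) {
  if (n_speakers < 2 || n_speakers %% 2 != 0)
    stop("`n_speakers` must be an even count >= 2")
  if (!length(vowels)) stop("at least one vowel required")
  speaker_id <- sprintf("S%02d", seq_len(n_speakers))
  # gender alternates, age group alternates in pairs -> both balanced
  # and crossed when n_speakers is a multiple of 4
  gender <- rep(c("female", "male"), length.out = n_speakers)
  age <- rep(rep(c("young", "old"), each = 2), length.out = n_speakers)
  out <- expand.grid(vowel = vowels, speaker_id = speaker_id,
                     stringsAsFactors = FALSE)[, 2:1]
  out$stimulus_id <- paste0(out$speaker_id, "_", out$vowel)
  out$speaker_gender <- gender[match(out$speaker_id, speaker_id)]
  out$speaker_age_group <- age[match(out$speaker_id, speaker_id)]
  out <- out[, c("stimulus_id", "speaker_id", "vowel",
                 "speaker_gender", "speaker_age_group")]
  rownames(out) <- NULL
  out
}

#' Generate a randomized experiment design
#'
#' Lays out experimental trials (every stimulus repeated
#' `n_repetitions` times) and interleaved vigilance probe trials over
#' `n_blocks` blocks.  Vigilance probes are split 50/50 into
#' identical-pair probes (the vigilance stimulus is presented twice)
#' and different-pair probes (one vigilance-stimulus presentation
#' preceded by a random experimental stimulus).  Probes are spread
#' evenly within each block, never first in a block and never on
#' consecutive trials.  Stimulus onset asynchronies are jittered
#' uniformly within `jitter_range_ms`.
#'
#' @param stimuli stimulus set from [make_stimulus_set()]
#' @param n_repetitions repetitions of every experimental stimulus
#' @param vigilance_stimuli number of distinct vigilance stimuli
#' @param vigilance_repetitions probe trials per vigilance stimulus
#' @param n_blocks number of blocks the trials are split over
#' @param jitter_range_ms length-2 numeric, onset-asynchrony range (ms)
#' @param seed integer seed controlling trial order and jitter
#' @return an object of class `experiment_design`: list with `trials`
#'   (data.frame: index, block, stimulus_id, trial_type,
#'   onset_asynchrony_ms), `n_blocks`, `jitter_range_ms`
#' @export
generate_design <- function(stimuli, n_repetitions = 40,
                            vigilance_stimuli = 24,
                            vigilance_repetitions = 16,
                            n_blocks = 6,
                            jitter_range_ms = c(800, 1000),
                            seed = 1) {
  stopifnot(n_repetitions >= 1, n_blocks >= 1,
            vigilance_stimuli >= 0, vigilance_repetitions >= 0)
  n_stim <- nrow(stimuli)
  n_exp <- n_stim * n_repetitions
  n_vig <- vigilance_stimuli * vigilance_repetitions
  n_total <- n_exp + n_vig
  if (n_total %% n_blocks != 0)
    stop("total trial count ", n_total, " (", n_exp, " experimental + ",
         n_vig, " vigilance) is not divisible by n_blocks = ", n_blocks)
  per_block <- n_total %/% n_blocks
  if (n_exp %% n_blocks != 0)
    stop("experimental trial count ", n_exp,
         " is not divisible by n_blocks = ", n_blocks)
  if (n_vig %% n_blocks != 0)
    stop("vigilance trial count ", n_vig,
         " is not divisible by n_blocks = ", n_blocks)
  vig_per_block <- n_vig %/% n_blocks
  if (n_vig > 0 && vig_per_block > (per_block - 1) %/% 2)
    stop("cannot place ", vig_per_block, " non-consecutive vigilance ",
         "trials after slot 1 within a block of ", per_block, " trials")
  if (n_vig %% 2 != 0)
    stop("vigilance trial count must be even for a 50/50 ",
         "identical/different split (got ", n_vig, ")")

  with_seed(seed, {
    exp_ids <- sample(rep(stimuli$stimulus_id, n_repetitions))
    if (n_vig > 0) {
      vig_ids <- sprintf("V%02d", seq_len(vigilance_stimuli))
      # per vigilance stimulus: half identical-pair, half different-pair
      half <- vigilance_repetitions / 2
      vtype <- unlist(lapply(seq_len(vigilance_stimuli), function(i) {
        k <- floor(half)
        types <- c(rep("vigilance_identical", k),
                   rep("vigilance_different", vigilance_repetitions - k))
        # odd repetition counts alternate the extra type across stimuli
        if (vigilance_repetitions %% 2 == 1 && i %% 2 == 0)
          types <- rev(types)
        types
      }))
      vstim <- rep(vig_ids, each = vigilance_repetitions)
      ord <- sample(n_vig)
      vstim <- vstim[ord]; vtype <- vtype[ord]
    }

    trials <- vector("list", n_blocks)
    exp_per_block <- n_exp %/% n_blocks
    for (b in seq_len(n_blocks)) {
      ids <- exp_ids[((b - 1) * exp_per_block + 1):(b * exp_per_block)]
      block_ids <- character(per_block)
      block_type <- rep("experimental", per_block)
      if (vig_per_block > 0) {
        # even spacing with a small seeded jitter; never slot 1,
        # never adjacent
        base <- round(seq(2, per_block, length.out = vig_per_block))
        jit <- sample(-1:1, vig_per_block, replace = TRUE)
        slots <- pmin(pmax(base + jit, 2), per_block)
        while (any(duplicated(slots)) || any(diff(sort(slots)) < 2)) {
          slots <- sort(slots)
          bad <- which(duplicated(slots) | c(FALSE, diff(slots) < 2))
          slots[bad] <- pmin(slots[bad] + 1L, per_block)
          if (max(slots) > per_block) stop("vigilance placement failed")
        }
        slots <- sort(slots)
        vi <- ((b - 1) * vig_per_block + 1):(b * vig_per_block)
        block_ids[slots] <- vstim[vi]
        block_type[slots] <- vtype[vi]
        block_ids[block_type == "experimental"] <- ids
      } else {
        block_ids <- ids
      }
      trials[[b]] <- data.frame(
        block = b, stimulus_id = block_ids, trial_type = block_type,
        stringsAsFactors = FALSE)
    }
    trials <- do.call(rbind, trials)
    trials$index <- seq_len(nrow(trials))
    trials$onset_asynchrony_ms <- runif(nrow(trials), jitter_range_ms[1],
                                        jitter_range_ms[2])
    trials <- trials[, c("index", "block", "stimulus_id", "trial_type",
                         "onset_asynchrony_ms")]
    structure(list(trials = trials, n_blocks = n_blocks,
                   jitter_range_ms = jitter_range_ms,
                   stimuli = stimuli, seed = seed),
              class = "experiment_design")
  })
}

#' Summarize trial counts of an experiment design
#'
#' @param design an `experiment_design`
#' @return list with `n_experimental`, `n_vigilance`,
#'   `n_vigilance_presentations` (identical-pair probes contribute two
#'   vigilance-stimulus presentations, different-pair probes one),
#'   `per_block` (table of trials per block) and `n_total`
#' @export
design_counts <- function(design) {
  tt <- design$trials$trial_type
  n_ident <- sum(tt == "vigilance_identical")
  n_diff <- sum(tt == "vigilance_different")
  list(
    n_experimental = sum(tt == "experimental"),
    n_vigilance = n_ident + n_diff,
    n_vigilance_identical = n_ident,
    n_vigilance_different = n_diff,
    n_vigilance_presentations = 2L * n_ident + n_diff,
    per_block = as.integer(table(design$trials$block)),
    n_total = nrow(design$trials)
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cnt <- design_counts(x)
  cat("<experiment_design> ", cnt$n_total, " trials (",
      cnt$n_experimental, " experimental, ", cnt$n_vigilance,
      " vigilance) in ", x$n_blocks, " blocks\n", sep = "")
  invisible(x)
}
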