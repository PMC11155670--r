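#' Describe the five-block attention-bias malleability paradigm
#'
#' The AM paradigm is a dot-probe task with five blocks: three assessment
#' blocks (no probe/pain-word contingency, equal numbers of congruent and
#' incongruent trials) interleaved with two training blocks in which the probe
#' always follows the pain word ("towards" training) or always the neutral
#' word ("away" training). Word pairs are organised in three lists: list 1
#' serves assessment 1 and training 1, list 2 serves assessment 2 and training
#' 2, and list 3 serves the final assessment. Each pair appears 4 times in its
#' assessment block and 12 times in its training block, so the default 24-pair
#' lists give block lengths 96, 288, 96, 288, 96.
#'
#' @param n_pairs_per_list word pairs per list (default 24).
#' @param training_order `"towards_first"` (block 2 trains towards pain,
#'   block 4 away) or `"away_first"`.
#' @param list_order permutation of `1:3` giving which stimulus list serves
#'   each (assessment, training) slot; counterbalanced across participants in
#'   cohort simulations.
#' @param fixation_ms,stimulus_ms,iti_ms display durations in ms (recorded in
#'   the design for completeness; they do not affect simulated RTs).
#' @return an object of class `paradigm_design`.
#' @seealso [make_paradigm_schedule()]
#' @export
paradigm_design <- function(n_pairs_per_list = 24,
                            training_order = c("towards_first", "away_first"),
                            list_order = 1:3,
                            fixation_ms = 500, stimulus_ms = 500, iti_ms = 500) {
  training_order <- match.arg(training_order)
  if (!is.numeric(n_pairs_per_list) || length(n_pairs_per_list) != 1L ||
      n_pairs_per_list < 1 || n_pairs_per_list != round(n_pairs_per_list)) {
    stop("`n_pairs_per_list` must be a single positive integer", call. = FALSE)
  }
  if (length(list_order) != 3L || !setequal(list_order, 1:3)) {
    stop("`list_order` must be a permutation of 1:3", call. = FALSE)
  }
  design <- list(
    n_pairs_per_list = as.integer(n_pairs_per_list),
    n_assessment_trials = 4L * as.integer(n_pairs_per_list),
    n_training_trials = 12L * as.integer(n_pairs_per_list),
    block_sequence = c("assessment", "training", "assessment", "training",
                       "assessment"),
    training_order = training_order,
    list_order = as.integer(list_order),
    fixation_ms = fixation_ms, stimulus_ms = stimulus_ms, iti_ms = iti_ms
  )
  class(design) <- "paradigm_design"
  design
}

#' @export
print.paradigm_design <- function(x, ...) {
  cat("AM paradigm design\n")
  cat(sprintf("  blocks: %s\n", paste(x$block_sequence, collapse = " -> ")))
  cat(sprintf("  trials per block: %d assessment / %d training (%d pairs per list)\n",
              x$n_assessment_trials, x$n_training_trials, x$n_pairs_per_list))
  cat(sprintf("  training order: %s; list order: %s\n",
              x$training_order, paste(x$list_order, collapse = ",")))
  invisible(x)
}

# direction trained in each training block, given the counterbalancing arm
training_directions <- function(training_order) {
  if (training_order == "towards_first") c("towards", "away") else c("away", "towards")
}

#' Generate the trial-by-trial schedule of an AM paradigm session
#'
#' Expands a [paradigm_design()] into an ordered table of trial templates, one
#' per trial, with the congruency contract enforced exactly: assessment blocks
#' contain equal numbers of congruent (probe at the pain-word location) and
#' incongruent trials, a towards-training block is fully congruent and an
#' away-training block fully incongruent. The pain word appears equally often
#' above and below fixation within every block, and within-block trial order
#' is randomized by `seed`.
#'
#' @param design a [paradigm_design()].
#' @param seed integer seed controlling within-block shuffling.
#' @return a data frame with one row per trial and columns `block_index`,
#'   `block_type`, `trial_index`, `pair_id`, `pain_word_position`,
#'   `probe_position`, `congruent`, `training_direction` (`NA` in assessment
#'   blocks).
#' @examples
#' sched <- make_paradigm_schedule(paradigm_design(), seed = 1)
#' table(sched$block_index)            # 96 288 96 288 96
#' with(subset(sched, block_index == 1), table(congruent))
#' @export
make_paradigm_schedule <- function(design, seed = 1L) {
  stopifnot(inherits(design, "paradigm_design"))
  np <- design$n_pairs_per_list
  dirs <- training_directions(design$training_order)
  # list serving each block: assessments 1..3 use lists 1..3, training k its
  # assessment's list, all via the counterbalanced list_order permutation
  block_list <- design$list_order[c(1L, 1L, 2L, 2L, 3L)]

  rng <- local_rng(seed)
  blocks <- vector("list", 5L)
  for (b in 1:5) {
    type <- design$block_sequence[b]
    pair_id <- sprintf("L%d_P%02d", block_list[b], seq_len(np))
    if (type == "assessment") {
      # 4 presentations per pair: congruent/incongruent x pain word top/bottom
      tpl <- expand.grid(pair_id = pair_id,
                         congruent = c(TRUE, FALSE),
                         pain_word_position = c("top", "bottom"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      tpl$training_direction <- NA_character_
    } else {
      dir <- dirs[if (b == 2L) 1L else 2L]
      # 12 presentations per pair, pain word 6x top / 6x bottom
      tpl <- expand.grid(pair_id = pair_id,
                         rep = 1:6,
                         pain_word_position = c("top", "bottom"),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      tpl$rep <- NULL
      tpl$congruent <- dir == "towards"
      tpl$training_direction <- dir
    }
    tpl <- tpl[sample.int(nrow(tpl)), , drop = FALSE]
    tpl$block_index <- b
    tpl$block_type <- type
    tpl$trial_index <- seq_len(nrow(tpl))
    blocks[[b]] <- tpl
  }
  restore_rng(rng)

  out <- do.call(rbind, blocks)
  # probe location follows from congruency: congruent = probe at pain word
  out$probe_position <- ifelse(out$congruent == (out$pain_word_position == "top"),
                               "top", "bottom")
  rownames(out) <- NULL
  out[, c("block_index", "block_type", "trial_index", "pair_id",
          "pain_word_position", "probe_position", "congruent",
          "training_direction")]
}

# Scoped RNG: seed the generator without clobbering the caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
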