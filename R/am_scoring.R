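#' Trial-cleaning rules for dot-probe data
#'
#' The defaults implement the standard pipeline for dot-probe RT data:
#' incorrect responses are dropped, responses outside a 200-2000 ms window are
#' dropped, and within each participant x assessment block, responses whose
#' absolute deviation from the block median exceeds `mad_multiplier` times the
#' unscaled median absolute deviation (MAD, no 1.4826 consistency factor) are
#' dropped. Participants whose overall accuracy across the whole paradigm
#' falls below `accuracy_threshold` are excluded.
#'
#' @param rt_min_ms,rt_max_ms response-window bounds in ms.
#' @param mad_multiplier MAD-rule multiplier.
#' @param accuracy_threshold minimum proportion correct for inclusion.
#' @return an object of class `cleaning_rules`.
#' @export
cleaning_rules <- function(rt_min_ms = 200, rt_max_ms = 2000,
                           mad_multiplier = 2.5, accuracy_threshold = 0.75) {
  stopifnot(rt_min_ms > 0, rt_min_ms < rt_max_ms, mad_multiplier > 0,
            accuracy_threshold > 0, accuracy_threshold < 1)
  structure(list(rt_min_ms = rt_min_ms, rt_max_ms = rt_max_ms,
                 mad_multiplier = mad_multiplier,
                 accuracy_threshold = accuracy_threshold),
            class = "cleaning_rules")
}

#' Clean dot-probe trial data
#'
#' Applies, in order: (1) removal of incorrect responses; (2) removal of
#' responses outside the `[rt_min_ms, rt_max_ms]` window; (3) within each
#' participant x assessment block, removal of RTs farther than
#' `mad_multiplier x MAD` from the block median (MAD unscaled; if the block
#' MAD is 0 — e.g. all RTs identical — the step is skipped for that block so
#' it cannot remove every off-median trial); (4) exclusion of participants
#' whose accuracy over all paradigm trials is below the threshold. Training
#' blocks pass through steps 1-2 only; they contribute to accuracy but the
#' MAD rule applies to assessment blocks alone. A retained participant left
#' with an empty assessment block is flagged as excluded (reason
#' `"empty_block"`) rather than silently dropped downstream.
#'
#' @param trials data frame of trial records with columns `participant_id`,
#'   `block_index`, `block_type`, `congruent`, `correct`, `rt_ms`.
#' @param rules a [cleaning_rules()].
#' @return a list of class `am_cleaning` with `trials` (clean rows, excluded
#'   participants removed), `report` (per participant x block counts removed
#'   under each rule and retained), and `excluded` (data frame
#'   `participant_id`, `reason`, `detail`).
#' @examples
#' tr <- data.frame(participant_id = "P1", block_index = 1,
#'                  block_type = "assessment",
#'                  congruent = rep(c(TRUE, FALSE), 3), correct = TRUE,
#'                  rt_ms = c(480, 490, 500, 510, 520, 900))
#' clean_dotprobe(tr)$report$n_mad_outlier  # 1 (the 900 ms trial)
#' @export
clean_dotprobe <- function(trials, rules = cleaning_rules()) {
  stopifnot(inherits(rules, "cleaning_rules"))
  need <- c("participant_id", "block_index", "block_type", "congruent",
            "correct", "rt_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial data lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("no trials supplied", call. = FALSE)

  trials$.row <- seq_len(nrow(trials))
  drop_incorrect <- !trials$correct
  in_window <- trials$rt_ms >= rules$rt_min_ms & trials$rt_ms <= rules$rt_max_ms
  drop_window <- !drop_incorrect & !in_window

  # MAD rule: per participant x assessment block, on trials surviving 1-2
  alive <- !drop_incorrect & !drop_window
  drop_mad <- rep(FALSE, nrow(trials))
  is_assess <- trials$block_type == "assessment"
  idx_sets <- split(which(alive & is_assess),
                    list(trials$participant_id[alive & is_assess],
                         trials$block_index[alive & is_assess]),
                    drop = TRUE)
  for (idx in idx_sets) {
    rt <- trials$rt_ms[idx]
    med <- median(rt)
    mad_u <- median(abs(rt - med))          # unscaled MAD
    if (mad_u > 0) {
      drop_mad[idx] <- abs(rt - med) > rules$mad_multiplier * mad_u
    }
  }

  # participant-level accuracy over every paradigm trial (assessment + training)
  acc <- tapply(trials$correct, trials$participant_id, mean)
  excluded <- data.frame(participant_id = character(), reason = character(),
                         detail = character(), stringsAsFactors = FALSE)
  low_acc <- names(acc)[acc < rules$accuracy_threshold]
  if (length(low_acc)) {
    excluded <- rbind(excluded, data.frame(
      participant_id = low_acc, reason = "accuracy",
      detail = sprintf("accuracy %.3f < %.2f", acc[low_acc],
                       rules$accuracy_threshold),
      stringsAsFactors = FALSE))
  }

  keep <- alive & !drop_mad
  clean <- trials[keep, , drop = FALSE]

  # a retained participant must keep >= 1 trial in every assessment block
  want <- unique(trials[trials$block_type == "assessment",
                        c("participant_id", "block_index")])
  have <- unique(clean[clean$block_type == "assessment",
                       c("participant_id", "block_index")])
  tag <- function(d) paste(d$participant_id, d$block_index, sep = "\r")
  empty <- want[!tag(want) %in% tag(have), , drop = FALSE]
  empty <- empty[!empty$participant_id %in% excluded$participant_id, ,
                 drop = FALSE]
  if (nrow(empty)) {
    agg <- aggregate(block_index ~ participant_id, empty,
                     function(b) paste(sort(b), collapse = ","))
    excluded <- rbind(excluded, data.frame(
      participant_id = agg$participant_id, reason = "empty_block",
      detail = paste("no clean trials in assessment block", agg$block_index),
      stringsAsFactors = FALSE))
  }

  key <- interaction(trials$participant_id, trials$block_index, drop = TRUE)
  report <- data.frame(
    participant_id = tapply(as.character(trials$participant_id), key, `[`, 1L),
    block_index = as.numeric(tapply(trials$block_index, key, `[`, 1L)),
    block_type = tapply(as.character(trials$block_type), key, `[`, 1L),
    n_input = as.integer(table(key)),
    n_incorrect = as.integer(tapply(drop_incorrect, key, sum)),
    n_out_of_window = as.integer(tapply(drop_window, key, sum)),
    n_mad_outlier = as.integer(tapply(drop_mad, key, sum)),
    stringsAsFactors = FALSE)
  report$n_retained <- report$n_input - report$n_incorrect -
    report$n_out_of_window - report$n_mad_outlier
  report$retained_fraction <- report$n_retained / report$n_input
  report <- report[order(report$participant_id, report$block_index), ]
  rownames(report) <- NULL

  clean <- clean[!clean$participant_id %in% excluded$participant_id, , drop = FALSE]
  clean$.row <- NULL
  rownames(clean) <- NULL
  structure(list(trials = clean, report = report, excluded = excluded,
                 accuracy = acc, rules = rules),
            class = "am_cleaning")
}

#' @export
print.am_cleaning <- function(x, ...) {
  n_in <- sum(x$report$n_input)
  n_out <- sum(x$report$n_retained)
  cat(sprintf("dot-probe cleaning: %d of %d trials retained (%.1f%% removed)\n",
              n_out, n_in, 100 * (1 - n_out / n_in)))
  if (nrow(x$excluded)) {
    cat(sprintf("  excluded participants: %s\n",
                paste(sprintf("%s (%s)", x$excluded$participant_id,
                              x$excluded$reason), collapse = ", ")))
  }
  invisible(x)
}

#' Attention-bias index of one assessment block
#'
#' The AB index is the mean RT of incongruent trials (probe at the neutral
#' word's location) minus the mean RT of congruent trials (probe at the pain
#' word's location); positive values indicate a bias toward pain words.
#'
#' @param trials clean trials of a single participant x assessment block,
#'   with columns `congruent` and `rt_ms`.
#' @param participant_id,block_index optional labels used in error messages.
#' @return the AB index in ms.
#' @examples
#' compute_ab_index(data.frame(congruent = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
#'                             rt_ms = c(500, 510, 520, 530, 540, 550)))  # 30
#' @export
compute_ab_index <- function(trials, participant_id = NULL, block_index = NULL) {
  stopifnot(all(c("congruent", "rt_ms") %in% names(trials)))
  n_con <- sum(trials$congruent)
  n_inc <- sum(!trials$congruent)
  if (n_con == 0L || n_inc == 0L) {
    where <- paste0(
      if (!is.null(participant_id)) paste0(" for participant ", participant_id),
      if (!is.null(block_index)) paste0(", block ", block_index))
    stop("AB index undefined", where, ": ",
         if (n_con == 0L) "no congruent" else "no incongruent",
         " trials remain", call. = FALSE)
  }
  mean(trials$rt_ms[!trials$congruent]) - mean(trials$rt_ms[trials$congruent])
}

#' Malleability indices from the three assessment-block AB values
#'
#' Directional indices follow the post-minus-pre convention: the index for
#' the training performed between assessments k and k+1 is `AB(k+1) - AB(k)`,
#' assigned to towards/away according to `training_order`. The overall index
#' is direction-agnostic: `|AB2 - AB1| + |AB3 - AB2|`.
#'
#' @param ab1,ab2,ab3 AB indices of assessment blocks 1-3, in ms.
#' @param training_order `"towards_first"` or `"away_first"`.
#' @return data frame with one row: `ab1_ms`, `ab2_ms`, `ab3_ms`,
#'   `am_towards_ms`, `am_away_ms`, `am_overall_ms`, `training_order`.
#' @examples
#' compute_am_indices(0, 10, -5, "towards_first")  # towards 10, away -15, overall 25
#' @export
compute_am_indices <- function(ab1, ab2, ab3,
                               training_order = c("towards_first", "away_first")) {
  training_order <- match.arg(training_order)
  stopifnot(is.finite(ab1), is.finite(ab2), is.finite(ab3))
  d1 <- ab2 - ab1
  d2 <- ab3 - ab2
  if (training_order == "towards_first") {
    am_towards <- d1; am_away <- d2
  } else {
    am_away <- d1; am_towards <- d2
  }
  data.frame(ab1_ms = ab1, ab2_ms = ab2, ab3_ms = ab3,
             am_towards_ms = am_towards, am_away_ms = am_away,
             am_overall_ms = abs(d1) + abs(d2),
             training_order = training_order, stringsAsFactors = FALSE)
}

#' Clean and score a cohort of dot-probe data
#'
#' Convenience wrapper: runs [clean_dotprobe()], computes the three per-block
#' AB indices and the AM indices for every retained participant.
#'
#' @param trials trial records for one or more participants.
#' @param training_orders named character vector (or data frame with columns
#'   `participant_id`, `training_order`) giving each participant's
#'   counterbalancing arm.
#' @param rules a [cleaning_rules()].
#' @return list of class `am_scores` with `indices` (one row per retained
#'   participant), `cleaning` (the [clean_dotprobe()] result).
#' @export
score_am <- function(trials, training_orders, rules = cleaning_rules()) {
  if (is.data.frame(training_orders)) {
    training_orders <- setNames(training_orders$training_order,
                                training_orders$participant_id)
  }
  cleaning <- clean_dotprobe(trials, rules)
  clean <- cleaning$trials
  assess <- clean[clean$block_type == "assessment", , drop = FALSE]
  by_id <- split(assess, as.character(assess$participant_id))
  rows <- lapply(names(by_id), function(p) {
    to <- training_orders[[p]]
    if (is.null(to) || is.na(to)) {
      stop("no training_order supplied for participant ", p, call. = FALSE)
    }
    sub <- by_id[[p]]
    ab <- vapply(sort(unique(sub$block_index)), function(b) {
      compute_ab_index(sub[sub$block_index == b, ], p, b)
    }, numeric(1))
    if (length(ab) != 3L) {
      stop("participant ", p, " has ", length(ab),
           " assessment blocks; expected 3", call. = FALSE)
    }
    cbind(data.frame(participant_id = p, stringsAsFactors = FALSE),
          compute_am_indices(ab[1], ab[2], ab[3], to))
  })
  indices <- do.call(rbind, rows)
  rownames(indices) <- NULL
  structure(list(indices = indices, cleaning = cleaning), class = "am_scores")
}

#' Cohort descriptives of the attention indices
#'
#' Mean and sample SD (n-1 denominator) of the baseline AB and the three AM
#' indices over retained participants, in the row order used for reporting.
#'
#' @param indices the `indices` data frame from [score_am()] (or any data
#'   frame with columns `ab1_ms`, `am_away_ms`, `am_towards_ms`,
#'   `am_overall_ms`).
#' @return data frame with columns `index`, `mean`, `sd`, `n`.
#' @export
cohort_indices_table <- function(indices) {
  if (is.list(indices) && !is.data.frame(indices) && !is.null(indices$indices)) {
    indices <- indices$indices
  }
  if (nrow(indices) < 2L) {
    stop("at least 2 retained participants are required for descriptives",
         call. = FALSE)
  }
  cols <- c(AB_Baseline = "ab1_ms", AM_Away = "am_away_ms",
            AM_Towards = "am_towards_ms", AM_Overall = "am_overall_ms")
  data.frame(index = names(cols),
             mean = vapply(cols, function(cl) mean(indices[[cl]]), numeric(1)),
             sd = vapply(cols, function(cl) sd(indices[[cl]]), numeric(1)),
             n = nrow(indices),
             row.names = NULL, stringsAsFactors = FALSE)
}
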