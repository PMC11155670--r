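#' Clean RIR tone-detection data
#'
#' Prepares tone-level data for the RT analysis. Per participant, in order:
#' timed responses faster than 100 ms are reclassified as anticipations;
#' anticipations and omissions are removed from the RT set (they remain
#' available for error-rate computation); the first and last tone of every
#' episode are removed; and timed RTs more than 3 SDs *above* the
#' participant's mean timed RT (one-sided rule, mean and SD computed over the
#' whole session after anticipation/omission removal) are removed. A
#' participant with fewer than 2 timed responses cannot support the SD rule;
#' it is skipped and flagged in the report.
#'
#' @param trials data frame with columns `participant_id`, `tone_index`,
#'   `episode_index`, `pain`, `response_class`, `rt_ms` (as produced by
#'   [simulate_rir_responses()]).
#' @return list of class `rir_cleaning` with `trials` (rows usable for RT
#'   analysis), `all_trials` (input after reclassification and with an
#'   `endpoint` flag, for error rates) and `report` (per-participant removal
#'   tallies and `sd_rule_skipped` flag).
#' @export
clean_rir <- function(trials) {
  need <- c("participant_id", "tone_index", "episode_index", "pain",
            "response_class", "rt_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("RIR data lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0L) stop("no RIR trials supplied", call. = FALSE)

  trials <- trials[order(trials$participant_id, trials$tone_index), ]
  reclass <- trials$response_class == "timed" & !is.na(trials$rt_ms) &
    trials$rt_ms < 100
  trials$response_class[reclass] <- "anticipation"
  trials$rt_ms[trials$response_class != "timed"] <- NA_real_

  # first/last tone of every participant x episode
  key <- interaction(trials$participant_id, trials$episode_index, drop = TRUE)
  first <- !duplicated(key)
  last <- !duplicated(key, fromLast = TRUE)
  trials$endpoint <- first | last

  ids <- unique(as.character(trials$participant_id))
  keep <- rep(FALSE, nrow(trials))
  rep_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- ids[i]
    sel <- trials$participant_id == p
    timed <- sel & trials$response_class == "timed"
    sd_skipped <- FALSE
    hi <- Inf
    if (sum(timed) >= 2L) {
      m <- mean(trials$rt_ms[timed])
      s <- sd(trials$rt_ms[timed])
      hi <- m + 3 * s
    } else {
      sd_skipped <- TRUE
      warning("participant ", p,
              " has < 2 timed RIR responses; 3-SD rule skipped", call. = FALSE)
    }
    use <- timed & !trials$endpoint & trials$rt_ms <= hi
    keep[use] <- TRUE
    rep_rows[[i]] <- data.frame(
      participant_id = p,
      n_tones = sum(sel),
      n_anticipation = sum(sel & trials$response_class == "anticipation"),
      n_omission = sum(sel & trials$response_class == "omission"),
      n_endpoint_removed = sum(timed & trials$endpoint),
      n_sd_outlier = sum(timed & !trials$endpoint & trials$rt_ms > hi),
      n_retained_rt = sum(use),
      sd_rule_skipped = sd_skipped,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rep_rows)
  report$pct_excluded <- 100 * (1 - report$n_retained_rt / report$n_tones)

  clean <- trials[keep, , drop = FALSE]
  rownames(clean) <- rownames(trials) <- NULL
  structure(list(trials = clean, all_trials = trials, report = report),
            class = "rir_cleaning")
}

#' @export
print.rir_cleaning <- function(x, ...) {
  cat(sprintf("RIR cleaning: %d of %d tones usable for RT analysis (%.2f%% excluded)\n",
              sum(x$report$n_retained_rt), sum(x$report$n_tones),
              100 * (1 - sum(x$report$n_retained_rt) / sum(x$report$n_tones))))
  invisible(x)
}

#' Pain-interference scores from cleaned RIR data
#'
#' Two difference scores per participant, pain minus no-pain episodes:
#' `delta_rt_ms`, the mean timed RT difference computed on the cleaned RT
#' set, and `delta_error_pct`, the difference in error percentage, where an
#' error is an anticipation or an omission and the denominator is the number
#' of tones presented in the condition (first/last tones of each episode
#' excluded on both sides of the ratio).
#'
#' @param cleaning a [clean_rir()] result.
#' @return data frame with one row per participant: `delta_rt_ms`,
#'   `delta_error_pct`, plus the per-condition means and error rates.
#' @export
compute_interference <- function(cleaning) {
  stopifnot(inherits(cleaning, "rir_cleaning"))
  clean <- cleaning$trials
  all_tr <- cleaning$all_trials[!cleaning$all_trials$endpoint, , drop = FALSE]
  ids <- unique(as.character(cleaning$all_trials$participant_id))
  rows <- lapply(ids, function(p) {
    cl <- clean[clean$participant_id == p, ]
    al <- all_tr[all_tr$participant_id == p, ]
    n_pain_rt <- sum(cl$pain)
    n_nopain_rt <- sum(!cl$pain)
    if (n_pain_rt == 0L || n_nopain_rt == 0L) {
      stop("participant ", p, " has no usable ",
           if (n_pain_rt == 0L) "pain" else "no-pain",
           "-episode RTs; interference undefined", call. = FALSE)
    }
    if (!any(al$pain) || !any(!al$pain)) {
      stop("participant ", p, " lacks tones in one condition", call. = FALSE)
    }
    rt_pain <- mean(cl$rt_ms[cl$pain])
    rt_nopain <- mean(cl$rt_ms[!cl$pain])
    err <- function(pain) {
      sub <- al[al$pain == pain, ]
      100 * mean(sub$response_class != "timed")
    }
    err_pain <- err(TRUE)
    err_nopain <- err(FALSE)
    data.frame(participant_id = p,
               rt_pain_ms = rt_pain, rt_nopain_ms = rt_nopain,
               delta_rt_ms = rt_pain - rt_nopain,
               error_pain_pct = err_pain, error_nopain_pct = err_nopain,
               delta_error_pct = err_pain - err_nopain,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clean and score RIR data in one step
#'
#' @param trials tone-level RIR records.
#' @return list of class `rir_scores` with `interference` (one row per
#'   participant) and `cleaning`.
#' @export
score_rir <- function(trials) {
  cleaning <- clean_rir(trials)
  structure(list(interference = compute_interference(cleaning),
                 cleaning = cleaning),
            class = "rir_scores")
}
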