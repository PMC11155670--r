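check_items <- function(items, n, lo, hi, what) {
  items <- unlist(items, use.names = FALSE)
  if (length(items) != n) {
    stop(what, " requires exactly ", n, " item responses, got ",
         length(items), call. = FALSE)
  }
  if (anyNA(items)) stop(what, ": missing item response", call. = FALSE)
  if (!is.numeric(items) || any(items < lo | items > hi)) {
    stop(what, ": item responses must lie in [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  items
}

#' Score the Pain Catastrophizing Scale (PCS)
#'
#' 13 items rated 0-4. The total is the item sum (0-52); subscales follow the
#' original instrument's mapping: rumination items 8-11, magnification items
#' 6, 7, 13, helplessness items 1-5 and 12. No imputation: any missing or
#' out-of-range item is an error.
#'
#' @param items numeric vector of the 13 responses, in item order.
#' @return named list: `pcs_total`, `pcs_rumination`, `pcs_magnification`,
#'   `pcs_helplessness`.
#' @examples
#' score_pcs(rep(4, 13))$pcs_total  # 52
#' @export
score_pcs <- function(items) {
  items <- check_items(items, 13L, 0, 4, "PCS")
  list(pcs_total = sum(items),
       pcs_rumination = sum(items[c(8, 9, 10, 11)]),
       pcs_magnification = sum(items[c(6, 7, 13)]),
       pcs_helplessness = sum(items[c(1, 2, 3, 4, 5, 12)]))
}

#' Score the DASS-21
#'
#' 21 items rated 0-3, three 7-item scales. Scores are raw 0-21 sums (not
#' doubled to the 42-item metric). The standard short-form item mapping is
#' used: depression 3, 5, 10, 13, 16, 17, 21; anxiety 2, 4, 7, 9, 15, 19,
#' 20; stress 1, 6, 8, 11, 12, 14, 18.
#'
#' @param items numeric vector of the 21 responses, in item order.
#' @return named list: `dass_depression`, `dass_anxiety`, `dass_stress`.
#' @examples
#' score_dass21(rep(3, 21))  # 21 on each scale
#' @export
score_dass21 <- function(items) {
  items <- check_items(items, 21L, 0, 3, "DASS-21")
  list(dass_depression = sum(items[c(3, 5, 10, 13, 16, 17, 21)]),
       dass_anxiety = sum(items[c(2, 4, 7, 9, 15, 19, 20)]),
       dass_stress = sum(items[c(1, 6, 8, 11, 12, 14, 18)]))
}

#' Score the Graded Chronic Pain Scale (GCPS)
#'
#' Six 0-10 items plus a disability-days count. Items 1-3 (current, worst and
#' average pain intensity) average into a 0-100 intensity score (mean x 10);
#' items 4-6 (interference with daily, social and work activities) average
#' into a 0-100 disability score. The days-disabled count passes through
#' unchanged; the categorical chronic-pain grade is not computed.
#'
#' @param items numeric vector of the 6 item responses (intensity items
#'   first).
#' @param disability_days non-negative day count.
#' @return named list: `gcps_intensity`, `gcps_disability`,
#'   `gcps_disability_days`.
#' @examples
#' score_gcps(c(5, 7, 6, 0, 0, 0), 10)$gcps_intensity  # 60
#' @export
score_gcps <- function(items, disability_days = 0) {
  items <- check_items(items, 6L, 0, 10, "GCPS")
  if (length(disability_days) != 1L || is.na(disability_days) ||
      disability_days < 0) {
    stop("GCPS: `disability_days` must be a single non-negative number",
         call. = FALSE)
  }
  list(gcps_intensity = mean(items[1:3]) * 10,
       gcps_disability = mean(items[4:6]) * 10,
       gcps_disability_days = disability_days)
}

#' Score attention to pain during the tone-detection task
#'
#' Two 0-10 items: attention paid to the heat stimuli, and ability to put the
#' heat stimulus out of mind (reverse-scored). The score is the mean of the
#' first item and the reversed second item.
#'
#' @param item_a 0-10 rating of attention paid to the pain stimuli.
#' @param item_b_raw 0-10 raw rating of the reverse-keyed item.
#' @return scalar in 0-10.
#' @examples
#' score_attention_to_pain(8, 3)  # 7.5
#' @export
score_attention_to_pain <- function(item_a, item_b_raw) {
  check_items(item_a, 1L, 0, 10, "attention-to-pain item A")
  check_items(item_b_raw, 1L, 0, 10, "attention-to-pain item B")
  (item_a + (10 - item_b_raw)) / 2
}

#' Score a table of questionnaire item responses
#'
#' Expects one row per participant with item columns named
#' `pcs_01`..`pcs_13`, `dass_01`..`dass_21` and, when present,
#' `gcps_01`..`gcps_06` + `gcps_days` and `atp_a`, `atp_b`. Instruments whose
#' columns are absent are simply skipped.
#'
#' @param items data frame of item responses with a `participant_id` column.
#' @return data frame of scale scores, one row per participant.
#' @export
score_questionnaires <- function(items) {
  stopifnot("participant_id" %in% names(items))
  grab <- function(row, prefix, n) {
    cols <- sprintf("%s_%02d", prefix, seq_len(n))
    if (!all(cols %in% names(items))) return(NULL)
    as.numeric(row[cols])
  }
  rows <- lapply(seq_len(nrow(items)), function(i) {
    row <- items[i, ]
    out <- list(participant_id = as.character(row$participant_id))
    pcs <- grab(row, "pcs", 13L)
    if (!is.null(pcs)) out <- c(out, score_pcs(pcs))
    dass <- grab(row, "dass", 21L)
    if (!is.null(dass)) out <- c(out, score_dass21(dass))
    gcps <- grab(row, "gcps", 6L)
    if (!is.null(gcps) && "gcps_days" %in% names(items)) {
      out <- c(out, score_gcps(gcps, as.numeric(row$gcps_days)))
    }
    if (all(c("atp_a", "atp_b") %in% names(items))) {
      out <- c(out, list(attention_to_pain =
                           score_attention_to_pain(as.numeric(row$atp_a),
                                                   as.numeric(row$atp_b))))
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
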