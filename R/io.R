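#' Write a simulated cohort to a directory of delimited text files
#'
#' One CSV per table (comma-separated, UTF-8, header row, `.` decimal
#' separator; RTs rounded to integer ms; missing responses as empty fields),
#' plus JSON sidecars: `truth.json` (ground-truth parameters) and
#' `config.json` (the full configuration including its seed).
#'
#' @param cohort an [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "am_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE, na = "")
    paths <<- c(paths, p)
  }
  dp <- cohort$dotprobe
  dp$rt_ms <- as.integer(round(dp$rt_ms))
  dp$true_bias_ms <- NULL
  put(dp, "dotprobe.csv")
  if (!is.null(cohort$rir)) {
    rr <- cohort$rir
    rr$rt_ms <- ifelse(is.na(rr$rt_ms), NA_integer_, as.integer(round(rr$rt_ms)))
    put(rr, "rir.csv")
  }
  put(cohort$items, "items.csv")
  put(cohort$participants, "participants.csv")
  if (!is.null(cohort$outcomes)) put(cohort$outcomes, "outcomes.csv")

  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, tj, digits = NA, dataframe = "columns")
  cj <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cohort$config), cj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tj, cj))
}

trial_schemas <- list(
  dotprobe = list(
    required = c("participant_id", "block_index", "block_type", "trial_index",
                 "congruent", "correct", "rt_ms"),
    key = c("participant_id", "block_index", "trial_index")),
  rir = list(
    required = c("participant_id", "tone_index", "episode_index", "pain",
                 "response_class", "rt_ms"),
    key = c("participant_id", "tone_index"))
)

#' Read and validate a trial table
#'
#' Reads a delimited trial table in the dialect written by [write_cohort()]
#' and validates it against the named schema: the header must contain every
#' required column, RTs must parse as numbers, logical flags as TRUE/FALSE,
#' and the trial key (participant x block x trial, or participant x tone)
#' must be unique. All row-level problems are collected and reported in one
#' error rather than at the first offence.
#'
#' @param path CSV file path.
#' @param schema `"dotprobe"` or `"rir"`.
#' @return validated data frame.
#' @export
read_trial_data <- function(path, schema = c("dotprobe", "rir")) {
  schema <- match.arg(schema)
  sc <- trial_schemas[[schema]]
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = "")
  miss <- setdiff(sc$required, names(raw))
  if (length(miss)) {
    stop("'", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  num_col <- function(col, allow_na = FALSE) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(x) & (!allow_na | !is.na(raw[[col]])))
    if (length(bad)) {
      problems <<- c(problems, sprintf(
        "column '%s': unparseable value%s at row%s %s", col,
        if (length(bad) > 1) "s" else "", if (length(bad) > 1) "s" else "",
        paste(utils::head(bad, 5), collapse = ", ")))
    }
    x
  }
  lgl_col <- function(col) {
    x <- toupper(trimws(raw[[col]]))
    out <- x == "TRUE"
    bad <- which(!x %in% c("TRUE", "FALSE"))
    if (length(bad)) {
      problems <<- c(problems, sprintf(
        "column '%s': not TRUE/FALSE at row %s", col,
        paste(utils::head(bad, 5), collapse = ", ")))
    }
    out
  }
  out <- raw
  if (schema == "dotprobe") {
    out$block_index <- num_col("block_index")
    out$trial_index <- num_col("trial_index")
    out$congruent <- lgl_col("congruent")
    out$correct <- lgl_col("correct")
    out$rt_ms <- num_col("rt_ms")
  } else {
    out$tone_index <- num_col("tone_index")
    out$episode_index <- num_col("episode_index")
    out$pain <- lgl_col("pain")
    out$rt_ms <- num_col("rt_ms", allow_na = TRUE)
    bad_cls <- which(!out$response_class %in% c("timed", "anticipation", "omission"))
    if (length(bad_cls)) {
      problems <- c(problems, sprintf(
        "column 'response_class': unknown class at row %s",
        paste(utils::head(bad_cls, 5), collapse = ", ")))
    }
  }
  key <- do.call(paste, c(out[sc$key], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup)) {
    problems <- c(problems, sprintf(
      "duplicate (%s) key at row %s", paste(sc$key, collapse = ", "),
      paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid trial table '", path, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  out
}
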