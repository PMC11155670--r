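#' Analysis plans for a study
#'
#' One plan per outcome x focal AM index, in reporting order: for each
#' outcome the control block is gender + baseline AB (study 1) or gender +
#' age + baseline AB (study 2), the focal predictor is one AM index, and the
#' Bonferroni family size is 3 (the three AM indices tested per outcome).
#'
#' @param study `"study1"` or `"study2"`.
#' @param outcomes outcome column names; defaults to the study's standard
#'   set (study 1: attention to pain, pain threshold/tolerance, RIR
#'   interference RT and error deltas; study 2: GCPS intensity and
#'   disability).
#' @return data frame of plans with list-column `controls`.
#' @export
analysis_plans <- function(study = c("study2", "study1"), outcomes = NULL) {
  study <- match.arg(study)
  if (is.null(outcomes)) {
    outcomes <- if (study == "study1") {
      c("attention_to_pain", "pain_threshold", "pain_tolerance",
        "delta_rt_ms", "delta_error_pct")
    } else {
      c("gcps_intensity", "gcps_disability")
    }
  }
  controls <- if (study == "study1") c("gender_female", "ab1_ms") else
    c("gender_female", "age", "ab1_ms")
  indices <- c("am_towards_ms", "am_away_ms", "am_overall_ms")
  plans <- expand.grid(outcome = outcomes, predictor = indices,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plans <- plans[order(match(plans$outcome, outcomes)), ]
  plans$m <- 3L
  plans$alpha <- 0.05
  plans$controls <- rep(list(controls), nrow(plans))
  rownames(plans) <- NULL
  plans
}

#' Assemble the per-participant analysis table
#'
#' Joins the AM indices, questionnaire scores, demographics and (when
#' available) RIR interference scores and numeric outcomes into one row per
#' retained participant, adding the `gender_female` indicator (female = 1)
#' used as a control variable.
#'
#' @param am an [score_am()] result.
#' @param questionnaire_scores from [score_questionnaires()].
#' @param participants demographics table (`participant_id`, `gender`,
#'   `age`, ...).
#' @param rir optional [score_rir()] result.
#' @param outcomes optional extra outcome table keyed by `participant_id`.
#' @return data frame, one row per participant retained by the AM cleaning.
#' @export
build_analysis_table <- function(am, questionnaire_scores, participants,
                                 rir = NULL, outcomes = NULL) {
  tab <- am$indices
  tab <- merge(tab, participants, by = "participant_id", sort = TRUE)
  tab$gender_female <- as.integer(tab$gender == "female")
  tab <- merge(tab, questionnaire_scores, by = "participant_id", all.x = TRUE)
  if (!is.null(rir)) {
    tab <- merge(tab, rir$interference, by = "participant_id", all.x = TRUE)
  }
  if (!is.null(outcomes)) {
    tab <- merge(tab, outcomes, by = "participant_id", all.x = TRUE)
  }
  tab[order(tab$participant_id), ]
}

#' Run the full simulate-score-analyze pipeline
#'
#' Simulates a cohort (or takes one supplied), cleans and scores the
#' dot-probe and RIR data, scores the questionnaires, runs every planned
#' hierarchical regression and the index-trait correlations, and (optionally)
#' writes the report, tables and a run manifest to `out_dir`.
#'
#' @param config a [cohort_config()]; ignored when `cohort` is given.
#' @param cohort an existing [simulate_cohort()] result.
#' @param rules a [cleaning_rules()].
#' @param out_dir optional output directory; when given, writes the cohort
#'   CSVs, `indices.csv`, `analysis_table.csv`, `report.txt`, `report.json`
#'   and `manifest.json`.
#' @return object of class `am_run`: list with `cohort`, `am`, `rir`,
#'   `scores`, `table`, `descriptives`, `correlations`, `regressions`,
#'   `config`.
#' @export
run_pipeline <- function(config = cohort_config(), cohort = NULL,
                         rules = cleaning_rules(), out_dir = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  config <- cohort$config
  study <- config$study

  am <- score_am(cohort$dotprobe, cohort$participants, rules)
  rir <- if (!is.null(cohort$rir)) score_rir(cohort$rir) else NULL
  scores <- score_questionnaires(cohort$items)
  tab <- build_analysis_table(am, scores, cohort$participants, rir,
                              cohort$outcomes)

  plans <- analysis_plans(study)
  regressions <- do.call(rbind, lapply(seq_len(nrow(plans)), function(k) {
    hierarchical_regression(tab, plans$outcome[k], plans$controls[[k]],
                            plans$predictor[k], m = plans$m[k],
                            alpha = plans$alpha[k])
  }))

  trait_cols <- intersect(c("pcs_total", "dass_anxiety", "dass_depression",
                            "dass_stress"), names(tab))
  idx <- tab[, c("ab1_ms", "am_away_ms", "am_towards_ms", "am_overall_ms")]
  names(idx) <- c("AB_Baseline", "AM_Away", "AM_Towards", "AM_Overall")
  correlations <- correlate_indices(idx, tab[, trait_cols, drop = FALSE])

  run <- structure(list(
    cohort = cohort, am = am, rir = rir, scores = scores, table = tab,
    descriptives = cohort_indices_table(am$indices),
    correlations = correlations, regressions = regressions,
    config = config
  ), class = "am_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "data"))
    write.csv(am$indices, file.path(out_dir, "indices.csv"), row.names = FALSE)
    num <- vapply(tab, is.numeric, logical(1))
    tab_out <- tab
    tab_out[num] <- lapply(tab_out[num], function(x) round(x, 4))
    write.csv(tab_out, file.path(out_dir, "analysis_table.csv"),
              row.names = FALSE)
    rep_lines <- run_report(run, file.path(out_dir, "report.json"))
    writeLines(rep_lines, file.path(out_dir, "report.txt"))
    write_manifest(run, out_dir)
  }
  run
}

#' @export
print.am_run <- function(x, ...) {
  cat(sprintf("AM pipeline run (%s): %d participants retained of %d\n",
              x$config$study, nrow(x$am$indices),
              nrow(x$cohort$participants)))
  print(x$descriptives)
  invisible(x)
}

fmt2 <- function(x) formatC(x, digits = 2, format = "f")

#' Render the cohort report
#'
#' Produces the plain-text report — indices descriptives as `mean (SD)`
#' rows, the index-trait correlation matrix with significance stars, and one
#' paragraph-style block per hierarchical regression — and, when `json_path`
#' is given, the same content as structured JSON.
#'
#' @param run an [run_pipeline()] result.
#' @param json_path optional path for the JSON report.
#' @return character vector of report lines, invisibly also written to
#'   `json_path` when requested.
#' @export
run_report <- function(run, json_path = NULL) {
  stopifnot(inherits(run, "am_run"))
  for (part in c("descriptives", "correlations", "regressions")) {
    if (is.null(run[[part]])) {
      stop("run is missing stage output: ", part, call. = FALSE)
    }
  }
  lines <- c(sprintf("AM cohort report (%s, n = %d retained)",
                     run$config$study, run$descriptives$n[1]),
             "", "Attention indices (ms):")
  lines <- c(lines, sprintf("  %-12s %s (%s)", run$descriptives$index,
                            fmt2(run$descriptives$mean),
                            fmt2(run$descriptives$sd)))
  lines <- c(lines, "", "Correlations with individual-difference measures:")
  ct <- run$correlations
  w <- pmax(nchar(colnames(ct$r)), 7L)
  pad <- function(x) paste(mapply(formatC, x, width = w), collapse = "  ")
  lines <- c(lines, sprintf("  %-12s %s", "", pad(colnames(ct$r))))
  for (i in seq_len(nrow(ct$r))) {
    lines <- c(lines, sprintf("  %-12s %s", rownames(ct$r)[i],
                              pad(paste0(fmt2(ct$r[i, ]), ct$stars[i, ]))))
  }
  lines <- c(lines, "  * p < .05, ** p < .01", "", "Hierarchical regressions:")
  rg <- run$regressions
  for (k in seq_len(nrow(rg))) {
    lines <- c(lines, sprintf(
      "  %s ~ + %s: dR2 = %s, F(%d,%d) = %s, p = %s, b* = %s, f2 = %s%s",
      rg$outcome[k], rg$predictor[k], fmt2(rg$delta_r2[k]), rg$df1[k],
      rg$df2[k], fmt2(rg$f_change[k]), fmt2(rg$p_change[k]),
      fmt2(rg$b_std[k]), fmt2(rg$f2[k]),
      if (rg$bonferroni_significant[k]) " [significant after Bonferroni]" else ""))
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      study = run$config$study,
      seed = as.integer(run$config$seed),
      n_retained = nrow(run$am$indices),
      descriptives = run$descriptives,
      correlations = list(r = ct$r, p = ct$p, n = ct$n),
      regressions = run$regressions
    ), json_path, digits = 10, dataframe = "columns", matrix = "rowmajor",
    auto_unbox = TRUE, pretty = TRUE)
  }
  lines
}

#' Write the run manifest
#'
#' Records the configuration (seed included), per-stage row counts, the
#' package version and MD5 digests of every file the run wrote, so that an
#' identical configuration can be verified to reproduce identical outputs.
#'
#' @param run an [run_pipeline()] result.
#' @param out_dir directory holding the run outputs.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(run, out_dir) {
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  digests <- as.list(md5sum(file.path(out_dir, files)))
  names(digests) <- files
  manifest <- list(
    package = "ampain",
    version = as.character(packageVersion("ampain")),
    config = unclass(run$config),
    counts = list(
      participants = nrow(run$cohort$participants),
      retained = nrow(run$am$indices),
      dotprobe_trials = nrow(run$cohort$dotprobe),
      dotprobe_clean = nrow(run$am$cleaning$trials),
      rir_tones = if (is.null(run$cohort$rir)) 0L else nrow(run$cohort$rir),
      rir_clean = if (is.null(run$rir)) 0L else nrow(run$rir$cleaning$trials)
    ),
    digests = digests
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
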