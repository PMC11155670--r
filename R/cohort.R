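#' Configuration of a simulated AM study cohort
#'
#' Bundles the population-level parameters from which [simulate_cohort()]
#' draws participants. The two presets mirror the two study designs the
#' package targets: `"study1"`, a laboratory sample of healthy adults who
#' complete the AM paradigm, a tone-detection (RIR) task under alternating
#' heat-pain episodes, the PCS and DASS-21, and attention-to-pain items, with
#' pain threshold/tolerance as numeric outcomes; and `"study2"`, an online
#' chronic-pain sample completing the AM paradigm, PCS, DASS-21 and the GCPS,
#' whose intensity/disability outcomes are linked linearly to true overall
#' malleability via `beta_intensity` / `beta_disability` (points per ms of
#' true overall AM, plus Gaussian noise with SD `outcome_noise_sd`).
#'
#' Person-level parameters are drawn from normal distributions (truncated to
#' their admissible ranges) with the means/SDs given here; training order,
#' stimulus-list order and (study 1) pain-first episode order are
#' counterbalanced deterministically across the participant index.
#'
#' @param study `"study1"` or `"study2"`.
#' @param n_participants cohort size (default 53 / 71 by study).
#' @param ... overrides of any default listed below (see Details in the
#'   package vignette); unknown names are an error.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(study = c("study2", "study1"),
                          n_participants = NULL, ...) {
  study <- match.arg(study)
  cfg <- list(
    study = study,
    n_participants = if (study == "study1") 53L else 71L,
    # ex-Gaussian RT population
    mu_mean = 450, mu_sd = 40,
    sigma_mean = 50, sigma_sd = 10,
    tau_mean = 100, tau_sd = 25,
    # attentional bias and its malleability
    ab_base_mean = 0, ab_base_sd = 15,
    malleability_mean = 1, malleability_sd = 0.5,
    shift_towards_ms = 5, shift_away_ms = -5,
    error_rate_mean = 0.05, error_rate_sd = 0.03,
    # RIR task population (study 1)
    rir_base_mean = 300, rir_base_sd = 40,
    interference_mean = 20, interference_sd = 15,
    anticipation_rate_mean = 0.02, anticipation_rate_sd = 0.01,
    omission_rate_mean = 0.02, omission_rate_sd = 0.01,
    # questionnaires (per-study means/SDs of the scale scores)
    pcs_mean = if (study == "study1") 12.45 else 18.07,
    pcs_sd = if (study == "study1") 10.73 else 13.11,
    dass_dep_mean = if (study == "study1") 8.08 else 15.75,
    dass_dep_sd = if (study == "study1") 7.34 else 11.62,
    dass_anx_mean = if (study == "study1") 7.51 else 10.14,
    dass_anx_sd = if (study == "study1") 5.57 else 8.93,
    dass_str_mean = if (study == "study1") 11.62 else 17.13,
    dass_str_sd = if (study == "study1") 7.25 else 10.64,
    atp_mean = 5, atp_sd = 2, atp_gender_effect = 1.5,
    gcps_intensity_mean = 51.36, gcps_intensity_sd = 17.51,
    gcps_disability_mean = 41.92, gcps_disability_sd = 25.38,
    disability_days_mean = 30, disability_days_sd = 25,
    # outcome linkage (study 2)
    beta_intensity = 0.5, beta_disability = 1.0, outcome_noise_sd = 20,
    # study-1 numeric pain outcomes (deg C)
    threshold_mean = 43.5, threshold_sd = 2,
    tolerance_mean = 46, tolerance_sd = 1.5,
    # demographics
    age_mean = if (study == "study1") 23.66 else 41.55,
    age_sd = if (study == "study1") 3.32 else 14.83,
    age_range = if (study == "study1") c(18, 60) else c(20, 74),
    prop_female = if (study == "study1") 29 / 53 else 43 / 71,
    # paradigm
    n_pairs_per_list = 24L,
    seed = 1L
  )
  dots <- list(...)
  if (!is.null(n_participants)) dots$n_participants <- n_participants
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop("unknown cohort_config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_participants >= 1)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config: %s, n = %d, seed = %d\n",
              x$study, x$n_participants, as.integer(x$seed)))
  invisible(x)
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

# integer allocation of `total` points over n_items items, each capped at
# item_max; preserves the total exactly (total must be <= n_items * item_max)
distribute_total <- function(total, n_items, item_max) {
  stopifnot(total >= 0, total <= n_items * item_max)
  items <- integer(n_items)
  for (k in seq_len(total)) {
    open <- which(items < item_max)
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    items[pick] <- items[pick] + 1L
  }
  items
}

# three 0-10 items whose mean is close to target_score / 10
gcps_style_items <- function(target_score, jitter_sd = 0.8) {
  pmin(pmax(round(rnorm(3, target_score / 10, jitter_sd)), 0), 10)
}

list_orders <- rbind(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L),
                     c(1L, 3L, 2L), c(2L, 1L, 3L), c(3L, 2L, 1L))

#' Simulate a complete AM study dataset
#'
#' Generates, for every participant: dot-probe trials for the full five-block
#' paradigm (training order, list order and — in study 1 — pain-first episode
#' order counterbalanced by participant index), RIR tone-detection trials
#' (study 1), questionnaire item responses whose scale scores follow the
#' configured population means/SDs, numeric outcomes, and the ground-truth
#' person-level parameters that produced them.
#'
#' In study 2 the GCPS intensity/disability targets are
#' `mean + beta * (true_AM_overall - E[true_AM_overall]) + noise`, so
#' `beta_* = 0` yields outcomes independent of malleability.
#'
#' @param config a [cohort_config()].
#' @return object of class `am_cohort`: list with `participants`, `dotprobe`,
#'   `rir` (study 1, else `NULL`), `items`, `outcomes` (study 1, else
#'   `NULL`), `truth` and `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config("study2", n_participants = 4))
#' names(coh)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  rng <- local_rng(config$seed)
  on.exit(restore_rng(rng), add = TRUE)

  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 4L * n), nrow = n)
  ids <- sprintf("P%03d", seq_len(n))
  female <- runif(n) < config$prop_female
  age <- round(rtrunc_norm(n, config$age_mean, config$age_sd,
                           config$age_range[1], config$age_range[2]))
  training_order <- ifelse(seq_len(n) %% 2L == 1L, "towards_first", "away_first")
  pain_first <- seq_len(n) %% 2L == 1L

  draw <- function(mean, sd, lo = -Inf, hi = Inf) rtrunc_norm(n, mean, sd, lo, hi)
  pars <- data.frame(
    participant_id = ids,
    mu_ms = draw(config$mu_mean, config$mu_sd, lo = 150),
    sigma_ms = draw(config$sigma_mean, config$sigma_sd, lo = 0),
    tau_ms = draw(config$tau_mean, config$tau_sd, lo = 0),
    ab_base_ms = draw(config$ab_base_mean, config$ab_base_sd),
    malleability = draw(config$malleability_mean, config$malleability_sd, lo = 0),
    error_rate = draw(config$error_rate_mean, config$error_rate_sd, 0, 0.5),
    rir_base_ms = draw(config$rir_base_mean, config$rir_base_sd, lo = 120),
    interference_ms = draw(config$interference_mean, config$interference_sd),
    anticipation_rate = draw(config$anticipation_rate_mean,
                             config$anticipation_rate_sd, 0, 0.2),
    omission_rate = draw(config$omission_rate_mean,
                         config$omission_rate_sd, 0, 0.2),
    stringsAsFactors = FALSE)
  pars$true_am_towards_ms <- pars$malleability * config$shift_towards_ms
  pars$true_am_away_ms <- pars$malleability * config$shift_away_ms
  pars$true_am_overall_ms <- abs(pars$true_am_towards_ms) +
    abs(pars$true_am_away_ms)

  # questionnaire score targets
  pcs_t <- pmin(pmax(round(rnorm(n, config$pcs_mean, config$pcs_sd)), 0), 52)
  dass_t <- cbind(
    dep = pmin(pmax(round(rnorm(n, config$dass_dep_mean, config$dass_dep_sd)), 0), 21),
    anx = pmin(pmax(round(rnorm(n, config$dass_anx_mean, config$dass_anx_sd)), 0), 21),
    str = pmin(pmax(round(rnorm(n, config$dass_str_mean, config$dass_str_sd)), 0), 21))

  mean_true_am <- config$malleability_mean *
    (abs(config$shift_towards_ms) + abs(config$shift_away_ms))
  if (config$study == "study2") {
    gcps_int_t <- pmin(pmax(
      config$gcps_intensity_mean +
        config$beta_intensity * (pars$true_am_overall_ms - mean_true_am) +
        rnorm(n, 0, config$outcome_noise_sd), 0), 100)
    gcps_dis_t <- pmin(pmax(
      config$gcps_disability_mean +
        config$beta_disability * (pars$true_am_overall_ms - mean_true_am) +
        rnorm(n, 0, config$outcome_noise_sd), 0), 100)
    days_t <- pmax(round(rnorm(n, config$disability_days_mean,
                               config$disability_days_sd)), 0)
  } else {
    atp_t <- pmin(pmax(
      config$atp_mean + config$atp_gender_effect * (female - mean(female)) +
        rnorm(n, 0, config$atp_sd), 0), 10)
    threshold <- rtrunc_norm(n, config$threshold_mean, config$threshold_sd, 38, 48)
    tolerance <- pmin(pmax(threshold + abs(rnorm(n, config$tolerance_mean -
                                                   config$threshold_mean,
                                                 config$tolerance_sd)), 38), 48)
  }

  dot_list <- vector("list", n)
  rir_list <- if (config$study == "study1") vector("list", n) else NULL
  item_list <- vector("list", n)
  for (i in seq_len(n)) {
    design <- paradigm_design(
      n_pairs_per_list = config$n_pairs_per_list,
      training_order = training_order[i],
      list_order = list_orders[(i - 1L) %% 6L + 1L, ])
    sched <- make_paradigm_schedule(design, seed = sub_seeds[i, 1])
    pp <- participant_params(
      participant_id = ids[i],
      mu_ms = pars$mu_ms[i], sigma_ms = pars$sigma_ms[i],
      tau_ms = pars$tau_ms[i],
      ab_base_ms = pars$ab_base_ms[i], malleability = pars$malleability[i],
      shift_towards_ms = config$shift_towards_ms,
      shift_away_ms = config$shift_away_ms,
      error_rate = pars$error_rate[i],
      rir_base_ms = pars$rir_base_ms[i],
      interference_ms = pars$interference_ms[i],
      anticipation_rate = pars$anticipation_rate[i],
      omission_rate = pars$omission_rate[i],
      gender = if (female[i]) "female" else "male", age = age[i])
    dot_list[[i]] <- simulate_dotprobe_rts(sched, pp, seed = sub_seeds[i, 2])

    if (config$study == "study1") {
      rsch <- make_rir_schedule(pain_first = pain_first[i],
                                seed = sub_seeds[i, 3])
      rir_list[[i]] <- simulate_rir_responses(rsch, pp, seed = sub_seeds[i, 4])
    }

    row <- c(list(participant_id = ids[i]),
             setNames(as.list(distribute_total(pcs_t[i], 13L, 4L)),
                      sprintf("pcs_%02d", 1:13)))
    dass_items <- integer(21L)
    dass_items[c(3, 5, 10, 13, 16, 17, 21)] <- distribute_total(dass_t[i, "dep"], 7L, 3L)
    dass_items[c(2, 4, 7, 9, 15, 19, 20)] <- distribute_total(dass_t[i, "anx"], 7L, 3L)
    dass_items[c(1, 6, 8, 11, 12, 14, 18)] <- distribute_total(dass_t[i, "str"], 7L, 3L)
    row <- c(row, setNames(as.list(dass_items), sprintf("dass_%02d", 1:21)))
    if (config$study == "study2") {
      gi <- gcps_style_items(gcps_int_t[i])
      gd <- gcps_style_items(gcps_dis_t[i])
      row <- c(row, setNames(as.list(c(gi, gd)), sprintf("gcps_%02d", 1:6)),
               list(gcps_days = days_t[i]))
    } else {
      a <- min(max(round(atp_t[i] + rnorm(1, 0, 0.7)), 0), 10)
      b_raw <- min(max(round(10 - (2 * atp_t[i] - a)), 0), 10)
      row <- c(row, list(atp_a = a, atp_b = b_raw))
    }
    item_list[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }

  participants <- data.frame(
    participant_id = ids,
    gender = ifelse(female, "female", "male"),
    age = age,
    training_order = training_order,
    list_order = apply(list_orders[(seq_len(n) - 1L) %% 6L + 1L, , drop = FALSE],
                       1, paste, collapse = ","),
    stringsAsFactors = FALSE)
  if (config$study == "study1") participants$pain_first <- pain_first

  truth <- pars
  if (config$study == "study2") {
    truth$gcps_intensity_target <- gcps_int_t
    truth$gcps_disability_target <- gcps_dis_t
  } else {
    truth$attention_to_pain_target <- atp_t
  }
  truth$pcs_target <- pcs_t
  truth$dass_depression_target <- dass_t[, "dep"]
  truth$dass_anxiety_target <- dass_t[, "anx"]
  truth$dass_stress_target <- dass_t[, "str"]

  outcomes <- NULL
  if (config$study == "study1") {
    outcomes <- data.frame(participant_id = ids,
                           pain_threshold = threshold,
                           pain_tolerance = tolerance,
                           stringsAsFactors = FALSE)
  }

  structure(list(
    participants = participants,
    dotprobe = do.call(rbind, dot_list),
    rir = if (config$study == "study1") do.call(rbind, rir_list) else NULL,
    items = do.call(rbind, item_list),
    outcomes = outcomes,
    truth = truth,
    config = config
  ), class = "am_cohort")
}

#' @export
print.am_cohort <- function(x, ...) {
  cat(sprintf("simulated AM cohort (%s): %d participants, %d dot-probe trials%s\n",
              x$config$study, nrow(x$participants), nrow(x$dotprobe),
              if (!is.null(x$rir)) sprintf(", %d RIR tones", nrow(x$rir)) else ""))
  invisible(x)
}
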