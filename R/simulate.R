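#' Person-level generative parameters
#'
#' Bundles the ground-truth quantities the simulator needs for one
#' participant. Reaction times follow an ex-Gaussian with parameters
#' `mu_ms`, `sigma_ms`, `tau_ms`. On the dot-probe task the participant
#' carries a true attentional bias `b` (expected incongruent minus congruent
#' RT): `b` starts at `ab_base_ms` and, after each training block, shifts by
#' `malleability * shift_towards_ms` (towards training) or
#' `malleability * shift_away_ms` (away training); shifts persist
#' cumulatively through the remaining blocks. Congruent trials are sped up by
#' `b / 2` and incongruent trials slowed by `b / 2`, so the usual AB index
#' (mean incongruent minus mean congruent RT) recovers `b`.
#'
#' On the RIR tone task, timed responses are ex-Gaussian around `rir_base_ms`
#' (same `sigma_ms`/`tau_ms`), slowed by `interference_ms` during pain
#' episodes; each tone is independently an anticipation (press within 100 ms
#' of onset) with probability `anticipation_rate` or an omission with
#' probability `omission_rate`.
#'
#' @param participant_id identifier.
#' @param mu_ms,sigma_ms,tau_ms ex-Gaussian RT parameters, in ms.
#' @param ab_base_ms true baseline attentional bias, in ms (positive = bias
#'   toward pain words).
#' @param malleability non-negative scaling of training-induced bias shifts.
#' @param shift_towards_ms,shift_away_ms signed true bias change caused by a
#'   towards / away training block (at `malleability = 1`), in ms.
#' @param error_rate probability of an incorrect probe response.
#' @param rir_base_ms baseline RIR response expectation, in ms.
#' @param interference_ms true pain-minus-no-pain RT shift on the RIR task.
#' @param anticipation_rate,omission_rate per-tone probabilities.
#' @param gender `"female"` or `"male"`.
#' @param age years.
#' @return an object of class `participant_params`.
#' @export
participant_params <- function(participant_id = "P001",
                               mu_ms = 450, sigma_ms = 50, tau_ms = 100,
                               ab_base_ms = 0, malleability = 1,
                               shift_towards_ms = 5, shift_away_ms = -5,
                               error_rate = 0.05,
                               rir_base_ms = 300, interference_ms = 20,
                               anticipation_rate = 0.02, omission_rate = 0.02,
                               gender = "female", age = 30) {
  stopifnot(mu_ms > 0, sigma_ms >= 0, tau_ms >= 0, malleability >= 0,
            error_rate >= 0, error_rate <= 1,
            anticipation_rate >= 0, anticipation_rate <= 1,
            omission_rate >= 0, omission_rate <= 1,
            anticipation_rate + omission_rate <= 1)
  gender <- match.arg(gender, c("female", "male"))
  out <- list(participant_id = participant_id,
              mu_ms = mu_ms, sigma_ms = sigma_ms, tau_ms = tau_ms,
              ab_base_ms = ab_base_ms, malleability = malleability,
              shift_towards_ms = shift_towards_ms,
              shift_away_ms = shift_away_ms,
              error_rate = error_rate,
              rir_base_ms = rir_base_ms, interference_ms = interference_ms,
              anticipation_rate = anticipation_rate,
              omission_rate = omission_rate,
              gender = gender, age = age)
  class(out) <- "participant_params"
  out
}

#' Simulate dot-probe trial records for one participant
#'
#' Walks through a schedule from [make_paradigm_schedule()] and attaches a
#' response (correct with probability `1 - error_rate`) and an ex-Gaussian RT
#' to every trial. The participant's true bias enters as a `+/- b/2` location
#' shift by congruency and is updated after each training block as described
#' in [participant_params()]. Identical `(schedule, params, seed)` give
#' byte-identical output.
#'
#' @param schedule trial schedule from [make_paradigm_schedule()].
#' @param params a [participant_params()].
#' @param seed integer seed for RTs and response correctness.
#' @return the schedule with columns `participant_id`, `correct`, `rt_ms`
#'   added, plus `true_bias_ms` (the bias in force on that trial, kept for
#'   recovery tests).
#' @examples
#' sched <- make_paradigm_schedule(paradigm_design(), seed = 1)
#' pp <- participant_params(sigma_ms = 0, tau_ms = 0, ab_base_ms = 30,
#'                          error_rate = 0)
#' tr <- simulate_dotprobe_rts(sched, pp, seed = 2)
#' with(subset(tr, block_index == 1),
#'      mean(rt_ms[!congruent]) - mean(rt_ms[congruent]))  # exactly 30
#' @export
simulate_dotprobe_rts <- function(schedule, params, seed = 1L) {
  stopifnot(inherits(params, "participant_params"))
  need <- c("block_index", "block_type", "trial_index", "congruent")
  if (!all(need %in% names(schedule))) {
    stop("`schedule` must come from make_paradigm_schedule()", call. = FALSE)
  }

  # bias trajectory: ab_base in blocks 1-2, shifted after each training block
  bias <- rep(params$ab_base_ms, 5L)
  shift_of <- c(towards = params$malleability * params$shift_towards_ms,
                away = params$malleability * params$shift_away_ms)
  for (b in c(2L, 4L)) {
    dir <- schedule$training_direction[match(b, schedule$block_index)]
    if (!is.na(dir) && b < 5L) {
      bias[(b + 1L):5L] <- bias[(b + 1L):5L] + shift_of[[dir]]
    }
  }

  n <- nrow(schedule)
  rng <- local_rng(seed)
  rt <- rexgauss(n, params$mu_ms, params$sigma_ms, params$tau_ms)
  correct <- runif(n) >= params$error_rate
  restore_rng(rng)

  b_trial <- bias[schedule$block_index]
  rt <- rt + ifelse(schedule$congruent, -b_trial / 2, b_trial / 2)

  out <- schedule
  out$participant_id <- params$participant_id
  out$correct <- correct
  out$rt_ms <- rt
  out$true_bias_ms <- b_trial
  out[, c("participant_id", setdiff(names(out), "participant_id"))]
}

#' Build a random-interval-repetition (RIR) tone schedule
#'
#' Tones are separated by inter-onset intervals drawn as equal counts of the
#' two stated values in random order, starting from an onset at 0 ms, so the
#' tone count is the interval count plus one. The session is tiled by
#' alternating fixed-length pain / no-pain episodes; each tone is tagged with
#' the episode containing it (a tone falling exactly on the final boundary is
#' assigned to the last episode). The default configuration — 240 s, 900/1500
#' ms intervals, 24-s episodes — yields 100 + 100 intervals, 201 tones and 10
#' alternating episodes.
#'
#' @param total_ms session length; must equal an integer number of episodes
#'   and be tileable by equal counts of the two interval values.
#' @param interval_values_ms the two inter-onset intervals, in ms.
#' @param episode_ms episode length, in ms.
#' @param pain_first does the first episode carry pain?
#' @param seed integer seed for the interval order.
#' @return an object of class `rir_schedule`: a list with `tones` (data frame
#'   `tone_index`, `onset_ms`, `episode_index`, `pain`), `intervals_ms`,
#'   `episodes` (data frame of windows) and the configuration.
#' @examples
#' sch <- make_rir_schedule(seed = 1)
#' nrow(sch$tones)       # 201
#' table(sch$intervals_ms)
#' @export
make_rir_schedule <- function(total_ms = 240000, interval_values_ms = c(900, 1500),
                              episode_ms = 24000, pain_first = TRUE, seed = 1L) {
  stopifnot(length(interval_values_ms) == 2L, all(interval_values_ms > 0),
            total_ms > 0, episode_ms > 0)
  if (total_ms %% episode_ms != 0) {
    stop("`total_ms` must be an integer multiple of `episode_ms`", call. = FALSE)
  }
  pair_sum <- sum(interval_values_ms)
  if (total_ms %% pair_sum != 0) {
    stop("`total_ms` cannot be tiled by equal counts of the interval values",
         call. = FALSE)
  }
  n_each <- total_ms %/% pair_sum
  intervals <- rep(interval_values_ms, each = n_each)
  rng <- local_rng(seed)
  intervals <- intervals[sample.int(length(intervals))]
  restore_rng(rng)

  onsets <- c(0, cumsum(intervals))
  n_ep <- total_ms %/% episode_ms
  episode <- pmin(onsets %/% episode_ms + 1L, n_ep)
  pain_ep <- if (pain_first) seq_len(n_ep) %% 2L == 1L else seq_len(n_ep) %% 2L == 0L

  out <- list(
    tones = data.frame(tone_index = seq_along(onsets),
                       onset_ms = onsets,
                       episode_index = as.integer(episode),
                       pain = pain_ep[episode]),
    intervals_ms = intervals,
    episodes = data.frame(episode_index = seq_len(n_ep),
                          start_ms = (seq_len(n_ep) - 1L) * episode_ms,
                          end_ms = seq_len(n_ep) * episode_ms,
                          pain = pain_ep),
    total_ms = total_ms, episode_ms = episode_ms,
    interval_values_ms = interval_values_ms, pain_first = pain_first
  )
  class(out) <- "rir_schedule"
  out
}

#' @export
print.rir_schedule <- function(x, ...) {
  cat(sprintf("RIR schedule: %d tones over %g s, %d alternating %g-s episodes (%s first)\n",
              nrow(x$tones), x$total_ms / 1000, nrow(x$episodes),
              x$episode_ms / 1000, if (x$pain_first) "pain" else "no-pain"))
  invisible(x)
}

#' Simulate tone-detection responses on an RIR schedule
#'
#' Every tone receives exactly one of three response classes: `"timed"` (a
#' press with an ex-Gaussian RT around `rir_base_ms`, slowed by
#' `interference_ms` in pain episodes), `"anticipation"` (a press within
#' 0-99 ms of onset, probability `anticipation_rate`) or `"omission"` (no
#' press, probability `omission_rate`). A timed draw landing below 100 ms is
#' reclassified as an anticipation so classification stays consistent with
#' the press-latency definition.
#'
#' @param schedule an [make_rir_schedule()] object.
#' @param params a [participant_params()].
#' @param seed integer seed.
#' @return data frame with one row per tone: `participant_id`, `tone_index`,
#'   `episode_index`, `pain`, `response_class`, `rt_ms` (`NA` unless timed).
#' @export
simulate_rir_responses <- function(schedule, params, seed = 1L) {
  stopifnot(inherits(schedule, "rir_schedule"),
            inherits(params, "participant_params"))
  tones <- schedule$tones
  n <- nrow(tones)

  rng <- local_rng(seed)
  u <- runif(n)
  cls <- ifelse(u < params$anticipation_rate, "anticipation",
                ifelse(u < params$anticipation_rate + params$omission_rate,
                       "omission", "timed"))
  rt <- rexgauss(n, params$rir_base_ms, params$sigma_ms, params$tau_ms) +
    ifelse(tones$pain, params$interference_ms, 0)
  restore_rng(rng)

  cls[cls == "timed" & rt < 100] <- "anticipation"
  rt[cls != "timed"] <- NA_real_

  data.frame(participant_id = params$participant_id,
             tone_index = tones$tone_index,
             episode_index = tones$episode_index,
             pain = tones$pain,
             response_class = cls,
             rt_ms = rt,
             stringsAsFactors = FALSE)
}
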