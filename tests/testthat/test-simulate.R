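test_that("noise-free dot-probe RTs recover the configured bias exactly", {
  sched <- make_paradigm_schedule(paradigm_design(), seed = 1)
  pp <- participant_params(sigma_ms = 0, tau_ms = 0, ab_base_ms = 30,
                           error_rate = 0)
  tr <- simulate_dotprobe_rts(sched, pp, seed = 2)
  b1 <- tr[tr$block_index == 1, ]
  # every incongruent RT exceeds every congruent RT by exactly 30
  expect_equal(unique(b1$rt_ms[!b1$congruent]) - unique(b1$rt_ms[b1$congruent]),
               30)
  expect_true(all(tr$correct))
})

test_that("training shifts the bias cumulatively, scaled by malleability", {
  sched <- make_paradigm_schedule(
    paradigm_design(training_order = "towards_first"), seed = 3)
  pp <- participant_params(sigma_ms = 0, tau_ms = 0, ab_base_ms = 30,
                           malleability = 0.5, shift_towards_ms = 40,
                           shift_away_ms = -60, error_rate = 0)
  tr <- simulate_dotprobe_rts(sched, pp, seed = 4)
  ab_of <- function(b) {
    s <- tr[tr$block_index == b, ]
    mean(s$rt_ms[!s$congruent]) - mean(s$rt_ms[s$congruent])
  }
  expect_equal(ab_of(1), 30)
  expect_equal(ab_of(3), 30 + 0.5 * 40)       # after towards training
  expect_equal(ab_of(5), 30 + 0.5 * 40 - 0.5 * 60)  # persists, then away
})

test_that("large-sample AB estimates match the configured truth within Monte-Carlo error", {
  n <- 100
  abs3 <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    sched <- make_paradigm_schedule(
      paradigm_design(training_order = "towards_first"), seed = 100 + i)
    pp <- participant_params(sigma_ms = 30, tau_ms = 0, ab_base_ms = 30,
                             malleability = 1, shift_towards_ms = 40,
                             shift_away_ms = -40, error_rate = 0)
    tr <- simulate_dotprobe_rts(sched, pp, seed = 200 + i)
    for (b in c(1, 3, 5)) {
      s <- tr[tr$block_index == b, ]
      abs3[i, (b + 1) / 2] <- mean(s$rt_ms[!s$congruent]) -
        mean(s$rt_ms[s$congruent])
    }
  }
  se <- apply(abs3, 2, sd) / sqrt(n)
  expect_lt(abs(mean(abs3[, 1]) - 30), 3 * se[1])
  expect_lt(abs(mean(abs3[, 2]) - 70), 3 * se[2])   # 30 + 40 post-towards
  expect_lt(abs(mean(abs3[, 3]) - 30), 3 * se[3])   # 70 - 40 post-away
})

test_that("dot-probe simulation is deterministic given (schedule, params, seed)", {
  sched <- make_paradigm_schedule(paradigm_design(), seed = 11)
  pp <- participant_params()
  expect_identical(simulate_dotprobe_rts(sched, pp, seed = 12),
                   simulate_dotprobe_rts(sched, pp, seed = 12))
})

test_that("the default RIR schedule has 201 tones tiling 240 s in 10 episodes", {
  sch <- make_rir_schedule(seed = 1)
  expect_equal(nrow(sch$tones), 201L)
  expect_equal(as.integer(table(sch$intervals_ms)), c(100L, 100L))
  expect_equal(sum(sch$intervals_ms), 240000)
  expect_equal(sch$tones$onset_ms[201], 240000)         # onsets cumulative from 0
  expect_equal(sch$tones$onset_ms[1], 0)
  expect_equal(nrow(sch$episodes), 10L)
  expect_equal(sch$episodes$pain, rep(c(TRUE, FALSE), 5))
  expect_equal(sch$episodes$end_ms - sch$episodes$start_ms, rep(24000, 10))
  # pain_first = FALSE flips every episode label
  sch2 <- make_rir_schedule(pain_first = FALSE, seed = 1)
  expect_equal(sch2$episodes$pain, rep(c(FALSE, TRUE), 5))
})

test_that("infeasible RIR configurations are rejected", {
  expect_error(make_rir_schedule(total_ms = 240001), "multiple of")
  expect_error(make_rir_schedule(total_ms = 231000, episode_ms = 21000),
               "equal counts")
})

test_that("RIR responses honor the configured rates and interference", {
  sch <- make_rir_schedule(seed = 2)
  # no anticipations/omissions -> all tones timed
  pp0 <- participant_params(anticipation_rate = 0, omission_rate = 0)
  r0 <- simulate_rir_responses(sch, pp0, seed = 3)
  expect_true(all(r0$response_class == "timed"))
  expect_true(all(!is.na(r0$rt_ms)))
  # noise off -> pain RTs exceed no-pain RTs by exactly interference_ms
  ppn <- participant_params(sigma_ms = 0, tau_ms = 0, interference_ms = 50,
                            anticipation_rate = 0, omission_rate = 0)
  rn <- simulate_rir_responses(sch, ppn, seed = 4)
  expect_equal(unique(rn$rt_ms[rn$pain]) - unique(rn$rt_ms[!rn$pain]), 50)
  # with noise, the mean difference converges on the configured truth
  big <- make_rir_schedule(total_ms = 24000 * 500, seed = 5)  # 10,000+ tones
  rb <- simulate_rir_responses(big, participant_params(interference_ms = 50),
                               seed = 6)
  d <- mean(rb$rt_ms[rb$pain], na.rm = TRUE) -
    mean(rb$rt_ms[!rb$pain], na.rm = TRUE)
  se <- sqrt(var(rb$rt_ms[rb$pain], na.rm = TRUE) / sum(rb$pain) +
               var(rb$rt_ms[!rb$pain], na.rm = TRUE) / sum(!rb$pain))
  expect_lt(abs(d - 50), 4 * se)
})

test_that("simulated cohorts are reproducible and counterbalanced", {
  cfg <- cohort_config("study1", n_participants = 6, seed = 21)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(a$participants$training_order,
               rep(c("towards_first", "away_first"), 3))
  expect_equal(a$participants$pain_first, rep(c(TRUE, FALSE), 3))
  expect_equal(nrow(a$dotprobe), 6 * 864)
  expect_equal(nrow(a$rir), 6 * 201)
  # questionnaire items reproduce their target scale totals
  sc <- score_questionnaires(a$items)
  expect_equal(sc$pcs_total, a$truth$pcs_target)
  expect_equal(sc$dass_anxiety, a$truth$dass_anxiety_target)
})

test_that("zero RT noise and zero shifts give AM_Overall of exactly 0", {
  cfg <- cohort_config("study2", n_participants = 4, seed = 31,
                       mu_sd = 0, sigma_mean = 0, sigma_sd = 0,
                       tau_mean = 0, tau_sd = 0,
                       shift_towards_ms = 0, shift_away_ms = 0,
                       error_rate_mean = 0, error_rate_sd = 0)
  coh <- simulate_cohort(cfg)
  am <- score_am(coh$dotprobe, coh$participants)
  expect_equal(am$indices$am_overall_ms, rep(0, 4))
  expect_equal(am$indices$ab1_ms, coh$truth$ab_base_ms)
})

test_that("a null outcome link leaves disability uncorrelated with malleability", {
  cfg <- cohort_config("study2", n_participants = 150, seed = 41,
                       beta_disability = 0, beta_intensity = 0)
  coh <- simulate_cohort(cfg)
  sc <- score_questionnaires(coh$items)
  r <- cor(coh$truth$true_am_overall_ms, sc$gcps_disability)
  expect_lt(abs(r), 3 / sqrt(150))  # null correlation, 3 SE band
})

test_that("mean recovered directional AM indices match the configured shifts", {
  # 200 participants, fixed malleability 1, +/-40 ms shifts; AB recovered by
  # the raw cell-mean contrast so only the generator is under test here
  cfg <- cohort_config("study2", n_participants = 200, seed = 51,
                       shift_towards_ms = 40, shift_away_ms = -40,
                       malleability_mean = 1, malleability_sd = 0)
  coh <- simulate_cohort(cfg)
  dp <- coh$dotprobe[coh$dotprobe$block_type == "assessment" &
                       coh$dotprobe$correct, ]
  ab <- aggregate(rt_ms ~ participant_id + block_index + congruent, dp, mean)
  ab <- reshape(ab, idvar = c("participant_id", "block_index"),
                timevar = "congruent", direction = "wide")
  ab$ab_ms <- ab$rt_ms.FALSE - ab$rt_ms.TRUE
  wide <- reshape(ab[, c("participant_id", "block_index", "ab_ms")],
                  idvar = "participant_id", timevar = "block_index",
                  direction = "wide")
  wide <- merge(wide, coh$participants[, c("participant_id", "training_order")])
  idx <- do.call(rbind, lapply(seq_len(nrow(wide)), function(i) {
    compute_am_indices(wide$ab_ms.1[i], wide$ab_ms.3[i], wide$ab_ms.5[i],
                       wide$training_order[i])
  }))
  se_t <- sd(idx$am_towards_ms) / sqrt(nrow(idx))
  se_a <- sd(idx$am_away_ms) / sqrt(nrow(idx))
  expect_lt(abs(mean(idx$am_towards_ms) - 40), 3 * se_t)
  expect_lt(abs(mean(idx$am_away_ms) - (-40)), 3 * se_a)
})
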