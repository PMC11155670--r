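# Independent brute-force oracles, written straight from the scoring
# definitions with plain loops; deliberately share no code with R/.

# clean + score one participant's trials the slow way; returns the six
# index values or NULL when the participant would be excluded
oracle_indices <- function(trials, training_order,
                           rt_min = 200, rt_max = 2000, k = 2.5,
                           acc_thresh = 0.75) {
  if (mean(trials$correct) < acc_thresh) return(NULL)
  ab <- numeric(0)
  for (b in sort(unique(trials$block_index[trials$block_type == "assessment"]))) {
    keep <- c()
    for (i in seq_len(nrow(trials))) {
      r <- trials[i, ]
      if (r$block_index != b || r$block_type != "assessment") next
      if (!r$correct) next
      if (r$rt_ms < rt_min || r$rt_ms > rt_max) next
      keep <- c(keep, i)
    }
    rt <- trials$rt_ms[keep]
    med <- median(rt)
    madu <- median(abs(rt - med))
    if (madu > 0) {
      keep <- keep[abs(rt - med) <= k * madu]
      rt <- trials$rt_ms[keep]
    }
    con <- trials$congruent[keep]
    ab <- c(ab, sum(rt[!con]) / sum(!con) - sum(rt[con]) / sum(con))
  }
  d1 <- ab[2] - ab[1]
  d2 <- ab[3] - ab[2]
  if (training_order == "towards_first") {
    tow <- d1; awa <- d2
  } else {
    awa <- d1; tow <- d2
  }
  c(ab1 = ab[1], ab2 = ab[2], ab3 = ab[3],
    am_towards = tow, am_away = awa, am_overall = abs(d1) + abs(d2))
}

# random small single-participant dot-probe dataset (3 assessment blocks
# plus a couple of training trials so accuracy covers the whole paradigm)
random_small_trials <- function(n_per_block = 12) {
  blocks <- lapply(1:5, function(b) {
    type <- if (b %% 2 == 1) "assessment" else "training"
    n <- if (type == "assessment") n_per_block else 6
    data.frame(participant_id = "P1", block_index = b, block_type = type,
               trial_index = seq_len(n),
               congruent = if (type == "assessment")
                 sample(rep(c(TRUE, FALSE), n / 2)) else rep(b == 2, n),
               correct = runif(n) > 0.1,
               rt_ms = round(rexgauss(n, 450, 60, 80)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}

# minimal valid trial frame for targeted cleaning tests
make_trials <- function(rt, congruent = rep(c(TRUE, FALSE), length.out = length(rt)),
                        correct = TRUE, block_index = 1,
                        block_type = "assessment", id = "P1") {
  data.frame(participant_id = id, block_index = block_index,
             block_type = block_type, trial_index = seq_along(rt),
             congruent = congruent, correct = correct, rt_ms = rt,
             stringsAsFactors = FALSE)
}

# five-block frame for one participant with controllable accuracy;
# incorrect trials spread evenly so no single block is emptied
five_block_trials <- function(id = "P1", accuracy = 1, rt = 500) {
  out <- do.call(rbind, lapply(1:5, function(b) {
    type <- if (b %% 2 == 1) "assessment" else "training"
    n <- if (type == "assessment") 8 else 12
    make_trials(rep(rt, n), congruent = rep(c(TRUE, FALSE), n / 2),
                block_index = b, block_type = type, id = id)
  }))
  n <- nrow(out)
  n_bad <- n - round(accuracy * n)
  out$correct <- TRUE
  if (n_bad > 0) {
    out$correct[round(seq(1, n, length.out = n_bad))] <- FALSE
  }
  out
}

expect_same_df <- function(a, b) {
  expect_identical(nrow(a), nrow(b))
  expect_identical(names(a), names(b))
  for (cl in names(a)) expect_equal(a[[cl]], b[[cl]])
}
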