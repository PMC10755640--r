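test_that("learning curve: ideal tracker 1.0, alternator near 0.5, WSLS near 0.9", {
  s <- run_session(agent_ideal(), task_preset("training_0_100"), seed = 1)
  s$day <- 1L
  lc <- learning_curve(s)
  expect_identical(lc$p_high, 1)

  s2 <- run_session(agent_alternator(), task_preset("training_0_100"), seed = 2)
  s2$day <- 1L
  expect_lt(abs(learning_curve(s2)$p_high - 0.5), 0.05)

  # WSLS settles into 10-trial blocks with a single error each: 0.9 per block
  s3 <- run_session(agent_wsls(), task_preset("training_0_100"), seed = 3)
  s3$day <- 1L
  expect_lt(abs(learning_curve(s3)$p_high - 0.9), 0.02)
})

test_that("a day with zero valid-choice trials yields NA, not zero", {
  t <- make_trials(choice = rep("none", 5), high_side = rep("left", 5),
                   rewarded = rep(FALSE, 5))
  t$day <- 1L
  lc <- learning_curve(t)
  expect_true(is.na(lc$p_high))
  expect_identical(lc$n_trials, 0L)
})

test_that("days are derived from session order when no day column exists", {
  t1 <- make_trials(choice = c("left", "left"), high_side = c("left", "left"),
                    rewarded = c(TRUE, TRUE), session_id = "a")
  t2 <- make_trials(choice = c("right", "right"), high_side = c("left", "left"),
                    rewarded = c(FALSE, FALSE), session_id = "b")
  lc <- learning_curve(dplyr::bind_rows(t1, t2))
  expect_identical(lc$day, c(1L, 2L))
  expect_identical(lc$p_high, c(1, 0))
})

test_that("WSLS reversal curve in 0/100: 0 at trial 1, then 1.0", {
  s <- run_session(agent_wsls(), task_preset("training_0_100"), seed = 4)
  rc <- reversal_aligned(s, n_after = 5)
  expect_identical(rc$p_new_high[1], 0)
  expect_true(all(rc$p_new_high[2:5] == 1))
})

test_that("uniform chooser gives a flat reversal curve near 0.5", {
  cfg <- task_preset("full_15_60", max_trials = 8000L)
  s <- run_session(agent_biased_random(0.5), cfg, seed = 5)
  rc <- reversal_aligned(s, n_after = 10)
  n_blocks <- min(rc$n)
  expect_lt(abs(mean(rc$p_new_high) - 0.5), 3 * sqrt(0.25 / (10 * n_blocks)))
})

test_that("hand-built reversal fixture: exclusions for none and short blocks", {
  # two sessions; reversal blocks of unequal length with a no-response trial
  s1 <- make_trials(
    choice     = c("left", "left", "right", "right", "right", "right"),
    high_side  = c("left", "left", "right", "right", "right", "right"),
    rewarded   = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    block_index = c(0, 0, 1, 1, 1, 1),
    session_id = "a")
  s2 <- make_trials(
    choice     = c("right", "right", "none", "left"),
    high_side  = c("right", "right", "left", "left"),
    rewarded   = c(TRUE, TRUE, FALSE, TRUE),
    block_index = c(0, 0, 1, 1),
    session_id = "b")
  rc <- reversal_aligned(dplyr::bind_rows(s1, s2), n_after = 4,
                         pool = "blocks")
  # position 1: block a1 correct; block b1 trial is 'none' -> excluded
  expect_identical(rc$p_new_high[rc$trials_since_reversal == 1], 1)
  expect_identical(rc$n[rc$trials_since_reversal == 1], 1L)
  # position 2: both blocks contribute, both correct
  expect_identical(rc$p_new_high[rc$trials_since_reversal == 2], 1)
  expect_identical(rc$n[rc$trials_since_reversal == 2], 2L)
  # positions 3-4: only block a1 is long enough
  expect_identical(rc$n[rc$trials_since_reversal %in% 3:4], c(1L, 1L))
})

test_that("no reversals means an empty curve", {
  t <- make_trials(choice = rep("left", 10), high_side = rep("left", 10),
                   rewarded = rep(TRUE, 10))
  rc <- reversal_aligned(t)
  expect_identical(nrow(rc), 0L)
})

test_that("win-stay/lose-switch fractions on hand-enumerated transitions", {
  # choices L,L,R,R with rewards 1,1,0,1: transitions are
  # (L->L | win), (L->R | win), (R->R | lose) -> win_stay 1/2, lose_switch 0
  t <- make_trials(choice = c("left", "left", "right", "right"),
                   high_side = rep("left", 4),
                   rewarded = c(TRUE, TRUE, FALSE, TRUE))
  w <- wsls_fractions(t, by = NULL)
  expect_identical(w$win_stay, 0.5)
  expect_identical(w$lose_switch, 0)
  expect_identical(w$n_win_transitions, 2L)
  expect_identical(w$n_lose_transitions, 1L)
})

test_that("perseverator: win_stay 1, lose_switch 0; empty denominators give NA", {
  t <- make_trials(choice = rep("left", 10), high_side = rep("left", 10),
                   rewarded = rep(c(TRUE, FALSE), 5))
  w <- wsls_fractions(t, by = NULL)
  expect_identical(w$win_stay, 1)
  expect_identical(w$lose_switch, 0)

  all_wins <- make_trials(choice = rep("left", 4), high_side = rep("left", 4),
                          rewarded = rep(TRUE, 4))
  w2 <- wsls_fractions(all_wins, by = NULL)
  expect_true(is.na(w2$lose_switch))
  expect_identical(w2$n_lose_transitions, 0L)
})

test_that("conditional ITI on a hand-listed fixture", {
  # ITIs assigned to the previous trial's outcome:
  # prev rewarded -> {1, 2, 3}; prev unrewarded -> {4, 6}
  t <- make_trials(
    choice    = rep("left", 6),
    high_side = rep("left", 6),
    rewarded  = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    iti_s     = c(NA, 1, 2, 3, 4, 6))
  ci <- conditional_iti(t, by = NULL)
  expect_identical(ci$median_rewarded_s, 2)
  expect_identical(ci$q1_rewarded, 1.5)
  expect_identical(ci$q3_rewarded, 2.5)
  expect_identical(ci$median_unrewarded_s, 5)
  expect_identical(ci$n_rewarded, 3L)
  expect_identical(ci$n_unrewarded, 2L)
  expect_true(ci$q1_rewarded <= ci$median_rewarded_s &&
                ci$median_rewarded_s <= ci$q3_rewarded)
})

test_that("generator medians are recovered from 10^4 simulated trials", {
  cfg <- task_preset("full_15_60", max_trials = 10000L)
  s <- run_session(agent_biased_random(0.5), cfg, seed = 6,
                   latency = latency_model(1.8, 1.1, dispersion = 0.3))
  ci <- conditional_iti(s, by = NULL)
  expect_lt(abs(ci$median_rewarded_s - 1.8) / 1.8, 0.02)
  expect_lt(abs(ci$median_unrewarded_s - 1.1) / 1.1, 0.02)
})

test_that("moving average: constant, alternation, and a hand-computed trace", {
  const <- make_trials(choice = rep("left", 15), high_side = rep("left", 15),
                       rewarded = rep(TRUE, 15))
  expect_true(all(moving_average_choice(const)$ma_left == 1))

  alt <- make_trials(choice = rep(c("left", "right"), 10),
                     high_side = rep("left", 20), rewarded = rep(TRUE, 20))
  ma <- moving_average_choice(alt, window = 10)$ma_left
  expect_true(all(ma[10:20] == 0.5))

  # window 3, choices L L R L R R L L L R L R; trailing means done by hand
  t <- make_trials(
    choice = c("left", "left", "right", "left", "right", "right",
               "left", "left", "left", "right", "left", "right"),
    high_side = rep("left", 12), rewarded = rep(TRUE, 12))
  ma3 <- moving_average_choice(t, window = 3)$ma_left
  expect_equal(ma3, c(1, 1, 2/3, 2/3, 1/3, 1/3, 1/3, 2/3, 1, 2/3, 2/3, 1/3))

  # a window of only no-response trials is NA
  t2 <- make_trials(choice = c("none", "left"), high_side = rep("left", 2),
                    rewarded = c(FALSE, TRUE))
  ma2 <- moving_average_choice(t2, window = 1)$ma_left
  expect_true(is.na(ma2[1]) && ma2[2] == 1)
})

test_that("contingency ratio matches the programmed probabilities", {
  expect_equal(contingency_ratio(60, 15), 0.8)
  expect_equal(contingency_ratio(15, 60), 0.2)
  expect_equal(contingency_ratio(30, 30), 0.5)
  expect_error(contingency_ratio(0, 0), "positive")
  expect_error(contingency_ratio(-1, 2), "nonnegative")
})

test_that("metrics agree with brute-force recounts on random sessions", {
  for (seed in 1:100) {
    s <- random_session(seed)
    w <- wsls_fractions(s, by = NULL)
    o <- brute_wsls(s)
    expect_equal(w$win_stay, o$win_stay)
    expect_equal(w$lose_switch, o$lose_switch)
    expect_identical(w$n_win_transitions, as.integer(o$n_win))
    expect_identical(w$n_lose_transitions, as.integer(o$n_lose))

    rc <- reversal_aligned(s, n_after = 8, pool = "blocks")
    ob <- brute_reversal(s, n_after = 8, pool = "blocks")
    expect_equal(rc$p_new_high, ob$p)
    expect_identical(rc$n, as.integer(ob$n))

    ci <- conditional_iti(s, by = NULL)
    oi <- brute_iti(s)
    expect_equal(ci$median_rewarded_s, oi$median_rewarded)
    expect_equal(ci$q1_rewarded, oi$q1_rewarded)
    expect_equal(ci$q3_rewarded, oi$q3_rewarded)
    expect_equal(ci$median_unrewarded_s, oi$median_unrewarded)
  }
})

test_that("subject-pooled reversal curve matches its brute-force recount", {
  trials <- dplyr::bind_rows(lapply(101:110, random_session))
  rc <- reversal_aligned(trials, n_after = 6, pool = "subject")
  ob <- brute_reversal(trials, n_after = 6, pool = "subject")
  expect_equal(rc$p_new_high, ob$p)
  expect_identical(rc$n, as.integer(ob$n))
})

test_that("all metrics are invariant to joint left/right relabeling", {
  flip <- function(x) c(left = "right", right = "left", none = "none")[x]
  for (seed in c(11, 47, 83)) {
    s <- random_session(seed)
    sf <- s
    sf$choice <- unname(flip(s$choice))
    sf$high_side <- unname(flip(s$high_side))

    expect_equal(wsls_fractions(s, by = NULL), wsls_fractions(sf, by = NULL))
    expect_equal(reversal_aligned(s, 8), reversal_aligned(sf, 8))
    s$day <- sf$day <- 1L
    expect_equal(learning_curve(s), learning_curve(sf))
    expect_equal(conditional_iti(s, by = NULL), conditional_iti(sf, by = NULL))
    # the left-choice trace mirrors
    ma <- moving_average_choice(s)$ma_left
    maf <- moving_average_choice(sf)$ma_left
    ok <- !is.na(ma)
    expect_equal(ma[ok], 1 - maf[ok])
  }
})
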