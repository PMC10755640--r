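test_that("baiting draws set flags with the port probability and never clear them", {
  set.seed(1)
  st <- sample_baiting(new_port_state(), 1, 0)
  expect_true(st[["left"]])
  expect_false(st[["right"]])

  st <- c(left = TRUE, right = FALSE)
  for (i in 1:50) {
    st2 <- sample_baiting(st, 0, 0)
    expect_true(st2[["left"]])  # assigned reward persists until collected
    expect_false(st2[["right"]])
  }
  # persistence also under nonzero probabilities
  st <- c(left = TRUE, right = TRUE)
  for (i in 1:50) {
    st <- sample_baiting(st, 0.3, 0.7)
    expect_true(all(st))
  }
  expect_error(sample_baiting(new_port_state(), -0.1, 0.5), "\\[0, 1\\]")
  expect_error(sample_baiting(new_port_state(), 0.5, 1.2), "\\[0, 1\\]")
})

test_that("first-visit reward probability after k skipped draws is 1-(1-p)^k", {
  # small-n check through the scalar engine primitives
  set.seed(42)
  n <- 4000; k <- 5; p <- 0.15
  hits <- logical(n)
  for (i in seq_len(n)) {
    st <- new_port_state()
    for (j in seq_len(k)) st <- sample_baiting(st, p, 0)
    hits[i] <- resolve_choice(st, "left")$rewarded
  }
  expected <- 1 - (1 - p)^k
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(hits) - expected), 3 * se)
})

test_that("resolving a choice collects only the chosen port's bait", {
  r <- resolve_choice(c(left = TRUE, right = FALSE), "left")
  expect_true(r$rewarded)
  expect_false(r$state[["left"]])

  r <- resolve_choice(c(left = FALSE, right = FALSE), "left")
  expect_false(r$rewarded)
  expect_equal(unname(r$state), c(FALSE, FALSE))

  # the unchosen port keeps its uncollected reward
  r <- resolve_choice(c(left = FALSE, right = TRUE), "left")
  expect_false(r$rewarded)
  expect_true(r$state[["right"]])

  expect_error(resolve_choice(new_port_state(), "up"), "left")
})

test_that("reversal rule: performance criterion within the current block only", {
  cfg <- task_preset("training_0_100")
  blk <- function(correct) {
    data.frame(choice = ifelse(correct, "left", "right"),
               high_side = "left")
  }
  expect_true(check_reversal(blk(rep(TRUE, 10)), cfg))     # 10/10 >= 9
  expect_true(check_reversal(blk(c(FALSE, rep(TRUE, 9))), cfg))  # exactly 9/10
  expect_false(check_reversal(blk(c(rep(FALSE, 2), rep(TRUE, 8))), cfg))  # 8/10
  # window cannot reach into the previous block: 9 correct but block too short
  expect_false(check_reversal(blk(rep(TRUE, 9)), cfg))
  # no-response trials count as incorrect
  b <- blk(rep(TRUE, 10)); b$choice[1:2] <- "none"
  expect_false(check_reversal(b, cfg))
})

test_that("reversal rule: fixed cap fires exactly at the cap", {
  cfg <- task_preset("full_15_60")
  blk <- function(n) data.frame(choice = rep("left", n), high_side = "right")
  expect_false(check_reversal(blk(79), cfg))
  expect_true(check_reversal(blk(80), cfg))
  # performance never triggers in the full task, even at perfect choice
  perfect <- data.frame(choice = rep("left", 30), high_side = rep("left", 30))
  expect_false(check_reversal(perfect, cfg))
})

test_that("no-lick period: bounded draws, 25 s ceiling, truncated-exponential mean", {
  cfg <- task_preset("headfixed_70_10")
  set.seed(3)
  singles <- replicate(1e5, sample_nolick_period(cfg, 0))
  expect_true(all(singles >= 1 & singles <= 5))

  expect_equal(nolick_max_total(cfg), 25)
  worst <- replicate(2000, sample_nolick_period(cfg, n_violations = 100))
  expect_true(all(worst >= 1 & worst <= 25))

  m <- trunc_exp_mean(cfg$nolick_rate, 1, 5)
  expect_lt(abs(mean(singles) - m), 3 * stats::sd(singles) / sqrt(length(singles)))

  expect_error(sample_nolick_period(cfg, -1), "nonnegative")
})

test_that("block-transition draws follow the truncated geometric", {
  cfg <- task_preset("headfixed_70_10")
  set.seed(4)
  draws <- replicate(1e5, sample_block_transition(cfg))
  expect_true(all(draws >= 0 & draws <= 30))

  m_oracle <- trunc_geom_mean_oracle(11, 0, 30)
  expect_equal(block_transition_mean(cfg), m_oracle, tolerance = 1e-12)
  expect_lt(abs(mean(draws) - m_oracle), 3 * stats::sd(draws) / sqrt(length(draws)))

  degenerate <- task_config(variant = "headfixed_bandit", baited = FALSE,
                            geo_min = 0, geo_max = 0, block_length_cap = NULL)
  expect_identical(sample_block_transition(degenerate), 0L)
})

test_that("training blocks: alternator hits the 100-trial cap, ideal tracker the 9-of-10 rule", {
  s <- run_session(agent_alternator(), task_preset("training_0_100"), seed = 10)
  lens <- diff(c(0L, block_boundaries(s)$trial_index))
  expect_gte(length(lens), 5)
  expect_true(all(lens == 100L))

  s2 <- run_session(agent_ideal(), task_preset("training_0_100"), seed = 11)
  lens2 <- diff(c(0L, block_boundaries(s2)$trial_index))
  expect_gte(length(lens2), 5)
  expect_true(all(lens2 == 10L))
})

test_that("full-task blocks are exactly the cap for any agent", {
  for (agent in list(agent_wsls(), agent_biased_random(0.7),
                     agent_q_softmax(0.2, 3))) {
    s <- run_session(agent, task_preset("full_15_60"), seed = 12)
    lens <- diff(c(0L, block_boundaries(s)$trial_index))
    expect_true(all(lens == 80L))
  }
})

test_that("sessions are reproducible and seeds matter", {
  a <- run_session(agent_q_softmax(), task_preset("full_15_60"), seed = 5)
  b <- run_session(agent_q_softmax(), task_preset("full_15_60"), seed = 5)
  expect_identical(a, b)
  c <- run_session(agent_q_softmax(), task_preset("full_15_60"), seed = 6)
  expect_false(identical(a$choice, c$choice))
})

test_that("agents returning an invalid side violate the session contract", {
  bad <- agent_wsls()
  bad$choose_fun <- function(self, high_side) "up"
  expect_error(run_session(bad, task_preset("full_15_60"), seed = 1),
               "invalid choice")
})

test_that("bait persistence shows up in session logs of the 0/100 task", {
  # the p = 1 port is re-baited every trial, so every high-side choice pays
  s <- run_session(agent_alternator(), task_preset("training_0_100"), seed = 13)
  expect_true(all(s$rewarded[s$choice == s$high_side]))

  # the p = 0 port can pay only by collecting a bait left over from before
  # the reversal, i.e. only on the first low-side visit of a block
  low_rewarded <- s |>
    dplyr::group_by(.data$block_index) |>
    dplyr::mutate(low_visit_rank = cumsum(.data$choice != .data$high_side)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$choice != .data$high_side, .data$rewarded)
  expect_true(all(low_rewarded$low_visit_rank == 1L))
  expect_true(all(low_rewarded$block_index > 0L))
  # and such carried-over collections do occur (persistence is observable)
  expect_gt(nrow(low_rewarded), 0)
})

test_that("ideal tracker out-earns a biased random agent in the baited task", {
  cfg <- task_preset("full_15_60", max_trials = 10000L)
  r_ideal <- mean(run_session(agent_ideal(), cfg, seed = 21)$rewarded)
  r_biased <- mean(run_session(agent_biased_random(0.8), cfg, seed = 21)$rewarded)
  expect_gte(r_ideal, r_biased)
})

test_that("head-fixed sessions: no-lick column, block arming, no-response termination", {
  cfg <- task_preset("headfixed_70_10", max_trials = 300L)
  s <- run_session(agent_ideal(), cfg, seed = 30)
  expect_true(all(s$nolick_s >= 1 & s$nolick_s <= 25))
  # ideal agent arms after its 10th high choice; block length = 10 + L_Random
  lens <- diff(c(0L, block_boundaries(s)$trial_index))
  expect_true(all(lens >= 10 & lens <= 40))

  mute <- agent_wsls(p_none = 1)
  s2 <- run_session(mute, cfg, seed = 31)
  expect_identical(nrow(s2), 20L)  # terminated by 20 consecutive no-responses
  expect_true(all(s2$choice == "none"))
  expect_false(any(s2$rewarded))
})

test_that("vectorised baiting Monte Carlo matches the closed form", {
  set.seed(9)
  for (p in c(0.15, 0.6)) {
    for (k in c(1, 5, 10)) {
      r <- baiting_first_visit(p, k, n = 2e5)
      expect_lt(abs(r$estimate - r$expected), 3 * r$se)
    }
  }
})
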