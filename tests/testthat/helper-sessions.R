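# Programmatic fixtures: hand-built and randomly generated session tables.

# minimal trial tibble from parallel vectors
make_trials <- function(choice, high_side, rewarded,
                        block_index = rep(0L, length(choice)),
                        iti_s = rep(NA_real_, length(choice)),
                        subject_id = "s01", session_id = "s01-1",
                        genotype = "WT", sex = "M") {
  tibble::tibble(
    subject_id = subject_id, genotype = genotype, sex = sex,
    session_id = session_id,
    trial_index = seq_along(choice) - 1L,
    block_index = as.integer(block_index),
    high_side = high_side, choice = choice,
    rewarded = as.logical(rewarded),
    iti_s = iti_s, nolick_s = NA_real_
  )
}

# random 50-trial session with reversals, occasional no-responses, and ITIs
random_session <- function(seed, n = 50L, p_none = 0.05) {
  set.seed(seed)
  n_blocks <- sample(2:4, 1)
  cuts <- sort(sample(5:(n - 5), n_blocks - 1))
  block_index <- as.integer(findInterval(seq_len(n) - 1L, cuts))
  first_high <- sample(c("left", "right"), 1)
  sides <- c("left", "right")
  high_side <- ifelse(block_index %% 2 == 0, first_high,
                      setdiff(sides, first_high))
  choice <- sample(c("left", "right"), n, replace = TRUE)
  choice[stats::runif(n) < p_none] <- "none"
  rewarded <- stats::runif(n) < 0.4 & choice != "none"
  iti_s <- round(stats::rlnorm(n, log(1.5), 0.4), 3)
  iti_s[1] <- NA_real_
  iti_s[stats::runif(n) < 0.05] <- NA_real_
  make_trials(choice, high_side, rewarded, block_index, iti_s,
              subject_id = sprintf("s%02d", seed %% 7 + 1),
              session_id = sprintf("sess%03d", seed))
}
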