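#' Create an empty port bait state
#'
#' The bait state records, for each side port, whether a reward is currently
#' assigned and waiting to be collected. Flags are set by [sample_baiting()]
#' and cleared only when the port is chosen ([resolve_choice()]).
#'
#' @return A named logical vector `c(left = FALSE, right = FALSE)`.
#' @export
new_port_state <- function() {
  c(left = FALSE, right = FALSE)
}

#' Per-trial baiting draw
#'
#' Before each choice, each port independently becomes baited with its
#' current reward probability. A port that is already baited stays baited:
#' once assigned, a reward remains available until that port is next chosen.
#' Two uniform draws are always consumed (left then right) so that the
#' session RNG stream does not depend on the bait state.
#'
#' @param state Port bait state (see [new_port_state()]).
#' @param p_left,p_right Reward probability of each port, in \[0, 1\].
#' @return The updated bait state.
#' @export
#' @examples
#' set.seed(1)
#' sample_baiting(new_port_state(), 1, 0)
sample_baiting <- function(state, p_left, p_right) {
  p <- c(p_left, p_right)
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("reward probabilities must be in [0, 1]", call. = FALSE)
  }
  state | (stats::runif(2L) < p)
}

#' Resolve a choice against the bait state
#'
#' The chosen port delivers a reward if and only if it is baited; its bait
#' flag is then cleared. The unchosen port is untouched, so an uncollected
#' reward there stays available.
#'
#' @param state Port bait state.
#' @param choice `"left"` or `"right"`.
#' @return A list with elements `rewarded` (logical) and `state` (updated
#'   bait state).
#' @export
#' @examples
#' st <- c(left = TRUE, right = FALSE)
#' resolve_choice(st, "left")
resolve_choice <- function(state, choice) {
  if (!choice %in% c("left", "right")) {
    stop("`choice` must be 'left' or 'right'", call. = FALSE)
  }
  rewarded <- unname(state[[choice]])
  state[[choice]] <- FALSE
  list(rewarded = rewarded, state = state)
}

#' Should the current block end?
#'
#' Evaluated after every completed trial on the trials of the current block
#' only. A reversal triggers when the block reaches `block_length_cap`
#' trials, or — when the performance rule is active — once at least
#' `perf_threshold` of the last `perf_window` trials chose the
#' high-probability port. The window never reaches back into the previous
#' block, so the earliest performance-triggered reversal is at trial
#' `perf_window` of a block. A trial is "correct" when the choice equals the
#' high side, regardless of whether a reward was actually collected;
#' no-response trials count as incorrect.
#'
#' @param block_trials Data frame of the current block's completed trials,
#'   with columns `choice` and `high_side`.
#' @param config A [task_config()].
#' @return Logical: reverse now?
#' @export
check_reversal <- function(block_trials, config) {
  n <- nrow(block_trials)
  if (!is.null(config$block_length_cap) && n >= config$block_length_cap) {
    return(TRUE)
  }
  if (config$perf_rule && n >= config$perf_window) {
    recent <- block_trials[(n - config$perf_window + 1L):n, , drop = FALSE]
    correct <- sum(recent$choice == recent$high_side, na.rm = TRUE)
    if (correct >= config$perf_threshold) return(TRUE)
  }
  FALSE
}

# Inverse-CDF draw from Exp(rate) truncated to [a, b]; vectorised over n.
rtrunc_exp <- function(n, rate, a, b) {
  u <- stats::runif(n)
  -log(exp(-rate * a) - u * (exp(-rate * a) - exp(-rate * b))) / rate
}

#' Sample a head-fixed no-lick period
#'
#' The no-lick period starts with one draw from an exponential distribution
#' (rate `nolick_rate`) truncated to `[nolick_min, nolick_max]`, sampled by
#' inverse CDF so every draw is bounded. Each premature lick during the
#' period adds another independent draw from the same distribution, up to
#' `nolick_max_draws` draws in total; the total duration is therefore always
#' in `[nolick_min, nolick_max_draws * nolick_max]` (1 to 25 s at the default
#' parameters).
#'
#' @param config A [task_config()] supplying the no-lick parameters.
#' @param n_violations Nonnegative count of premature licks during the
#'   period.
#' @return Total no-lick duration in seconds.
#' @seealso [nolick_max_total()]
#' @export
sample_nolick_period <- function(config, n_violations = 0L) {
  if (length(n_violations) != 1 || is.na(n_violations) || n_violations < 0) {
    stop("`n_violations` must be a nonnegative count", call. = FALSE)
  }
  n_draws <- 1L + min(as.integer(n_violations), config$nolick_max_draws - 1L)
  sum(rtrunc_exp(n_draws, config$nolick_rate, config$nolick_min, config$nolick_max))
}

#' Maximum attainable total no-lick duration
#'
#' The supremum of [sample_nolick_period()] over all violation counts:
#' `nolick_max_draws * nolick_max` (25 s at the default parameters).
#'
#' @param config A [task_config()].
#' @return Seconds.
#' @export
nolick_max_total <- function(config) {
  config$nolick_max_draws * config$nolick_max
}

# Truncated-geometric pmf over geo_min:geo_max with success prob 1/(mu + 1),
# mu interpreted as the untruncated mean, renormalised over the support.
trunc_geom_pmf <- function(config) {
  k <- config$geo_min:config$geo_max
  if (config$geo_mean == 0) {
    p <- as.numeric(k == 0)
    if (sum(p) == 0) p <- c(1, rep(0, length(k) - 1L))
    return(stats::setNames(p / sum(p), k))
  }
  succ <- 1 / (config$geo_mean + 1)
  w <- (1 - succ)^k * succ
  stats::setNames(w / sum(w), k)
}

#' Sample the extra-trial count of a head-fixed block transition
#'
#' Once the transition is armed (10 cumulative high-side choices within the
#' block), the block runs for an additional number of trials drawn from a
#' geometric distribution with untruncated mean `geo_mean` (success
#' probability `1/(geo_mean + 1)`, support starting at 0), renormalised over
#' `[geo_min, geo_max]`.
#'
#' @param config A [task_config()].
#' @return Integer in `[geo_min, geo_max]`.
#' @seealso [block_transition_mean()]
#' @export
sample_block_transition <- function(config) {
  k <- config$geo_min:config$geo_max
  if (length(k) == 1L) return(k)
  pmf <- trunc_geom_pmf(config)
  sample(k, 1L, prob = pmf)
}

#' Analytic mean of the truncated-geometric transition distribution
#'
#' @param config A [task_config()].
#' @return The mean of the renormalised truncated distribution.
#' @export
block_transition_mean <- function(config) {
  pmf <- trunc_geom_pmf(config)
  sum(as.numeric(names(pmf)) * pmf)
}

# high side of a contingency pair; ties resolved by swapping the previous
# high side (arbitrary but deterministic; tie blocks have no true high side)
pair_high_side <- function(pair, prev_high = "right") {
  if (pair[["left"]] > pair[["right"]]) "left"
  else if (pair[["right"]] > pair[["left"]]) "right"
  else if (identical(prev_high, "left")) "right" else "left"
}

#' Simulate one behavioral session
#'
#' Runs the full trial loop of the configured task variant with a synthetic
#' agent: per trial, ports are (re)baited, the agent chooses (or emits a
#' no-response), the choice is resolved against the bait state, the
#' self-paced intertrial interval is drawn from the agent's latency model
#' conditioned on the previous outcome, and the reversal rule is evaluated.
#' Sessions are deterministic given `(agent, config, seed)`: a single seeded
#' RNG stream drives all draws in a fixed per-trial order (bait left, bait
#' right; no-lick violations and durations for the head-fixed variant; agent
#' choice; ITI; block-transition length when armed).
#'
#' The head-fixed variant does not use baiting: each trial's reward is an
#' independent Bernoulli draw at the chosen port. Its block transition arms
#' after 10 cumulative high-side choices within the block and fires after a
#' truncated-geometric number of extra trials; the session ends after
#' `no_response_limit` consecutive no-responses.
#'
#' @param agent A behaving agent, e.g. [agent_wsls()].
#' @param config A [task_config()] or preset name for [task_preset()].
#' @param seed Integer seed for the session RNG.
#' @param subject_id,genotype,sex,session_id Metadata stamped on every trial
#'   row.
#' @param latency A [latency_model()] generating ITIs; `NULL` for no ITIs.
#' @return A tibble with one row per trial and columns `subject_id`,
#'   `genotype`, `sex`, `session_id`, `trial_index` (0-based),
#'   `block_index` (0-based), `high_side`, `choice`, `rewarded`, `iti_s`,
#'   `nolick_s`; the seed is kept in attribute `seed_used`.
#' @export
#' @examples
#' s <- run_session(agent_wsls(), task_preset("training_0_100"), seed = 1)
#' head(s)
#' block_boundaries(s)
run_session <- function(agent, config, seed,
                        subject_id = "s01", genotype = "WT", sex = "M",
                        session_id = paste0(subject_id, "-1"),
                        latency = latency_model()) {
  if (is.character(config)) config <- task_preset(config)
  stopifnot(inherits(config, "forage_task_config"))
  if (!inherits(agent, "forage_agent")) {
    stop("`agent` must be a forage_agent (see agent_wsls() and friends)",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  agent_reset(agent)

  sched <- config$contingency_schedule
  n_sched <- length(sched)
  sched_idx <- if (config$randomize_start && n_sched > 1L) {
    sample.int(n_sched, 1L)
  } else 1L
  pair <- sched[[sched_idx]]
  high <- pair_high_side(pair)

  headfixed <- config$variant == "headfixed_bandit"
  nmax <- config$max_trials
  choice_v <- character(nmax)
  high_v <- character(nmax)
  rewarded_v <- logical(nmax)
  block_v <- integer(nmax)
  iti_v <- rep(NA_real_, nmax)
  nolick_v <- rep(NA_real_, nmax)

  state <- new_port_state()
  block_idx <- 0L
  block_start <- 1L
  block_high_choices <- 0L   # head-fixed cumulative high-side choices
  armed <- FALSE
  extra_left <- 0L
  consec_none <- 0L
  prev_rewarded <- NA
  t <- 0L

  while (t < nmax) {
    t <- t + 1L
    if (!config$baited) state <- new_port_state()
    state <- sample_baiting(state, pair[["left"]], pair[["right"]])

    if (headfixed) {
      nv <- 0L
      p_viol <- agent_param(agent, "p_nolick_violation", 0)
      while (nv < config$nolick_max_draws - 1L && stats::runif(1L) < p_viol) {
        nv <- nv + 1L
      }
      nolick_v[t] <- sample_nolick_period(config, nv)
    }

    choice <- agent_choose(agent, high)
    if (!choice %in% c("left", "right", "none")) {
      stop("agent returned invalid choice: '", choice, "'", call. = FALSE)
    }

    if (choice == "none") {
      rewarded <- FALSE
      consec_none <- consec_none + 1L
    } else {
      res <- resolve_choice(state, choice)
      rewarded <- res$rewarded
      state <- res$state
      consec_none <- 0L
    }

    if (t > 1L && !is.null(latency)) {
      iti_v[t] <- sample_iti(latency, isTRUE(prev_rewarded))
    }

    choice_v[t] <- choice
    high_v[t] <- high
    rewarded_v[t] <- rewarded
    block_v[t] <- block_idx

    agent_update(agent, choice, rewarded)
    prev_rewarded <- rewarded

    # --- reversal logic -----------------------------------------------
    reverse <- FALSE
    if (headfixed) {
      if (choice == high) block_high_choices <- block_high_choices + 1L
      if (!armed && block_high_choices >= 10L) {
        armed <- TRUE
        extra_left <- sample_block_transition(config)
      } else if (armed) {
        extra_left <- extra_left - 1L
      }
      if (armed && extra_left <= 0L) reverse <- TRUE
    } else {
      # same rule as check_reversal(), on the raw vectors for speed
      blen <- t - block_start + 1L
      if (!is.null(config$block_length_cap) && blen >= config$block_length_cap) {
        reverse <- TRUE
      } else if (config$perf_rule && blen >= config$perf_window) {
        win <- (t - config$perf_window + 1L):t
        if (sum(choice_v[win] == high_v[win]) >= config$perf_threshold) {
          reverse <- TRUE
        }
      }
    }
    if (reverse && n_sched > 1L) {
      sched_idx <- sched_idx %% n_sched + 1L
      pair <- sched[[sched_idx]]
      high <- pair_high_side(pair, prev_high = high)
      block_idx <- block_idx + 1L
      block_start <- t + 1L
      block_high_choices <- 0L
      armed <- FALSE
      # bait flags persist across the reversal: only probabilities swap
    }

    if (!is.null(config$no_response_limit) &&
        consec_none >= config$no_response_limit) break
  }

  out <- tibble::tibble(
    subject_id = subject_id,
    genotype = genotype,
    sex = sex,
    session_id = session_id,
    trial_index = seq_len(t) - 1L,
    block_index = block_v[seq_len(t)],
    high_side = high_v[seq_len(t)],
    choice = choice_v[seq_len(t)],
    rewarded = rewarded_v[seq_len(t)],
    iti_s = iti_v[seq_len(t)],
    nolick_s = nolick_v[seq_len(t)]
  )
  attr(out, "seed_used") <- as.integer(seed)
  attr(out, "variant") <- config$variant
  out
}

#' Trial indices at which reversals occurred
#'
#' @param trials A session (or cohort) trial tibble with `trial_index` and
#'   `block_index` columns; for multi-session input, boundaries are computed
#'   within `session_id`.
#' @return A tibble with columns `session_id` (if present), `trial_index`:
#'   the first trial of each post-reversal block.
#' @export
block_boundaries <- function(trials) {
  grp <- intersect(c("subject_id", "session_id"), names(trials))
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::filter(.data$block_index != dplyr::lag(.data$block_index,
                                                  default = dplyr::first(.data$block_index))) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(grp), "trial_index", "block_index")
}

#' Monte-Carlo probability that a port is baited at first visit
#'
#' For a port with per-trial reward probability `p` that goes unvisited for
#' `k` trials (each with an independent baiting draw) and is then visited,
#' the collection probability is `1 - (1 - p)^k` by bait persistence. This
#' helper estimates that probability by simulating the baiting process.
#'
#' @param p Per-trial reward probability.
#' @param k Number of baiting draws before the visit.
#' @param n Number of Monte-Carlo replicates.
#' @return A list with `estimate`, `se` (binomial standard error), and the
#'   analytic `expected` value.
#' @export
baiting_first_visit <- function(p, k, n = 1e5) {
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]", call. = FALSE)
  draws <- matrix(stats::runif(n * k) < p, nrow = k)
  baited <- colSums(draws) > 0
  est <- mean(baited)
  list(
    estimate = est,
    se = sqrt(est * (1 - est) / n),
    expected = 1 - (1 - p)^k
  )
}
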