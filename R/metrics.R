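#' Per-day learning curve
#'
#' For each subject and training day, the fraction of valid-choice trials on
#' which the subject chose the high-probability port. Days with zero
#' valid-choice trials yield `NA`, not zero.
#'
#' @param trials Trial tibble (session log). A `day` column is used if
#'   present; otherwise days are derived per subject from the session order.
#' @return A tibble with `subject_id`, `genotype`, `sex` (when present),
#'   `day`, `p_high`, `n_trials`, of class `forage_learning_curve`.
#' @export
learning_curve <- function(trials) {
  if (!"day" %in% names(trials)) {
    trials <- trials |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::mutate(day = dplyr::dense_rank(.data$session_id)) |>
      dplyr::ungroup()
  }
  meta <- intersect(c("genotype", "sex"), names(trials))
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject_id", meta, "day")))) |>
    dplyr::summarise(
      p_high = {
        valid <- .data$choice != "none"
        if (sum(valid) > 0) {
          sum(.data$choice == .data$high_side & valid) / sum(valid)
        } else NA_real_
      },
      n_trials = sum(.data$choice != "none"),
      .groups = "drop"
    )
  class(out) <- c("forage_learning_curve", class(out))
  out
}

# per-block position table for reversal-aligned analysis: one row per trial
# of each post-reversal block, with its 1-based position in the block
reversal_positions <- function(trials, n_after) {
  trials |>
    dplyr::group_by(.data$subject_id, .data$session_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::filter(.data$block_index > 0L) |>
    dplyr::group_by(.data$subject_id, .data$session_id, .data$block_index) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$position <= n_after)
}

#' Reversal-aligned choice probability
#'
#' For each trial position k = 1..`n_after` after an uncued reversal, the
#' probability of choosing the new high-probability port. The first block of
#' a session is not preceded by a reversal and is excluded. Blocks shorter
#' than k do not contribute to position k's denominator, and no-response
#' trials are excluded from both numerator and denominator.
#'
#' With `pool = "subject"` (default) the per-position fraction is computed
#' within each subject and then averaged across subjects (each animal
#' weighted equally); `pool = "blocks"` pools all blocks directly.
#'
#' @param trials Trial tibble.
#' @param n_after Number of post-reversal trial positions.
#' @param by Optional grouping columns kept in the output (e.g.
#'   `"genotype"`).
#' @param pool `"subject"` or `"blocks"`.
#' @return A `forage_reversal_curve` tibble with columns `by...`,
#'   `trials_since_reversal`, `p_new_high`, `n` (subjects or blocks in the
#'   denominator). If the input contains no reversals the tibble is empty.
#' @export
reversal_aligned <- function(trials, n_after = 10L, by = NULL,
                             pool = c("subject", "blocks")) {
  pool <- match.arg(pool)
  stopifnot(n_after >= 1)
  pos <- reversal_positions(trials, n_after) |>
    dplyr::filter(.data$choice != "none") |>
    dplyr::mutate(new_high = .data$choice == .data$high_side)
  if (nrow(pos) == 0) {
    out <- tibble::tibble(trials_since_reversal = integer(0),
                          p_new_high = numeric(0), n = integer(0))
    class(out) <- c("forage_reversal_curve", class(out))
    return(out)
  }
  if (pool == "blocks") {
    out <- pos |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "position")))) |>
      dplyr::summarise(p_new_high = mean(.data$new_high),
                       n = dplyr::n(), .groups = "drop")
  } else {
    out <- pos |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "subject_id", "position")))) |>
      dplyr::summarise(p_new_high = mean(.data$new_high), .groups = "drop") |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "position")))) |>
      dplyr::summarise(p_new_high = mean(.data$p_new_high),
                       n = dplyr::n(), .groups = "drop")
  }
  out <- dplyr::rename(out, trials_since_reversal = "position")
  class(out) <- c("forage_reversal_curve", class(out))
  out
}

#' Win-stay / lose-switch fractions
#'
#' Over consecutive pairs of valid-choice trials within a session, the
#' fraction of stays following rewarded trials (win-stay) and of switches
#' following unrewarded trials (lose-switch). Pairs broken by a no-response
#' trial are excluded; pairs spanning a reversal are included, since the
#' strategy is defined purely on choice and outcome. A zero denominator
#' yields `NA` for that fraction.
#'
#' @param trials Trial tibble.
#' @param by Grouping columns (default per subject; use
#'   `c("subject_id", "session_id")` for per-session values, or `NULL` for
#'   one pooled row).
#' @return A tibble with `by...`, `win_stay`, `lose_switch`,
#'   `n_win_transitions`, `n_lose_transitions`.
#' @export
#' @examples
#' s <- run_session(agent_wsls(), task_preset("full_15_60"), seed = 2)
#' wsls_fractions(s, by = NULL)
wsls_fractions <- function(trials, by = "subject_id") {
  pairs <- trials |>
    dplyr::group_by(.data$subject_id, .data$session_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::mutate(prev_choice = dplyr::lag(.data$choice),
                  prev_rewarded = dplyr::lag(.data$rewarded)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_choice),
                  .data$choice != "none", .data$prev_choice != "none")
  ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_
  pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      win_stay = ratio_or_na(
        sum(.data$prev_rewarded & .data$choice == .data$prev_choice),
        sum(.data$prev_rewarded)),
      lose_switch = ratio_or_na(
        sum(!.data$prev_rewarded & .data$choice != .data$prev_choice),
        sum(!.data$prev_rewarded)),
      n_win_transitions = sum(.data$prev_rewarded),
      n_lose_transitions = sum(!.data$prev_rewarded),
      .groups = "drop"
    )
}

#' Outcome-conditioned intertrial intervals
#'
#' Each trial's self-paced initiation latency (`iti_s`) is assigned to the
#' outcome of the *previous* trial, and medians and quartiles (linear
#' interpolation, R quantile type 7) are computed separately for
#' previously-rewarded and previously-unrewarded conditions.
#'
#' @param trials Trial tibble with an `iti_s` column.
#' @param by Grouping columns (default per subject; `NULL` pools all
#'   trials).
#' @return A tibble with `by...` and, per condition, `median_*_s`, `q1_*`,
#'   `q3_*`, `n_*` columns.
#' @export
conditional_iti <- function(trials, by = "subject_id") {
  lagged <- trials |>
    dplyr::group_by(.data$subject_id, .data$session_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::mutate(prev_rewarded = dplyr::lag(.data$rewarded)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_rewarded), !is.na(.data$iti_s))
  q <- function(x, p) if (length(x) > 0) unname(stats::quantile(x, p, type = 7)) else NA_real_
  lagged |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      median_rewarded_s = q(.data$iti_s[.data$prev_rewarded], 0.5),
      q1_rewarded = q(.data$iti_s[.data$prev_rewarded], 0.25),
      q3_rewarded = q(.data$iti_s[.data$prev_rewarded], 0.75),
      n_rewarded = sum(.data$prev_rewarded),
      median_unrewarded_s = q(.data$iti_s[!.data$prev_rewarded], 0.5),
      q1_unrewarded = q(.data$iti_s[!.data$prev_rewarded], 0.25),
      q3_unrewarded = q(.data$iti_s[!.data$prev_rewarded], 0.75),
      n_unrewarded = sum(!.data$prev_rewarded),
      .groups = "drop"
    )
}

#' Trailing moving average of left choices
#'
#' Adds a column `ma_left`: the trailing `window`-trial mean of the
#' left-choice indicator, computed per session. The first `window - 1`
#' trials average over the history available so far. No-response trials are
#' excluded from both numerator and denominator; a window containing only
#' no-response trials yields `NA`.
#'
#' @param trials Trial tibble.
#' @param window Positive integer window length.
#' @return The input tibble with an added `ma_left` column.
#' @export
moving_average_choice <- function(trials, window = 10L) {
  stopifnot(window >= 1)
  ma_one <- function(choice) {
    x <- ifelse(choice == "none", NA_real_, as.numeric(choice == "left"))
    n <- length(x)
    out <- numeric(n)
    for (t in seq_len(n)) {
      w <- x[max(1L, t - window + 1L):t]
      out[t] <- mean(w, na.rm = TRUE)
    }
    out[is.nan(out)] <- NA_real_
    out
  }
  trials |>
    dplyr::group_by(.data$subject_id, .data$session_id) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::mutate(ma_left = ma_one(.data$choice)) |>
    dplyr::ungroup()
}

#' Relative reward-probability (matching) ratio
#'
#' The fraction of total programmed reward probability assigned to the left
#' port, `p_left / (p_left + p_right)` — e.g. 60/(15 + 60) = 0.8. Under
#' matching behavior, choice fractions track this ratio.
#'
#' @param p_left,p_right Reward probabilities; vectorised.
#' @return `p_left / (p_left + p_right)`.
#' @export
#' @examples
#' contingency_ratio(60, 15)
contingency_ratio <- function(p_left, p_right) {
  if (any(p_left < 0) || any(p_right < 0)) {
    stop("probabilities must be nonnegative", call. = FALSE)
  }
  if (any(p_left + p_right == 0)) {
    stop("`p_left + p_right` must be positive", call. = FALSE)
  }
  p_left / (p_left + p_right)
}
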