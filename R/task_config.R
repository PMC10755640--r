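#' Task configuration for a dynamic foraging variant
#'
#' Builds a validated configuration object describing one variant of the
#' two-armed bandit foraging task: the reward contingencies per block, the
#' reversal rule, whether rewards are baited (persist until collected), and,
#' for the head-fixed variant, the no-lick period and block-transition
#' distribution parameters.
#'
#' The task variants are:
#' \describe{
#'   \item{`training_single_port`}{shaping stage: a single port carries reward
#'     with probability 1, no reversals.}
#'   \item{`training_0_100`}{deterministic training: one port at 100%, the
#'     other at 0%; uncued reversals every `block_length_cap` (100) trials or
#'     once the animal chose the high port on at least `perf_threshold` (9) of
#'     the last `perf_window` (10) trials of the current block.}
#'   \item{`full_freely_moving`}{the probabilistic task: both ports baited
#'     (default 60% vs 15%); uncued reversals every `block_length_cap` (80)
#'     trials regardless of performance.}
#'   \item{`headfixed_bandit`}{lick-based variant: 70:10 reward blocks
#'     (not baited), block transitions armed after 10 cumulative high-side
#'     choices plus a truncated-geometric number of extra trials, session
#'     terminated after 20 consecutive no-responses, and an iterated
#'     truncated-exponential no-lick period before each trial.}
#' }
#'
#' @param variant One of `"training_single_port"`, `"training_0_100"`,
#'   `"full_freely_moving"`, `"headfixed_bandit"`.
#' @param contingency_schedule List of numeric pairs `c(p_left, p_right)`
#'   giving the reward probability of each port, one pair per block; the
#'   schedule is cycled when more blocks occur than pairs listed.
#' @param block_length_cap Positive integer: block length at which a reversal
#'   is forced, or `NULL` for no cap.
#' @param perf_rule Logical: is the performance-triggered reversal rule
#'   active?
#' @param perf_window,perf_threshold Reversal triggers once at least
#'   `perf_threshold` of the last `perf_window` trials of the current block
#'   chose the high-probability port.
#' @param baited Logical: once assigned, does a reward persist at its port
#'   until that port is next chosen?
#' @param max_trials Session length cap (trials).
#' @param no_response_limit Consecutive no-response trials that terminate the
#'   session, or `NULL`.
#' @param nolick_rate,nolick_min,nolick_max Rate (per second) and truncation
#'   bounds (seconds) of the truncated-exponential no-lick draw (head-fixed).
#' @param nolick_max_draws Maximum total number of no-lick draws (initial
#'   draw plus violation-triggered additions).
#' @param geo_mean,geo_min,geo_max Parameters of the truncated geometric
#'   distribution of extra trials before an armed head-fixed block
#'   transition: `geo_mean` is the untruncated mean (success probability
#'   `1/(geo_mean + 1)`), renormalised over `geo_min:geo_max`.
#' @param randomize_start Logical: pick the starting schedule entry at random
#'   at session start (one RNG draw), as opposed to always starting from the
#'   first pair.
#'
#' @return An object of class `forage_task_config` (a named list).
#' @seealso [task_preset()] for the named presets, [run_session()].
#' @export
#' @examples
#' cfg <- task_preset("full_15_60")
#' cfg$block_length_cap
task_config <- function(variant = c("full_freely_moving", "training_single_port",
                                    "training_0_100", "headfixed_bandit"),
                        contingency_schedule = list(c(0.60, 0.15), c(0.15, 0.60)),
                        block_length_cap = 80L,
                        perf_rule = FALSE,
                        perf_window = 10L,
                        perf_threshold = 9L,
                        baited = TRUE,
                        max_trials = 938L,
                        no_response_limit = NULL,
                        nolick_rate = 1 / 3,
                        nolick_min = 1,
                        nolick_max = 5,
                        nolick_max_draws = 5L,
                        geo_mean = 11,
                        geo_min = 0L,
                        geo_max = 30L,
                        randomize_start = TRUE) {
  variant <- match.arg(variant)
  if (!is.list(contingency_schedule) || length(contingency_schedule) < 1) {
    stop("`contingency_schedule` must be a non-empty list of (p_left, p_right) pairs",
         call. = FALSE)
  }
  for (pair in contingency_schedule) {
    if (length(pair) != 2 || !is.numeric(pair) || anyNA(pair) ||
        any(pair < 0) || any(pair > 1)) {
      stop("each contingency pair must be two probabilities in [0, 1]", call. = FALSE)
    }
  }
  if (!is.null(block_length_cap)) {
    block_length_cap <- as.integer(block_length_cap)
    if (block_length_cap < 1) stop("`block_length_cap` must be positive", call. = FALSE)
  }
  perf_window <- as.integer(perf_window)
  perf_threshold <- as.integer(perf_threshold)
  if (perf_threshold > perf_window) {
    stop("`perf_threshold` must not exceed `perf_window`", call. = FALSE)
  }
  max_trials <- as.integer(max_trials)
  if (max_trials < 1) stop("`max_trials` must be positive", call. = FALSE)
  if (!is.null(no_response_limit)) no_response_limit <- as.integer(no_response_limit)
  if (nolick_rate <= 0) stop("`nolick_rate` must be positive", call. = FALSE)
  if (!(nolick_min < nolick_max)) {
    stop("`nolick_min` must be strictly less than `nolick_max`", call. = FALSE)
  }
  nolick_max_draws <- as.integer(nolick_max_draws)
  if (nolick_max_draws < 1) stop("`nolick_max_draws` must be at least 1", call. = FALSE)
  geo_min <- as.integer(geo_min); geo_max <- as.integer(geo_max)
  if (geo_min > geo_max) stop("`geo_min` must not exceed `geo_max`", call. = FALSE)
  if (geo_mean < 0) stop("`geo_mean` must be nonnegative", call. = FALSE)

  structure(
    list(
      variant = variant,
      contingency_schedule = lapply(contingency_schedule, function(p) {
        stats::setNames(as.numeric(p), c("left", "right"))
      }),
      block_length_cap = block_length_cap,
      perf_rule = isTRUE(perf_rule),
      perf_window = perf_window,
      perf_threshold = perf_threshold,
      baited = isTRUE(baited),
      max_trials = max_trials,
      no_response_limit = no_response_limit,
      nolick_rate = nolick_rate,
      nolick_min = nolick_min,
      nolick_max = nolick_max,
      nolick_max_draws = nolick_max_draws,
      geo_mean = geo_mean,
      geo_min = geo_min,
      geo_max = geo_max,
      randomize_start = isTRUE(randomize_start)
    ),
    class = "forage_task_config"
  )
}

#' @export
print.forage_task_config <- function(x, ...) {
  cat("<forage_task_config> variant:", x$variant, "\n")
  sched <- vapply(x$contingency_schedule,
                  function(p) sprintf("%g/%g", p[["left"]], p[["right"]]),
                  character(1))
  cat("  contingencies (left/right):", paste(sched, collapse = ", "), "\n")
  cat("  block cap:", if (is.null(x$block_length_cap)) "none" else x$block_length_cap,
      " perf rule:", x$perf_rule,
      sprintf("(%d of %d)", x$perf_threshold, x$perf_window), "\n")
  cat("  baited:", x$baited, " max trials:", x$max_trials, "\n")
  invisible(x)
}

#' Named task presets
#'
#' Ready-made [task_config()] objects for the task variants used across the
#' study design: deterministic training, the default 15/60 probabilistic
#' task, its 40- and 100-trial block-length variants, the two
#' mixed-contingency variants, and the head-fixed 70:10 bandit.
#'
#' @param name One of `"training_single_port"`, `"training_0_100"`,
#'   `"full_15_60"`, `"block40"`, `"block100"`,
#'   `"contingencies_30_30_15_45_10_50"`, `"contingencies_50_50_15_85_25_75"`,
#'   `"headfixed_70_10"`.
#' @param ... Overrides passed on to [task_config()].
#' @return A `forage_task_config`.
#' @export
#' @examples
#' task_preset("training_0_100")$perf_threshold
task_preset <- function(name, ...) {
  presets <- list(
    training_single_port = list(
      variant = "training_single_port",
      contingency_schedule = list(c(1, 0)),
      block_length_cap = NULL, perf_rule = FALSE,
      max_trials = 100L, randomize_start = TRUE
    ),
    training_0_100 = list(
      variant = "training_0_100",
      contingency_schedule = list(c(1, 0), c(0, 1)),
      block_length_cap = 100L, perf_rule = TRUE,
      perf_window = 10L, perf_threshold = 9L,
      max_trials = 714L
    ),
    full_15_60 = list(
      variant = "full_freely_moving",
      contingency_schedule = list(c(0.60, 0.15), c(0.15, 0.60)),
      block_length_cap = 80L, max_trials = 938L
    ),
    block40 = list(
      variant = "full_freely_moving",
      contingency_schedule = list(c(0.60, 0.15), c(0.15, 0.60)),
      block_length_cap = 40L, max_trials = 938L
    ),
    block100 = list(
      variant = "full_freely_moving",
      contingency_schedule = list(c(0.60, 0.15), c(0.15, 0.60)),
      block_length_cap = 100L, max_trials = 938L
    ),
    # Mixed-contingency sessions: each 80-trial block draws the next pair in
    # the cycle; the second pass mirrors sides so both ports serve as high.
    contingencies_30_30_15_45_10_50 = list(
      variant = "full_freely_moving",
      contingency_schedule = list(
        c(0.30, 0.30), c(0.15, 0.45), c(0.10, 0.50),
        c(0.30, 0.30), c(0.45, 0.15), c(0.50, 0.10)
      ),
      block_length_cap = 80L, max_trials = 938L
    ),
    contingencies_50_50_15_85_25_75 = list(
      variant = "full_freely_moving",
      contingency_schedule = list(
        c(0.50, 0.50), c(0.15, 0.85), c(0.25, 0.75),
        c(0.50, 0.50), c(0.85, 0.15), c(0.75, 0.25)
      ),
      block_length_cap = 80L, max_trials = 938L
    ),
    headfixed_70_10 = list(
      variant = "headfixed_bandit",
      contingency_schedule = list(c(0.70, 0.10), c(0.10, 0.70)),
      block_length_cap = NULL, perf_rule = FALSE, baited = FALSE,
      no_response_limit = 20L, max_trials = 500L
    )
  )
  if (!name %in% names(presets)) {
    stop("unknown task preset: '", name, "'. Available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(task_config, args)
}

#' Read a task configuration from YAML
#'
#' The YAML file either names a `preset` (with optional field overrides) or
#' lists [task_config()] fields directly. `contingency_schedule` is given as
#' a list of two-element sequences.
#'
#' @param path Path to a YAML file.
#' @return A `forage_task_config`.
#' @export
read_task_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$preset)) {
    name <- raw$preset
    raw$preset <- NULL
    do.call(task_preset, c(list(name = name), raw))
  } else {
    do.call(task_config, raw)
  }
}
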