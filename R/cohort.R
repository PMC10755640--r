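#' Specify a synthetic cohort
#'
#' A cohort spec describes a multi-subject, multi-session synthetic study:
#' how many subjects per genotype-by-sex cell, which task variants they run
#' and in what order (the training curriculum), which agent policy generates
#' their choices, and the size of an injectable genotype effect (0 = null,
#' i.e. wild-type and heterozygous subjects are generated from identical
#' parameters and every behavioral metric is exchangeable across genotype).
#'
#' A nonzero `effect_size` perturbs the heterozygous agents' core learning
#' parameter: for `q_softmax` agents the learning rate becomes
#' `alpha * (1 - effect_size)` (slower value updating); for `wsls` agents
#' rule compliance is degraded, `eps -> 1 - (1 - eps) * (1 - effect_size)`.
#' `effect_size = 0.5` therefore halves the Q-learning rate.
#'
#' @param n_per_cell Subjects per genotype-by-sex cell (2 genotypes x 2
#'   sexes; the default 12 gives 24 subjects per genotype, the scale of a
#'   typical study cohort).
#' @param sessions_per_subject Sessions per subject per curriculum stage.
#' @param curriculum Character vector of [task_preset()] names run in order,
#'   or a list of `forage_task_config` objects.
#' @param agent_spec Declarative agent spec (see [agent_from_spec()]) used
#'   for every subject; the genotype effect, if any, perturbs it for HET.
#' @param effect_size Genotype effect in `[0, 1)`; 0 for a null cohort.
#' @param latency A [latency_model()] shared by all subjects.
#' @param seizure_rate Probability that a HET subject carries the (purely
#'   annotational) seizure metadata flag.
#' @param master_seed Integer; all subject/session seeds derive from it.
#' @return A `forage_cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_per_cell = 2, sessions_per_subject = 1,
#'                     curriculum = "full_15_60", master_seed = 1)
#' coh <- generate_cohort(spec)
#' coh$subjects
cohort_spec <- function(n_per_cell = 12L,
                        sessions_per_subject = 1L,
                        curriculum = c("training_single_port",
                                       "training_0_100", "full_15_60"),
                        agent_spec = list(type = "q_softmax",
                                          params = list(alpha = 0.2, beta = 3)),
                        effect_size = 0,
                        latency = latency_model(),
                        seizure_rate = 0,
                        master_seed = 20231208L) {
  n_per_cell <- as.integer(n_per_cell)
  if (n_per_cell < 1) stop("`n_per_cell` must be at least 1", call. = FALSE)
  sessions_per_subject <- as.integer(sessions_per_subject)
  if (sessions_per_subject < 1) {
    stop("`sessions_per_subject` must be at least 1", call. = FALSE)
  }
  if (effect_size < 0 || effect_size >= 1) {
    stop("`effect_size` must be in [0, 1)", call. = FALSE)
  }
  if (seizure_rate < 0 || seizure_rate > 1) {
    stop("`seizure_rate` must be in [0, 1]", call. = FALSE)
  }
  if (is.character(curriculum)) {
    stages <- stats::setNames(lapply(curriculum, task_preset), curriculum)
  } else {
    stopifnot(all(vapply(curriculum, inherits, logical(1), "forage_task_config")))
    stages <- curriculum
    if (is.null(names(stages))) {
      names(stages) <- vapply(stages, function(cfg) cfg$variant, character(1))
    }
  }
  structure(
    list(n_per_cell = n_per_cell,
         sessions_per_subject = sessions_per_subject,
         curriculum = stages,
         agent_spec = agent_spec,
         effect_size = effect_size,
         latency = latency,
         seizure_rate = seizure_rate,
         master_seed = as.integer(master_seed)),
    class = "forage_cohort_spec"
  )
}

# HET parameter perturbation encoding the injected genotype effect
apply_genotype_effect <- function(agent_spec, effect_size) {
  if (effect_size == 0) return(agent_spec)
  params <- as.list(agent_spec$params %||% list())
  if (agent_spec$type == "q_softmax") {
    params$alpha <- (params$alpha %||% 0.2) * (1 - effect_size)
  } else if (agent_spec$type == "wsls") {
    params$eps <- 1 - (1 - (params$eps %||% 0)) * (1 - effect_size)
  } else {
    warning("effect_size has no defined perturbation for agent type '",
            agent_spec$type, "'; ignored", call. = FALSE)
  }
  agent_spec$params <- params
  agent_spec
}

# deterministic 32-bit-safe seed stream derived from the master seed
derive_seed <- function(master_seed, ...) {
  idx <- c(...)
  s <- as.double(master_seed) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + 10007 * as.double(k) + 1) %% 2147483647
  }
  as.integer(s)
}

#' Generate a labeled synthetic cohort
#'
#' Simulates one session per subject, per session replicate, and per
#' curriculum stage, with subject seeds derived deterministically from the
#' master seed. Identical specs (including `master_seed`) reproduce the
#' cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A `forage_cohort`: a list with `trials` (one row per trial; the
#'   session-log schema plus `stage` and `day` columns) and `subjects`
#'   (one row per subject: `subject_id`, `genotype`, `sex`, `seizure`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "forage_cohort_spec"))
  genotypes <- c("WT", "HET")
  sexes <- c("M", "F")

  subjects <- tidyr::expand_grid(genotype = genotypes, sex = sexes,
                                 cell_idx = seq_len(spec$n_per_cell))
  subjects <- subjects |>
    dplyr::group_by(.data$genotype) |>
    dplyr::mutate(subject_id = sprintf("%s%02d", tolower(.data$genotype),
                                       dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "genotype", "sex")

  set.seed(derive_seed(spec$master_seed, 0L))
  subjects$seizure <- subjects$genotype == "HET" &
    stats::runif(nrow(subjects)) < spec$seizure_rate

  stage_names <- names(spec$curriculum)
  all_trials <- vector("list", nrow(subjects) * length(stage_names) *
                         spec$sessions_per_subject)
  i <- 0L
  for (si in seq_len(nrow(subjects))) {
    subj <- subjects[si, ]
    aspec <- spec$agent_spec
    if (subj$genotype == "HET") {
      aspec <- apply_genotype_effect(aspec, spec$effect_size)
    }
    day <- 0L
    for (gi in seq_along(stage_names)) {
      cfg <- spec$curriculum[[gi]]
      for (rep_i in seq_len(spec$sessions_per_subject)) {
        day <- day + 1L
        seed <- derive_seed(spec$master_seed, si, gi, rep_i)
        agent <- agent_from_spec(aspec)
        trials <- run_session(
          agent, cfg, seed = seed,
          subject_id = subj$subject_id, genotype = subj$genotype,
          sex = subj$sex,
          session_id = sprintf("%s_%s_d%02d", subj$subject_id,
                               stage_names[gi], day),
          latency = spec$latency
        )
        trials$stage <- stage_names[gi]
        trials$day <- day
        i <- i + 1L
        all_trials[[i]] <- trials
      }
    }
  }
  structure(
    list(trials = dplyr::bind_rows(all_trials), subjects = subjects,
         spec = spec),
    class = "forage_cohort"
  )
}

#' Empirical family-wise type-I error of the group-comparison scheme
#'
#' Generates replicate null cohorts (identical agent parameters in both
#' genotypes, `effect_size = 0`), computes per-subject win-stay and
#' lose-switch fractions on the probabilistic task, runs the pairwise
#' Mann-Whitney tests with Bonferroni correction over that metric family,
#' and reports the fraction of replicates in which any adjusted p value
#' falls below `alpha`. Under the null this family-wise rejection rate must
#' not exceed `alpha` (Bonferroni is conservative).
#'
#' @param n_replicates Number of replicate null cohorts.
#' @param n_per_group Subjects per genotype (split evenly across sexes).
#' @param trials_per_session Session length (trials).
#' @param agent_spec Agent spec shared by all subjects.
#' @param alpha Nominal level.
#' @param master_seed Base seed; replicate r uses `master_seed + r`.
#' @return A list with `rate` (family-wise rejection fraction), `se`
#'   (binomial standard error), and `rejected` (logical per replicate).
#' @export
null_rejection_rate <- function(n_replicates = 1000L, n_per_group = 8L,
                                trials_per_session = 200L,
                                agent_spec = list(type = "wsls",
                                                  params = list(eps = 0.15)),
                                alpha = 0.05, master_seed = 0L) {
  if (n_per_group %% 2 != 0) {
    stop("`n_per_group` must be even (split across the two sexes)", call. = FALSE)
  }
  cfg <- task_preset("full_15_60", max_trials = trials_per_session)
  rejected <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    spec <- cohort_spec(
      n_per_cell = n_per_group %/% 2L, sessions_per_subject = 1L,
      curriculum = list(full_15_60 = cfg),
      agent_spec = agent_spec, effect_size = 0,
      latency = NULL, master_seed = master_seed + r
    )
    coh <- generate_cohort(spec)
    m <- wsls_fractions(coh$trials, by = "subject_id") |>
      dplyr::left_join(coh$subjects, by = "subject_id")
    cmp <- compare_groups(m, c("win_stay", "lose_switch"),
                          group = "genotype", alpha = alpha)
    rejected[r] <- any(cmp$significant)
  }
  rate <- mean(rejected)
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_replicates),
       rejected = rejected)
}

#' @export
print.forage_cohort <- function(x, ...) {
  cat("<forage_cohort>", nrow(x$subjects), "subjects,",
      length(unique(x$trials$session_id)), "sessions,",
      nrow(x$trials), "trials\n")
  print(dplyr::count(x$subjects, .data$genotype, .data$sex))
  invisible(x)
}
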