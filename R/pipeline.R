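pipeline_log <- function(stage, ...) {
  message(sprintf("[forage:%s] %s", stage, paste0(...)))
}

#' Run the full simulate-analyze-compare-report pipeline
#'
#' Generates a synthetic cohort, writes the session logs, computes the
#' per-subject metric table and the group-level curves, runs the
#' group-comparison statistics (pairwise Mann-Whitney tests with Bonferroni
#' correction over the metric family, and mixed-design repeated-measures
#' ANOVAs on the learning and reversal-aligned curves), and renders a
#' plain-markdown report. All outputs are deterministic given the spec
#' (including its `master_seed`).
#'
#' @param spec A [cohort_spec()], or the path to a cohort-spec YAML file.
#' @param out_dir Output directory.
#' @param alpha Significance level used throughout the report.
#' @return A run manifest (list): spec hash, master seed, package version,
#'   per-stage output paths, and timestamp. Written as `manifest.json`
#'   (the only output containing the timestamp).
#' @export
pipeline_run <- function(spec, out_dir, alpha = 0.05) {
  if (is.character(spec)) spec <- read_cohort_spec(spec)
  stopifnot(inherits(spec, "forage_cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- simulate -------------------------------------------------------
  pipeline_log("simulate", "master seed ", spec$master_seed,
               ", ", spec$n_per_cell * 4, " subjects")
  cohort <- tryCatch(generate_cohort(spec), error = function(e) {
    stop("pipeline stage 'simulate' failed: ", conditionMessage(e), call. = FALSE)
  })
  write_cohort(cohort, out_dir)

  # -- analyze --------------------------------------------------------
  pipeline_log("analyze", nrow(cohort$trials), " trials")
  trials <- cohort$trials
  full_stages <- unique(trials$stage[startsWith(trials$stage, "full") |
                                       startsWith(trials$stage, "block") |
                                       startsWith(trials$stage, "contingencies")])
  full <- trials[trials$stage %in% full_stages, ]
  if (nrow(full) == 0) full <- trials

  metrics_tbl <- wsls_fractions(full, by = "subject_id") |>
    dplyr::left_join(conditional_iti(full, by = "subject_id"),
                     by = "subject_id") |>
    dplyr::left_join(cohort$subjects, by = "subject_id") |>
    dplyr::relocate("genotype", "sex", .after = "subject_id")
  readr::write_csv(metrics_tbl, file.path(out_dir, "metrics.csv"), na = "")

  lc <- learning_curve(trials[trials$stage == "training_0_100", ])
  if (nrow(lc) > 0) {
    readr::write_csv(lc, file.path(out_dir, "learning_curve.csv"), na = "")
  }
  rc <- reversal_aligned(full, n_after = 10L, by = "genotype")
  readr::write_csv(rc, file.path(out_dir, "reversal_curve.csv"), na = "")

  # -- compare --------------------------------------------------------
  pipeline_log("compare", "pairwise Mann-Whitney with Bonferroni, alpha = ", alpha)
  family <- c("win_stay", "lose_switch", "median_rewarded_s",
              "median_unrewarded_s")
  family <- family[family %in% names(metrics_tbl) &
                     vapply(family, function(cn) !anyNA(metrics_tbl[[cn]]),
                            logical(1))]
  comparisons <- tryCatch(
    compare_groups(metrics_tbl, family, group = "genotype", alpha = alpha),
    error = function(e) {
      stop("pipeline stage 'compare' failed: ", conditionMessage(e), call. = FALSE)
    })

  anovas <- list()
  per_subj_rc <- reversal_aligned(full, n_after = 10L,
                                  by = c("genotype", "subject_id"),
                                  pool = "blocks")
  if (nrow(per_subj_rc) > 0 &&
      all(table(per_subj_rc$subject_id) == max(per_subj_rc$trials_since_reversal))) {
    anovas$reversal <- rm_two_way_anova(per_subj_rc, "p_new_high", "genotype",
                                        "trials_since_reversal", "subject_id")
  }
  if (nrow(lc) > 0 && length(unique(lc$day)) >= 2 &&
      all(table(lc$subject_id) == length(unique(lc$day)))) {
    anovas$learning <- rm_two_way_anova(lc, "p_high", "genotype", "day",
                                        "subject_id")
  }

  stats_out <- list(
    alpha = alpha,
    pairwise = comparisons,
    anova = lapply(anovas, function(a) a$table)
  )
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- report ---------------------------------------------------------
  pipeline_log("report", "writing report.md")
  report_path <- file.path(out_dir, "report.md")
  writeLines(render_report(cohort, comparisons, anovas, alpha), report_path)

  manifest <- list(
    spec_hash = rlang::hash(spec),
    master_seed = spec$master_seed,
    package_version = as.character(utils::packageVersion("foragr")),
    alpha = alpha,
    paths = list(
      sessions = file.path(out_dir, "sessions.csv"),
      subjects = file.path(out_dir, "subjects.csv"),
      metrics = file.path(out_dir, "metrics.csv"),
      reversal_curve = file.path(out_dir, "reversal_curve.csv"),
      stats = file.path(out_dir, "stats.json"),
      report = report_path
    ),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

render_report <- function(cohort, comparisons, anovas, alpha) {
  spec <- cohort$spec
  n_sig <- sum(comparisons$significant)
  lines <- c(
    "# Synthetic foraging cohort report",
    "",
    sprintf("- Subjects: %d (%d per genotype), genotype effect size: %g",
            nrow(cohort$subjects), nrow(cohort$subjects) / 2, spec$effect_size),
    sprintf("- Master seed: %d; trials simulated: %d",
            spec$master_seed, nrow(cohort$trials)),
    sprintf("- Curriculum: %s", paste(names(spec$curriculum), collapse = " -> ")),
    "",
    "## Pairwise genotype comparisons (Mann-Whitney, Bonferroni-corrected)",
    "",
    "| metric | U | n (WT, HET) | p | p (adj) | significant |",
    "|---|---|---|---|---|---|",
    sprintf("| %s | %g | (%d, %d) | %.4g | %.4g | %s |",
            comparisons$metric, comparisons$U, comparisons$n2, comparisons$n1,
            comparisons$p, comparisons$p_adj,
            ifelse(comparisons$significant, "yes", "no")),
    ""
  )
  for (nm in names(anovas)) {
    tab <- anovas[[nm]]$table
    lines <- c(lines,
      sprintf("## Repeated-measures two-way ANOVA: %s curve", nm),
      "",
      "| effect | F | df | p |",
      "|---|---|---|---|",
      sprintf("| %s | %.4g | (%d, %d) | %.4g |",
              tab$effect, tab$statistic, tab$df1, tab$df2, tab$p.value),
      "")
  }
  conclusion <- if (n_sig == 0) {
    sprintf("No genotype effect detected on any metric at alpha = %g.", alpha)
  } else {
    sprintf("Genotype effect flagged (alpha = %g) on: %s.", alpha,
            paste(comparisons$metric[comparisons$significant], collapse = ", "))
  }
  c(lines, "## Conclusion", "", conclusion)
}
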