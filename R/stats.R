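#' Mixed-design (repeated-measures) two-way ANOVA
#'
#' The group-comparison workhorse for per-subject metric curves: one
#' between-subject factor (e.g. genotype) crossed with one within-subject
#' factor (e.g. training day, or trial position since reversal), each
#' subject measured once at every within level. The decomposition uses
#' subject-nested error terms: the group effect is tested against
#' between-subject variation, the within and interaction effects against
#' the subject-by-within residual. No sphericity correction is applied.
#'
#' The design must be complete: every subject needs exactly one observation
#' at every within level, and each group at least two subjects. Missing
#' cells raise an error rather than being silently imputed.
#'
#' @param data A data frame in long format.
#' @param value,group,within,subject Names (strings) of the response,
#'   between-subject factor, within-subject factor, and subject identifier
#'   columns.
#' @return A `forage_rm_anova` object; see [tidy()] / [glance()] methods.
#'   Its `table` element is a tibble with one row per effect (`group`,
#'   `within`, `group:within`) holding F, both degrees of freedom, and the
#'   p value from the F distribution.
#' @export
#' @examples
#' d <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:8), day = 1:3)
#' d$genotype <- rep(c("WT", "HET"), each = 12)
#' set.seed(1); d$y <- rnorm(24)
#' tidy(rm_two_way_anova(d, "y", "genotype", "day", "subject_id"))
rm_two_way_anova <- function(data, value, group, within, subject) {
  cols <- c(value, group, within, subject)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("columns not found in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(
    y = as.numeric(data[[value]]),
    g = factor(data[[group]]),
    w = factor(data[[within]]),
    s = factor(data[[subject]])
  )
  if (anyNA(d$y)) {
    stop("missing values in the response; complete cases are required",
         call. = FALSE)
  }
  counts <- table(d$s, d$w)
  if (any(counts != 1L)) {
    stop("incomplete design: every subject needs exactly one observation ",
         "at every within level", call. = FALSE)
  }
  subj_group <- table(unique(d[, c("s", "g")])$g)
  if (any(subj_group < 2L)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  if (any(table(unique(d[, c("s", "g")])$s) > 1L)) {
    stop("each subject must belong to exactly one group", call. = FALSE)
  }

  fit <- stats::aov(y ~ g * w + Error(s / w), data = d)
  smry <- summary(fit)

  pick <- function(stratum, term) {
    tab <- smry[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(term, rn)
    resid <- match("Residuals", rn)
    tibble::tibble(
      df1 = tab[i, "Df"], df2 = tab[resid, "Df"],
      statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"]
    )
  }
  table <- dplyr::bind_rows(
    dplyr::mutate(pick("Error: s", "g"), effect = "group", .before = 1),
    dplyr::mutate(pick("Error: s:w", "w"), effect = "within", .before = 1),
    dplyr::mutate(pick("Error: s:w", "g:w"), effect = "group:within", .before = 1)
  )
  structure(
    list(table = table, fit = fit,
         factors = list(value = value, group = group, within = within,
                        subject = subject),
         n_subjects = length(unique(d$s)),
         n_levels = length(levels(d$w))),
    class = "forage_rm_anova"
  )
}

#' @export
print.forage_rm_anova <- function(x, ...) {
  cat("Mixed-design repeated-measures ANOVA:", x$factors$value, "~",
      x$factors$group, "x", x$factors$within, "\n")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples, two-sided. U is computed
#' from rank sums with midranks for ties. The p value is exact (full
#' enumeration) when the smaller sample has at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y Numeric samples.
#' @return A `forage_mwu` object with elements `U`, `p_two_sided`, `n1`,
#'   `n2`, `method`; see [tidy()].
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) <= 8
  wt <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = TRUE)
  structure(
    list(U = unname(wt$statistic), p_two_sided = wt$p.value,
         n1 = length(x), n2 = length(y),
         method = if (exact) "exact" else "normal approximation"),
    class = "forage_mwu"
  )
}

#' @export
print.forage_mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s): U = %g, n = (%d, %d), p = %.4g\n",
              x$method, x$U, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

#' Bonferroni correction
#'
#' Adjusts p values for a family of `m` comparisons: `min(1, p * m)`.
#'
#' @param p Numeric vector of p values.
#' @param m Family size; must be at least `length(p)` (defaults to it).
#' @return Adjusted p values.
#' @export
#' @examples
#' bonferroni(c(0.01, 0.5), m = 4)
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) {
    stop("`m` must be at least the number of p values", call. = FALSE)
  }
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Pairwise group comparison of a metric family
#'
#' Runs a two-sided Mann-Whitney U test per metric column between the two
#' levels of the grouping column and applies a Bonferroni correction over
#' the whole family.
#'
#' @param data Per-subject metric table (one row per subject).
#' @param metrics Character vector of metric column names (the comparison
#'   family).
#' @param group Grouping column with exactly two levels.
#' @param alpha Significance level after correction.
#' @return A tibble with one row per metric: `metric`, `U`, `n1`, `n2`,
#'   `p`, `p_adj`, `significant`.
#' @export
compare_groups <- function(data, metrics, group = "genotype", alpha = 0.05) {
  levels <- sort(unique(data[[group]]))
  if (length(levels) != 2) {
    stop("`group` column must have exactly two levels", call. = FALSE)
  }
  res <- purrr::map_dfr(metrics, function(mcol) {
    xv <- data[[mcol]][data[[group]] == levels[1]]
    yv <- data[[mcol]][data[[group]] == levels[2]]
    mwu <- mann_whitney_u(xv, yv)
    tibble::tibble(metric = mcol, U = mwu$U, n1 = mwu$n1, n2 = mwu$n2,
                   p = mwu$p_two_sided)
  })
  res$p_adj <- bonferroni(res$p, m = length(metrics))
  res$significant <- res$p_adj < alpha
  res
}
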