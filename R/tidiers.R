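#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mixed-design ANOVA result
#'
#' @param x A `forage_rm_anova`.
#' @param ... Unused.
#' @return A tibble with one row per effect: `effect`, `df1`, `df2`,
#'   `statistic` (F), `p.value`.
#' @export
tidy.forage_rm_anova <- function(x, ...) {
  x$table
}

#' @rdname tidy.forage_rm_anova
#' @return For `glance()`: a one-row tibble with the design size and the
#'   interaction-term statistics (the headline effect).
#' @export
glance.forage_rm_anova <- function(x, ...) {
  inter <- x$table[x$table$effect == "group:within", ]
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_within_levels = x$n_levels,
    statistic = inter$statistic,
    p.value = inter$p.value
  )
}

#' Tidy a Mann-Whitney U result
#'
#' @param x A `forage_mwu`.
#' @param ... Unused.
#' @return A one-row tibble: `statistic` (U), `p.value`, `n1`, `n2`,
#'   `method`.
#' @export
tidy.forage_mwu <- function(x, ...) {
  tibble::tibble(statistic = x$U, p.value = x$p_two_sided,
                 n1 = x$n1, n2 = x$n2, method = x$method)
}
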