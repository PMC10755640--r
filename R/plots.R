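#' Plot a reversal-aligned choice curve
#'
#' Probability of choosing the new high-probability port as a function of
#' trials since the uncued reversal, optionally split by a grouping column
#' carried in the curve (e.g. genotype).
#'
#' @param object A `forage_reversal_curve` from [reversal_aligned()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.forage_reversal_curve <- function(object, ...) {
  grp <- setdiff(names(object), c("trials_since_reversal", "p_new_high", "n",
                                  "subject_id"))
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$trials_since_reversal,
                                    y = .data$p_new_high))
  if (length(grp) > 0) {
    p <- p + ggplot2::aes(colour = .data[[grp[1]]], group = .data[[grp[1]]])
  }
  p +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Trials since reversal",
                  y = "P(choose new high port)") +
    ggplot2::theme_classic()
}

#' Plot per-day learning curves
#'
#' Group mean (with standard-error ribbon) of the per-subject fraction of
#' high-port choices across training days.
#'
#' @param object A `forage_learning_curve` from [learning_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.forage_learning_curve <- function(object, ...) {
  has_geno <- "genotype" %in% names(object)
  grp_cols <- c(if (has_geno) "genotype", "day")
  summ <- object |>
    dplyr::filter(!is.na(.data$p_high)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_cols))) |>
    dplyr::summarise(mean = mean(.data$p_high),
                     sem = stats::sd(.data$p_high) / sqrt(dplyr::n()),
                     .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$day, y = .data$mean))
  if (has_geno) {
    p <- p + ggplot2::aes(colour = .data$genotype, fill = .data$genotype,
                          group = .data$genotype)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Training day", y = "P(choose high port)") +
    ggplot2::theme_classic()
}

#' Plot a single session's choice trace
#'
#' The 10-trial moving average of left choices overlaid on the programmed
#' left-side contingency (as the step trace of which side is high), the
#' standard single-session view of matching behavior.
#'
#' @param trials One session's trial tibble.
#' @param window Moving-average window (trials).
#' @return A ggplot object.
#' @export
plot_session <- function(trials, window = 10L) {
  stopifnot(length(unique(trials$session_id)) == 1)
  d <- moving_average_choice(trials, window = window)
  d$high_left <- as.numeric(d$high_side == "left")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trial_index)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$high_left),
                       colour = "black", linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ma_left),
                       colour = "darkgreen", na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Trial",
                  y = "P(left)  /  high side (1 = left)",
                  title = unique(trials$session_id)) +
    ggplot2::theme_classic()
}

#' Plot win-stay / lose-switch fractions by group
#'
#' One point per subject, split by strategy fraction and genotype.
#'
#' @param wsls Per-subject output of [wsls_fractions()], joined with a
#'   `genotype` column.
#' @return A ggplot object.
#' @export
plot_wsls <- function(wsls) {
  long <- wsls |>
    tidyr::pivot_longer(cols = c("win_stay", "lose_switch"),
                        names_to = "strategy", values_to = "fraction")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$strategy,
                                          y = .data$fraction))
  if ("genotype" %in% names(long)) {
    p <- p + ggplot2::aes(colour = .data$genotype)
  }
  p +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          position = ggplot2::position_dodge(width = 0.75)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1, dodge.width = 0.75), alpha = 0.6) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Fraction of transitions") +
    ggplot2::theme_classic()
}
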