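# Independent brute-force oracles used to cross-check the package's metric
# and statistics implementations. Everything here is written as plain loops
# over rows, deliberately sharing no code with the package internals.

# win-stay / lose-switch recount by explicit loop over trial pairs
brute_wsls <- function(trials) {
  trials <- trials[order(trials$session_id, trials$trial_index), ]
  wins <- stays <- losses <- switches <- 0
  for (i in 2:nrow(trials)) {
    if (trials$session_id[i] != trials$session_id[i - 1]) next
    a <- trials[i - 1, ]; b <- trials[i, ]
    if (a$choice == "none" || b$choice == "none") next
    if (a$rewarded) {
      wins <- wins + 1
      if (b$choice == a$choice) stays <- stays + 1
    } else {
      losses <- losses + 1
      if (b$choice != a$choice) switches <- switches + 1
    }
  }
  list(win_stay = if (wins > 0) stays / wins else NA_real_,
       lose_switch = if (losses > 0) switches / losses else NA_real_,
       n_win = wins, n_lose = losses)
}

# reversal-aligned recount: per post-reversal block, position-by-position
brute_reversal <- function(trials, n_after, pool = "blocks") {
  per_block <- list()
  for (sid in unique(trials$session_id)) {
    s <- trials[trials$session_id == sid, ]
    s <- s[order(s$trial_index), ]
    for (b in unique(s$block_index)) {
      if (b == 0) next
      blk <- s[s$block_index == b, ]
      per_block[[length(per_block) + 1]] <- blk
    }
  }
  out <- data.frame(position = integer(0), p = numeric(0), n = integer(0))
  for (k in seq_len(n_after)) {
    num <- den <- 0
    subj_num <- list(); subj_den <- list()
    for (blk in per_block) {
      if (nrow(blk) < k) next
      row <- blk[k, ]
      if (row$choice == "none") next
      den <- den + 1
      hit <- row$choice == row$high_side
      num <- num + hit
      sj <- row$subject_id
      subj_num[[sj]] <- (subj_num[[sj]] %||% 0) + hit
      subj_den[[sj]] <- (subj_den[[sj]] %||% 0) + 1
    }
    if (den == 0) next
    if (pool == "blocks") {
      out <- rbind(out, data.frame(position = k, p = num / den, n = den))
    } else {
      fr <- mapply(function(n, d) n / d, subj_num[names(subj_den)], subj_den)
      out <- rbind(out, data.frame(position = k, p = mean(unlist(fr)),
                                   n = length(fr)))
    }
  }
  out
}

# outcome-conditioned ITI recount
brute_iti <- function(trials) {
  trials <- trials[order(trials$session_id, trials$trial_index), ]
  rew <- c(); unrew <- c()
  for (i in 2:nrow(trials)) {
    if (trials$session_id[i] != trials$session_id[i - 1]) next
    if (is.na(trials$iti_s[i])) next
    if (trials$rewarded[i - 1]) rew <- c(rew, trials$iti_s[i])
    else unrew <- c(unrew, trials$iti_s[i])
  }
  list(median_rewarded = stats::median(rew),
       q1_rewarded = unname(stats::quantile(rew, 0.25, type = 7)),
       q3_rewarded = unname(stats::quantile(rew, 0.75, type = 7)),
       median_unrewarded = stats::median(unrew),
       q1_unrewarded = unname(stats::quantile(unrew, 0.25, type = 7)),
       q3_unrewarded = unname(stats::quantile(unrew, 0.75, type = 7)))
}

# exact two-sided Mann-Whitney p by full enumeration of rank assignments
mwu_enumerate <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_obs <- 0
  for (xi in x) for (yi in y) {
    u_obs <- u_obs + (xi > yi) + 0.5 * (xi == yi)
  }
  pooled <- c(x, y)
  idx_sets <- utils::combn(n1 + n2, n1)
  ranks <- rank(pooled)
  u_all <- apply(idx_sets, 2, function(ix) {
    sum(ranks[ix]) - n1 * (n1 + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# textbook mixed-design ANOVA from explicit sums of squares (balanced)
anova_by_hand <- function(d) {
  # d: data.frame with y, g (group), w (within), s (subject)
  grand <- mean(d$y)
  subjects <- unique(d[, c("s", "g")])
  n_s <- nrow(subjects)
  n_g <- length(unique(d$g))
  n_w <- length(unique(d$w))
  subj_means <- tapply(d$y, d$s, mean)
  grp_means <- tapply(d$y, d$g, mean)
  w_means <- tapply(d$y, d$w, mean)
  cell_means <- tapply(d$y, list(d$g, d$w), mean)
  n_per_g <- table(subjects$g)

  ss_between_subj <- n_w * sum((subj_means - grand)^2)
  ss_group <- n_w * sum(n_per_g * (grp_means[names(n_per_g)] - grand)^2)
  ss_subj_err <- ss_between_subj - ss_group
  ss_total <- sum((d$y - grand)^2)
  ss_within_subj <- ss_total - ss_between_subj
  ss_w <- n_s * sum((w_means - grand)^2)
  ss_int <- 0
  for (g in rownames(cell_means)) for (w in colnames(cell_means)) {
    ss_int <- ss_int + n_per_g[[g]] *
      (cell_means[g, w] - grp_means[[g]] - w_means[[w]] + grand)^2
  }
  ss_werr <- ss_within_subj - ss_w - ss_int

  df_g <- n_g - 1; df_serr <- n_s - n_g
  df_w <- n_w - 1; df_int <- df_g * df_w; df_werr <- (n_s - n_g) * df_w
  F_g <- (ss_group / df_g) / (ss_subj_err / df_serr)
  F_w <- (ss_w / df_w) / (ss_werr / df_werr)
  F_int <- (ss_int / df_int) / (ss_werr / df_werr)
  list(
    F_group = F_g, p_group = stats::pf(F_g, df_g, df_serr, lower.tail = FALSE),
    F_within = F_w, p_within = stats::pf(F_w, df_w, df_werr, lower.tail = FALSE),
    F_interaction = F_int,
    p_interaction = stats::pf(F_int, df_int, df_werr, lower.tail = FALSE)
  )
}

# mean of Exp(rate) truncated to [a, b], in closed form
trunc_exp_mean <- function(rate, a, b) {
  # integral of x * rate * exp(-rate x) over [a, b], over the mass in [a, b]
  mass <- exp(-rate * a) - exp(-rate * b)
  num <- (a + 1 / rate) * exp(-rate * a) - (b + 1 / rate) * exp(-rate * b)
  num / mass
}

# mean of the truncated geometric by direct summation over the support
trunc_geom_mean_oracle <- function(mu, lo, hi) {
  k <- lo:hi
  p <- 1 / (mu + 1)
  w <- (1 - p)^k * p
  sum(k * w) / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
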