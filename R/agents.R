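#' Synthetic behaving agents
#'
#' Agents are stateful decision policies that stand in for mice inside
#' [run_session()]. Each agent carries a name, a parameter list, and
#' internal memory (previous choice, action values) that is reset at the
#' start of every session. All agents accept the parameters `p_none`
#' (probability of emitting a no-response on any trial, default 0) and
#' `p_nolick_violation` (per-opportunity probability of a premature lick
#' during the head-fixed no-lick period, default 0).
#'
#' @param eps Lapse rate of the win-stay/lose-switch agent: probability of
#'   choosing uniformly at random instead of following the rule.
#' @param bias Probability that the biased-random agent chooses left.
#' @param alpha Learning rate of the Q-learning agent, in \[0, 1\].
#' @param beta Softmax inverse temperature, nonnegative.
#' @param p_none Probability of a no-response trial.
#' @param p_nolick_violation Premature-lick probability (head-fixed).
#' @return A `forage_agent` object.
#' @name agents
#' @examples
#' a <- agent_wsls()
#' s <- run_session(a, task_preset("training_0_100"), seed = 7)
#' mean(s$rewarded)
NULL

new_agent <- function(name, params, choose_fun, update_fun,
                      reset_fun = function(self) invisible(NULL)) {
  self <- new.env(parent = emptyenv())
  self$name <- name
  self$params <- params
  self$choose_fun <- choose_fun
  self$update_fun <- update_fun
  self$reset_fun <- reset_fun
  class(self) <- "forage_agent"
  self
}

#' @export
print.forage_agent <- function(x, ...) {
  ps <- x$params[!vapply(x$params, is.null, logical(1))]
  cat("<forage_agent>", x$name, "\n  params:",
      paste(names(ps), unlist(ps), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Ask an agent for its next choice
#'
#' @param agent A `forage_agent`.
#' @param high_side Current high-probability side (used only by the ideal
#'   tracker agent).
#' @return `"left"`, `"right"`, or `"none"`.
#' @export
agent_choose <- function(agent, high_side = NULL) {
  p_none <- agent_param(agent, "p_none", 0)
  if (p_none > 0 && stats::runif(1L) < p_none) return("none")
  agent$choose_fun(agent, high_side)
}

#' Inform an agent of the trial outcome
#'
#' @param agent A `forage_agent`.
#' @param choice The choice just made (`"left"`, `"right"`, or `"none"`).
#' @param rewarded Logical outcome.
#' @export
agent_update <- function(agent, choice, rewarded) {
  agent$update_fun(agent, choice, rewarded)
  invisible(agent)
}

#' Reset an agent's internal memory to its initial state
#' @param agent A `forage_agent`.
#' @export
agent_reset <- function(agent) {
  agent$prev_choice <- NULL
  agent$prev_rewarded <- NA
  agent$reset_fun(agent)
  invisible(agent)
}

agent_param <- function(agent, name, default = NULL) {
  v <- agent$params[[name]]
  if (is.null(v)) default else v
}

other_side <- function(side) if (identical(side, "left")) "right" else "left"

#' Win-stay/lose-switch decision rule
#'
#' Repeat the previous choice if it was rewarded, otherwise pick the
#' opposite side. Pure helper underlying [agent_wsls()].
#'
#' @param prev_choice Previous choice, `"left"` or `"right"`.
#' @param prev_rewarded Logical: was the previous trial rewarded?
#' @return `"left"` or `"right"`.
#' @export
#' @examples
#' wsls_choose("left", TRUE)   # stay
#' wsls_choose("left", FALSE)  # switch
wsls_choose <- function(prev_choice, prev_rewarded) {
  stopifnot(prev_choice %in% c("left", "right"))
  if (isTRUE(prev_rewarded)) prev_choice else other_side(prev_choice)
}

#' @rdname agents
#' @export
agent_wsls <- function(eps = 0, p_none = 0, p_nolick_violation = 0) {
  if (eps < 0 || eps > 1) stop("`eps` must be in [0, 1]", call. = FALSE)
  new_agent(
    "wsls",
    list(eps = eps, p_none = p_none, p_nolick_violation = p_nolick_violation),
    choose_fun = function(self, high_side) {
      if (is.null(self$prev_choice)) {
        return(c("left", "right")[1L + (stats::runif(1L) < 0.5)])
      }
      eps <- self$params$eps
      if (eps > 0 && stats::runif(1L) < eps) {
        return(c("left", "right")[1L + (stats::runif(1L) < 0.5)])
      }
      wsls_choose(self$prev_choice, self$prev_rewarded)
    },
    update_fun = function(self, choice, rewarded) {
      if (choice != "none") {
        self$prev_choice <- choice
        self$prev_rewarded <- rewarded
      }
    }
  )
}

#' @rdname agents
#' @export
agent_biased_random <- function(bias = 0.5, p_none = 0, p_nolick_violation = 0) {
  if (bias < 0 || bias > 1) stop("`bias` must be in [0, 1]", call. = FALSE)
  new_agent(
    "biased_random",
    list(bias = bias, p_none = p_none, p_nolick_violation = p_nolick_violation),
    choose_fun = function(self, high_side) {
      if (stats::runif(1L) < self$params$bias) "left" else "right"
    },
    update_fun = function(self, choice, rewarded) invisible(NULL)
  )
}

#' Softmax choice over action values
#'
#' Chooses left with probability `exp(beta * v_left) / (exp(beta * v_left) +
#' exp(beta * v_right))`. Pure helper underlying [agent_q_softmax()].
#'
#' @param values Named or positional numeric pair `(left, right)` of action
#'   values.
#' @param beta Inverse temperature, nonnegative; 0 gives uniform choice.
#' @return `"left"` or `"right"`.
#' @export
q_softmax_choose <- function(values, beta) {
  if (!is.numeric(beta) || beta < 0) {
    stop("`beta` must be nonnegative", call. = FALSE)
  }
  d <- beta * (values[[1L]] - values[[2L]])
  p_left <- 1 / (1 + exp(-d))
  if (stats::runif(1L) < p_left) "left" else "right"
}

#' Delta-rule value update
#'
#' Moves an action value toward the received reward by a step `alpha`.
#'
#' @param value Current action value.
#' @param reward Reward received (0 or 1).
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value.
#' @export
q_value_update <- function(value, reward, alpha) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  }
  value + alpha * (reward - value)
}

#' @rdname agents
#' @export
agent_q_softmax <- function(alpha = 0.2, beta = 3, p_none = 0,
                            p_nolick_violation = 0) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  if (beta < 0) stop("`beta` must be nonnegative", call. = FALSE)
  new_agent(
    "q_softmax",
    list(alpha = alpha, beta = beta, p_none = p_none,
         p_nolick_violation = p_nolick_violation),
    choose_fun = function(self, high_side) {
      q_softmax_choose(self$values, self$params$beta)
    },
    update_fun = function(self, choice, rewarded) {
      if (choice != "none") {
        self$values[[choice]] <- q_value_update(
          self$values[[choice]], as.numeric(rewarded), self$params$alpha
        )
      }
    },
    reset_fun = function(self) {
      self$values <- c(left = 0, right = 0)
    }
  )
}

#' @rdname agents
#' @export
agent_alternator <- function(p_none = 0, p_nolick_violation = 0) {
  new_agent(
    "alternator",
    list(p_none = p_none, p_nolick_violation = p_nolick_violation),
    choose_fun = function(self, high_side) {
      if (is.null(self$prev_choice)) "left" else other_side(self$prev_choice)
    },
    update_fun = function(self, choice, rewarded) {
      if (choice != "none") self$prev_choice <- choice
    }
  )
}

#' @rdname agents
#' @export
agent_ideal <- function(p_none = 0, p_nolick_violation = 0) {
  new_agent(
    "ideal",
    list(p_none = p_none, p_nolick_violation = p_nolick_violation),
    choose_fun = function(self, high_side) high_side,
    update_fun = function(self, choice, rewarded) invisible(NULL)
  )
}

#' Build an agent from a declarative spec
#'
#' Used by cohort YAML configuration: `list(type = "wsls", params =
#' list(eps = 0.1))`. Types: `wsls`, `biased_random`, `q_softmax`,
#' `alternator`, `ideal`.
#'
#' @param spec A list with elements `type` and (optionally) `params`.
#' @return A `forage_agent`.
#' @export
agent_from_spec <- function(spec) {
  ctor <- switch(spec$type,
    wsls = agent_wsls,
    biased_random = agent_biased_random,
    q_softmax = agent_q_softmax,
    alternator = agent_alternator,
    ideal = agent_ideal,
    stop("unknown agent type: '", spec$type, "'", call. = FALSE)
  )
  do.call(ctor, as.list(spec$params %||% list()))
}

#' Outcome-conditioned trial-initiation latency model
#'
#' Self-paced intertrial intervals are modelled as log-normal: strictly
#' positive and right-skewed, with the log-scale location set by the
#' outcome-conditional median and the log-scale SD by `dispersion`. Mice
#' take longer to initiate a trial after a rewarded one, so the default
#' medians are 1.8 s (previously rewarded) and 1.1 s (previously
#' unrewarded); `dispersion = 0` degenerates to the median exactly.
#'
#' @param median_rewarded_s Median ITI following a rewarded trial (seconds).
#' @param median_unrewarded_s Median ITI following an unrewarded trial.
#' @param dispersion Log-scale standard deviation (unitless shape).
#' @return A `forage_latency_model`.
#' @export
latency_model <- function(median_rewarded_s = 1.8, median_unrewarded_s = 1.1,
                          dispersion = 0.4) {
  if (median_rewarded_s <= 0 || median_unrewarded_s <= 0) {
    stop("latency medians must be positive", call. = FALSE)
  }
  if (dispersion < 0) stop("`dispersion` must be nonnegative", call. = FALSE)
  structure(
    list(median_rewarded_s = median_rewarded_s,
         median_unrewarded_s = median_unrewarded_s,
         dispersion = dispersion),
    class = "forage_latency_model"
  )
}

#' Draw intertrial intervals from a latency model
#'
#' @param model A [latency_model()].
#' @param prev_rewarded Logical: was the previous trial rewarded?
#' @param n Number of draws.
#' @return Positive ITI draws (seconds); the distribution is log-normal with
#'   median equal to the outcome-conditional median.
#' @export
sample_iti <- function(model, prev_rewarded, n = 1L) {
  med <- if (isTRUE(prev_rewarded)) model$median_rewarded_s else model$median_unrewarded_s
  med * exp(model$dispersion * stats::rnorm(n))
}
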