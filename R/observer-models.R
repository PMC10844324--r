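# Generative observer models of operant-task timing reports.
#
# All times are in ms with the physical action time anchored at t_A* = 0, so
# the physical outcome time equals the action-outcome interval t_AO. Percepts
# are Gaussian around the physical times (bias b, noise SD sigma); under the
# causal scenario a Gaussian coupling prior N(mu_AO, sigma_AO^2) over the
# interval shrinks the two percepts toward the expected interval, while the
# acausal scenario leaves them untouched.

#' Draw noisy percept pairs for one operant condition
#'
#' Samples `n` independent pairs `(tau_a, tau_o)` with
#' `tau_a ~ N(b_A, sigma_A^2)` and `tau_o ~ N(t_ao + b_O, sigma_O^2)`.
#'
#' @param params [observer_params()] of the observer.
#' @param t_ao Physical action-outcome interval (ms).
#' @param n Number of pairs (>= 1).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A data frame with columns `tau_a` and `tau_o`.
#' @export
#' @examples
#' pp <- sample_percepts(default_observer_params(), t_ao = 250, n = 5, seed = 1)
sample_percepts <- function(params, t_ao, n, seed = NULL) {
  params <- as_observer_params(params)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  with_seed(seed, {
    data.frame(
      tau_a = params$b_a + params$sigma_a * stats::rnorm(n),
      tau_o = t_ao + params$b_o + params$sigma_o * stats::rnorm(n)
    )
  })
}

as_percepts <- function(pp) {
  if (is.data.frame(pp) && all(c("tau_a", "tau_o") %in% names(pp))) {
    if (nrow(pp) < 1) stop("no percept pairs supplied", call. = FALSE)
    return(pp)
  }
  stop("percepts must be a data frame with columns `tau_a` and `tau_o`",
       call. = FALSE)
}

# MAP estimates under the causal scenario; weights are the relative sensory
# variances, dd the discrepancy between perceived and expected interval
.cond_causal <- function(tau_a, tau_o, params, mu_ao) {
  s2 <- sigma_tot2(params)
  dd <- tau_o - tau_a - mu_ao
  list(a = tau_a + (params$sigma_a^2 / s2) * dd,
       o = tau_o - (params$sigma_o^2 / s2) * dd)
}

#' Conditional MAP timing estimates under both causal scenarios
#'
#' Under the causal scenario the action and outcome estimates move toward each
#' other by the reliability-weighted discrepancy between the perceived
#' interval and the prior interval `mu_ao`; under the acausal scenario the
#' estimates equal the raw percepts.
#'
#' @param percepts Data frame with columns `tau_a`, `tau_o` (one row per
#'   trial), e.g. from [sample_percepts()].
#' @param params [observer_params()].
#' @param mu_ao Prior action-outcome interval (ms); 0 under the unity prior.
#' @return Data frame with columns `t_a_causal`, `t_o_causal`,
#'   `t_a_acausal`, `t_o_acausal`.
#' @export
#' @examples
#' pp <- data.frame(tau_a = 0, tau_o = 250)
#' conditional_estimates(pp, observer_params(0, 50, 0, 60), mu_ao = 0)
conditional_estimates <- function(percepts, params, mu_ao = 0) {
  percepts <- as_percepts(percepts)
  params <- as_observer_params(params)
  ce <- .cond_causal(percepts$tau_a, percepts$tau_o, params, mu_ao)
  data.frame(t_a_causal = ce$a, t_o_causal = ce$o,
             t_a_acausal = percepts$tau_a, t_o_acausal = percepts$tau_o)
}

# log odds of the causal scenario given the percepts:
#   causal joint density  p * exp(-dd^2 / 2 s2tot) / (sqrt(2 pi) T s_tot)
#   acausal joint density (1 - p) / T^2
.log_odds_causal <- function(dd, params, p_causal) {
  s2 <- sigma_tot2(params)
  log_l1 <- log(p_causal) - dd^2 / (2 * s2) -
    0.5 * log(2 * pi) - 0.5 * log(s2) - log(params$t_range)
  log_l0 <- log1p(-p_causal) - 2 * log(params$t_range)
  log_l1 - log_l0
}

#' Marginal posterior probability of a causal link
#'
#' `P(xi = 1 | tau_a, tau_o)`, obtained by marginalising the joint posterior
#' over event times in each scenario and normalising across the two
#' scenarios. Drives the model-selection, model-averaging and
#' probability-matching strategies.
#'
#' @inheritParams conditional_estimates
#' @param p_causal Prior causal probability `P(xi = 1)` in \[0, 1\].
#' @return Numeric vector of posterior probabilities in \[0, 1\].
#' @export
#' @examples
#' pp <- data.frame(tau_a = 0, tau_o = 250)
#' marginal_causal_posterior(pp, observer_params(0, 50, 0, 60), 0.5)
marginal_causal_posterior <- function(percepts, params, p_causal, mu_ao = 0) {
  percepts <- as_percepts(percepts)
  params <- as_observer_params(params)
  if (p_causal < 0 || p_causal > 1) {
    stop("`p_causal` must lie in [0, 1]", call. = FALSE)
  }
  dd <- percepts$tau_o - percepts$tau_a - mu_ao
  if (p_causal == 0) return(rep(0, length(dd)))
  if (p_causal == 1) return(rep(1, length(dd)))
  stats::plogis(.log_odds_causal(dd, params, p_causal))
}

#' Ratio of the joint-posterior peaks of the two causal scenarios
#'
#' The peak of the causal joint posterior (at the shrunken MAP estimates)
#' divided by the peak of the acausal joint posterior (at the raw percepts).
#' In closed form
#' `r = [p/(1-p)] * [T / (sqrt(2 pi) sigma_AO)] * exp(-dd^2 / (2 sigma_tot^2))`
#' with `dd = tau_o - tau_a - mu_ao`. A ratio above 1 selects the causal
#' estimates under the joint-posterior strategy. At the prior boundaries the
#' ratio degenerates to 0 (`p_causal = 0`) or `Inf` (`p_causal = 1`); both are
#' returned rather than raised, since bounded optimisation visits them.
#'
#' @inheritParams marginal_causal_posterior
#' @return Numeric vector of non-negative ratios (possibly `Inf`).
#' @export
joint_posterior_ratio <- function(percepts, params, p_causal, mu_ao = 0) {
  percepts <- as_percepts(percepts)
  params <- as_observer_params(params)
  if (p_causal < 0 || p_causal > 1) {
    stop("`p_causal` must lie in [0, 1]", call. = FALSE)
  }
  dd <- percepts$tau_o - percepts$tau_a - mu_ao
  if (p_causal == 0) return(rep(0, length(dd)))
  if (p_causal == 1) return(rep(Inf, length(dd)))
  log_r <- stats::qlogis(p_causal) + log(params$t_range) -
    0.5 * log(2 * pi) - log(params$sigma_ao) - dd^2 / (2 * sigma_tot2(params))
  exp(log_r)
}

# choose causal (est1) or acausal (est0) entries per trial
.pick <- function(causal, est1, est0) {
  out <- est0
  out[causal] <- est1[causal]
  out
}

# Responses of one model for both target events, vectorised over trials.
# `u` is the single per-trial uniform draw shared by the stochastic branches
# (probability-matching scenario choice, false-report swap).
.respond_both <- function(model, free, tau_a, tau_o, params, u) {
  strat <- model$strategy
  if (strat == "null") {
    return(list(action = tau_a, outcome = tau_o))
  }
  if (strat == "false_report") {
    swap <- u < free[["p_fr"]]
    return(list(action = .pick(swap, tau_o, tau_a),
                outcome = .pick(swap, tau_a, tau_o)))
  }
  if (strat == "fixed_criterion") {
    avg <- (tau_a + tau_o) / 2
    integrate <- (tau_o - tau_a) <= free[["phi"]]  # signed comparison
    return(list(action = .pick(integrate, avg, tau_a),
                outcome = .pick(integrate, avg, tau_o)))
  }
  bp <- bci_params(model, free)
  ce <- .cond_causal(tau_a, tau_o, params, bp$mu_ao)
  if (strat == "mandatory") {
    return(list(action = ce$a, outcome = ce$o))
  }
  if (strat == "joint_posterior") {
    dd <- tau_o - tau_a - bp$mu_ao
    causal <- if (bp$p_causal == 0) {
      rep(FALSE, length(dd))
    } else if (bp$p_causal == 1) {
      rep(TRUE, length(dd))
    } else {
      log_r <- stats::qlogis(bp$p_causal) + log(params$t_range) -
        0.5 * log(2 * pi) - log(params$sigma_ao) -
        dd^2 / (2 * sigma_tot2(params))
      log_r > 0
    }
    return(list(action = .pick(causal, ce$a, tau_a),
                outcome = .pick(causal, ce$o, tau_o)))
  }
  # hierarchical strategies need the marginal causal posterior
  dd <- tau_o - tau_a - bp$mu_ao
  post <- if (bp$p_causal == 0) {
    rep(0, length(dd))
  } else if (bp$p_causal == 1) {
    rep(1, length(dd))
  } else {
    stats::plogis(.log_odds_causal(dd, params, bp$p_causal))
  }
  switch(strat,
    model_selection = {
      causal <- post > 0.5
      list(action = .pick(causal, ce$a, tau_a),
           outcome = .pick(causal, ce$o, tau_o))
    },
    probability_matching = {
      causal <- post > u
      list(action = .pick(causal, ce$a, tau_a),
           outcome = .pick(causal, ce$o, tau_o))
    },
    model_averaging = list(
      action = post * ce$a + (1 - post) * tau_a,
      outcome = post * ce$o + (1 - post) * tau_o
    ),
    stop(sprintf("unhandled strategy '%s'", strat), call. = FALSE)
  )
}

#' Model response for one target event
#'
#' Applies a model's decision rule to noisy percept pairs and returns the
#' reported time of the target event for each trial. The uniform draw `u` is
#' supplied externally so that a single per-trial draw drives both the
#' probability-matching scenario choice and the false-report swap; it is
#' ignored by deterministic models.
#'
#' @param model Model id or [model_spec()].
#' @param free Named list of the model's free-parameter values.
#' @param percepts Data frame with columns `tau_a`, `tau_o`.
#' @param params [observer_params()].
#' @param target `"action"` or `"outcome"`: which event is reported.
#' @param u Uniform draws in \[0, 1\], one per trial (scalar recycled).
#'   Required for the stochastic models (`PMup`, `PMcp`, `FR`).
#' @return Numeric vector of reported times (ms), one per trial.
#' @export
#' @examples
#' pp <- data.frame(tau_a = -10, tau_o = 150)
#' respond("FC", list(phi = 200), pp, default_observer_params(), "action")
respond <- function(model, free, percepts, params,
                    target = c("action", "outcome"), u = NULL) {
  model <- as_model_spec(model)
  free <- validate_free_params(model, free)
  percepts <- as_percepts(percepts)
  params <- as_observer_params(params)
  target <- match.arg(target)
  n <- nrow(percepts)
  stochastic <- model$strategy %in% c("probability_matching", "false_report")
  if (is.null(u)) {
    if (stochastic) {
      stop(sprintf("model %s is stochastic: supply per-trial uniform draws `u`",
                   model$id), call. = FALSE)
    }
    u <- rep(0.5, n)
  }
  if (length(u) == 1) u <- rep(u, n)
  if (length(u) != n) {
    stop("`u` must have one draw per percept pair", call. = FALSE)
  }
  if (any(u < 0 | u > 1)) stop("`u` draws must lie in [0, 1]", call. = FALSE)
  both <- .respond_both(model, free, percepts$tau_a, percepts$tau_o, params, u)
  both[[target]]
}
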