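# Monte-Carlo trial likelihoods. Operant reports have no closed-form density
# under most models, so each condition cell's predicted response distribution
# is simulated (n_mc percept pairs pushed through the decision rule) and the
# observed reports are scored under a kernel density estimate of that sample.
# Baseline reports are exact Gaussians and bypass simulation.

#' Configuration of Monte-Carlo likelihood evaluation and fitting
#'
#' @param n_mc Monte-Carlo percept pairs per likelihood evaluation (>= 1000;
#'   default 100,000, the reference scale).
#' @param seed Seed anchoring the common random numbers: the same base draws
#'   are reused across all optimizer evaluations, making the objective
#'   deterministic in the free parameters.
#' @param density Density estimator over the simulated responses:
#'   `"kde"` (Gaussian kernel, Silverman bandwidth; default) or
#'   `"histogram"` (fixed-width bins).
#' @param hist_binwidth Bin width in ms for the histogram estimator.
#' @param likelihood_floor Minimum per-trial density (> 0); keeps the
#'   log-likelihood finite for reports far outside the predicted mass.
#' @param aic_k_offset Constant added to the counted free parameters in the
#'   AIC penalty (default 0; 1 reproduces published AIC tables that count one
#'   extra parameter per model).
#' @param optimizer Named list of deterministic grid-refinement settings:
#'   `stages` (default 3), `n_initial` and `n_refine` (points per dimension;
#'   defaults 17/9 for one free parameter, 9/5 for two).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_mc = 100000, seed = 1L,
                       density = c("kde", "histogram"),
                       hist_binwidth = 5, likelihood_floor = 1e-10,
                       aic_k_offset = 0L, optimizer = list()) {
  density <- match.arg(density)
  if (n_mc < 1000) {
    stop("`n_mc` below 1000 gives unusably noisy likelihoods", call. = FALSE)
  }
  if (likelihood_floor <= 0) {
    stop("`likelihood_floor` must be > 0", call. = FALSE)
  }
  if (hist_binwidth <= 0) stop("`hist_binwidth` must be > 0", call. = FALSE)
  structure(
    list(n_mc = as.integer(n_mc), seed = as.integer(seed), density = density,
         hist_binwidth = hist_binwidth, likelihood_floor = likelihood_floor,
         aic_k_offset = as.integer(aic_k_offset),
         optimizer = optimizer),
    class = "fit_config"
  )
}

as_fit_config <- function(cfg) {
  if (inherits(cfg, "fit_config")) return(cfg)
  stop("`cfg` must be a fit_config()", call. = FALSE)
}

# Base random numbers shared by every objective evaluation of a fit.
# Latin-hypercube draws: each margin is stratified into n_mc equal-probability
# cells (random offset within cell, random pairing across margins), which
# leaves every marginal distribution exact while sharply reducing the
# Monte-Carlo variance of the simulated response distributions.
base_draws <- function(n_mc, seed) {
  with_seed(seed, {
    lhs_unif <- function() {
      (sample.int(n_mc) - stats::runif(n_mc)) / n_mc
    }
    list(
      z_a = stats::qnorm(lhs_unif()),
      z_o = stats::qnorm(lhs_unif()),
      u = lhs_unif()
    )
  })
}

#' Estimate an observer's sensory parameters from baseline trials
#'
#' The baseline report distributions are the sensory-noise distributions of
#' the generative model, so the per-event bias and noise SD are the sample
#' mean and SD (denominator n - 1) of the baseline estimation errors. The
#' coupling-prior SD and normalisation range are fixed constants.
#'
#' @param trials Trial data frame containing baseline trials for both events.
#' @param sigma_ao,t_range Fixed constants passed to [observer_params()].
#' @return An [observer_params()] object.
#' @export
estimate_baseline_params <- function(trials, sigma_ao = 10, t_range = 250) {
  check_trials(trials)
  base <- trials[trials$task == "baseline", , drop = FALSE]
  est <- lapply(c("action", "outcome"), function(target) {
    err <- base$error[base$target == target]
    if (length(err) < 2) {
      stop(sprintf("need at least 2 baseline trials for target '%s'", target),
           call. = FALSE)
    }
    s <- stats::sd(err)
    if (!is.finite(s) || s <= 0) {
      stop(sprintf("degenerate baseline for target '%s': noise SD must be > 0",
                   target), call. = FALSE)
    }
    c(b = mean(err), s = s)
  })
  observer_params(b_a = est[[1]]["b"], sigma_a = est[[1]]["s"],
                  b_o = est[[2]]["b"], sigma_o = est[[2]]["s"],
                  sigma_ao = sigma_ao, t_range = t_range)
}

#' Simulate a model's predicted response sample for one condition cell
#'
#' Draws `n` percept pairs for the condition and pushes them through the
#' model's decision rule; the result is the Monte-Carlo sample whose density
#' approximates the model's response distribution in that cell.
#'
#' @inheritParams respond
#' @param t_ao Physical action-outcome interval of the cell (ms).
#' @param n Number of simulated trials.
#' @param seed Integer seed (the same seed reproduces the same sample).
#' @return Numeric vector of `n` simulated reports (ms).
#' @export
simulate_responses <- function(model, free, params, t_ao,
                               target = c("action", "outcome"),
                               n = 100000, seed = 1L) {
  model <- as_model_spec(model)
  free <- validate_free_params(model, free)
  params <- as_observer_params(params)
  target <- match.arg(target)
  draws <- base_draws(n, seed)
  tau_a <- params$b_a + params$sigma_a * draws$z_a
  tau_o <- t_ao + params$b_o + params$sigma_o * draws$z_o
  both <- .respond_both(model, free, tau_a, tau_o, params, draws$u)
  both[[target]]
}

# Density of `x` under the simulated sample `sims`.
# KDE path: counts in 1-ms bins, then an exact Gaussian kernel sum over the
# +/- 6 bandwidth window around each evaluation point (binning resolution is
# far below any realistic bandwidth). Histogram path: fixed-width bins.
cell_density <- function(sims, x, cfg) {
  n <- length(sims)
  if (cfg$density == "histogram") {
    bw <- cfg$hist_binwidth
    lo <- floor(min(sims) / bw) * bw
    idx <- as.integer(floor((sims - lo) / bw)) + 1L
    nb <- max(idx)
    counts <- tabulate(idx, nb)
    xi <- as.integer(floor((x - lo) / bw)) + 1L
    dens <- numeric(length(x))
    ok <- xi >= 1L & xi <= nb
    dens[ok] <- counts[xi[ok]] / (n * bw)
    return(pmax(dens, cfg$likelihood_floor))
  }
  h <- stats::bw.nrd0(sims)
  if (!is.finite(h) || h <= 0) h <- 1e-6  # degenerate (near-constant) sample
  lo <- as.integer(floor(min(sims)))
  idx <- as.integer(sims - lo) + 1L
  nb <- as.integer(ceiling(max(sims))) - lo + 1L
  counts <- tabulate(idx, nb)
  m <- as.integer(ceiling(6 * h))
  offs <- seq.int(-m, m)
  j0 <- as.integer(floor(x)) - lo + 1L
  jmat <- outer(j0, offs, `+`)
  w <- stats::dnorm((lo + jmat - 0.5) - x, sd = h)
  cnt <- matrix(0, nrow(jmat), ncol(jmat))
  ok <- jmat >= 1L & jmat <= nb
  cnt[ok] <- counts[jmat[ok]]
  pmax(rowSums(cnt * w) / n, cfg$likelihood_floor)
}

#' Per-trial likelihoods under a model
#'
#' Density of each observed report under the model's predicted response
#' distribution. Operant cells are scored against a Monte-Carlo simulation of
#' `cfg$n_mc` trials (one simulation per condition cell, shared by all trials
#' in the cell); baseline trials use the exact Gaussian density implied by the
#' sensory parameters. All densities are floored at `cfg$likelihood_floor`.
#'
#' @inheritParams respond
#' @param trials Trial data frame (baseline and/or operant rows).
#' @param cfg [fit_config()].
#' @param seed Seed for the Monte-Carlo percepts (defaults to `cfg$seed`).
#' @return Numeric vector of per-trial densities, aligned with `trials` rows.
#' @export
mc_likelihood <- function(model, free, params, trials, cfg = fit_config(),
                          seed = cfg$seed) {
  model <- as_model_spec(model)
  free <- validate_free_params(model, free)
  params <- as_observer_params(params)
  cfg <- as_fit_config(cfg)
  check_trials(trials)
  dens <- numeric(nrow(trials))
  is_base <- trials$task == "baseline"
  ba <- is_base & trials$target == "action"
  bo <- is_base & trials$target == "outcome"
  dens[ba] <- stats::dnorm(trials$report[ba], params$b_a, params$sigma_a)
  dens[bo] <- stats::dnorm(trials$report[bo], params$b_o, params$sigma_o)
  op <- which(!is_base)
  if (length(op)) {
    key <- paste(trials$t_ao[op], trials$target[op])
    for (k in unique(key)) {
      rows <- op[key == k]
      sims <- simulate_responses(model, free, params,
                                 t_ao = trials$t_ao[rows[1]],
                                 target = trials$target[rows[1]],
                                 n = cfg$n_mc, seed = seed)
      dens[rows] <- cell_density(sims, trials$report[rows], cfg)
    }
  }
  pmax(dens, cfg$likelihood_floor)
}

# Build the deterministic log-likelihood objective for a dataset.
# Returns list(fn, base_ll, k_obs): fn(free_list) is the summed operant log
# likelihood; base_ll the model-independent baseline constant. Sensory
# parameters are fixed per observer from that observer's own baselines.
make_objective <- function(model, trials, cfg, params = NULL) {
  check_trials(trials)
  ids <- unique(trials$observer_id)
  draws <- base_draws(cfg$n_mc, derive_seed(cfg$seed, 7L))
  floor_ <- cfg$likelihood_floor
  per <- lapply(ids, function(id) {
    tr <- trials[trials$observer_id == id, , drop = FALSE]
    p <- if (is.null(params)) estimate_baseline_params(tr) else
      as_observer_params(params)
    base <- tr[tr$task == "baseline", , drop = FALSE]
    bl <- sum(log(pmax(stats::dnorm(base$report[base$target == "action"],
                                    p$b_a, p$sigma_a), floor_))) +
      sum(log(pmax(stats::dnorm(base$report[base$target == "outcome"],
                                p$b_o, p$sigma_o), floor_)))
    op <- tr[tr$task == "operant", , drop = FALSE]
    if (nrow(op) == 0) {
      stop(sprintf("observer %s has no operant trials", id), call. = FALSE)
    }
    cells <- lapply(split(op, list(op$t_ao, op$target), drop = TRUE),
                    function(cc) list(t_ao = cc$t_ao[1], target = cc$target[1],
                                      reports = cc$report))
    list(params = p, base_ll = bl, cells = cells,
         tau_a = p$b_a + p$sigma_a * draws$z_a,
         tau_o0 = p$b_o + p$sigma_o * draws$z_o)
  })
  fn <- function(free) {
    ll <- 0
    for (ob in per) {
      t_aos <- unique(vapply(ob$cells, `[[`, numeric(1), "t_ao"))
      for (t_ao in t_aos) {
        both <- .respond_both(model, free, ob$tau_a, ob$tau_o0 + t_ao,
                              ob$params, draws$u)
        for (cc in ob$cells) {
          if (cc$t_ao == t_ao) {
            ll <- ll + sum(log(cell_density(both[[cc$target]],
                                            cc$reports, cfg)))
          }
        }
      }
    }
    ll
  }
  list(fn = fn, base_ll = sum(vapply(per, `[[`, numeric(1), "base_ll")),
       params = lapply(per, `[[`, "params"), ids = ids)
}

#' Full-data log-likelihood of a model at given parameter values
#'
#' The summed log Monte-Carlo likelihood of all operant trials plus the exact
#' Gaussian log-likelihood of the baseline trials, with per-observer sensory
#' parameters fixed from each observer's own baselines — the same objective
#' (including the common random numbers) maximised by [fit_model()].
#'
#' @inheritParams mc_likelihood
#' @param params Optional [observer_params()] overriding the per-observer
#'   baseline estimation (see [fit_model()]).
#' @return A single log-likelihood value.
#' @export
log_likelihood <- function(model, free, trials, cfg = fit_config(),
                           params = NULL) {
  model <- as_model_spec(model)
  free <- validate_free_params(model, free)
  cfg <- as_fit_config(cfg)
  obj <- make_objective(model, trials, cfg, params = params)
  obj$fn(free) + obj$base_ll
}
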