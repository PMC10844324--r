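# Bounded maximum-likelihood fitting by deterministic successive grid
# refinement: a coarse grid over the full box, then progressively finer grids
# centred on the running optimum. With common random numbers fixing the
# Monte-Carlo draws, the objective -- and hence the whole fit -- is a pure
# function of the data and configuration.

# maximise fn over the box [lower, upper]; ties resolve to the first
# (lowest-coordinate) grid point, deterministically
optim_grid_refine <- function(fn, lower, upper, control = list()) {
  d <- length(lower)
  stages <- control$stages %||% 3L
  n_init <- control$n_initial %||% (if (d == 1) 17L else 9L)
  n_ref <- control$n_refine %||% (if (d == 1) 9L else 5L)
  lo <- lower
  hi <- upper
  best_par <- NULL
  best_val <- -Inf
  n_eval <- 0L
  for (s in seq_len(stages)) {
    n <- if (s == 1) n_init else n_ref
    grids <- Map(function(l, h) {
      if (h - l < .Machine$double.eps) l else seq(l, h, length.out = n)
    }, lo, hi)
    pts <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    vals <- vapply(seq_len(nrow(pts)), function(i) fn(pts[i, ]),
                   numeric(1))
    n_eval <- n_eval + nrow(pts)
    i <- which.max(vals)
    if (vals[i] > best_val) {
      best_val <- vals[i]
      best_par <- pts[i, ]
    }
    span <- vapply(grids, function(g) {
      if (length(g) > 1) g[2] - g[1] else 0
    }, numeric(1))
    lo <- pmax(lower, best_par - 1.1 * span)
    hi <- pmin(upper, best_par + 1.1 * span)
  }
  list(par = best_par, value = best_val, n_eval = n_eval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Akaike information criterion
#'
#' `AIC = 2 k - 2 log L`; lower values indicate a better fit after penalising
#' the number of counted parameters.
#'
#' @param log_lik Maximised log-likelihood.
#' @param k Number of counted parameters (>= 0).
#' @return The AIC value.
#' @export
#' @examples
#' aic(-131276.07, 2)
aic <- function(log_lik, k) {
  if (k < 0) stop("`k` must be >= 0", call. = FALSE)
  2 * k - 2 * log_lik
}

#' Fit one model to a trial dataset by Monte-Carlo maximum likelihood
#'
#' Estimates the model's free parameters by maximising the summed log
#' Monte-Carlo likelihood of the operant trials within the shared parameter
#' bounds ([free_param_bounds()]). Each observer's sensory parameters are
#' fixed from that observer's own baseline trials, whose exact Gaussian
#' log-likelihood enters as a model-independent constant. With more than one
#' observer the free parameters are shared (group-level fit). The Monte-Carlo
#' percepts are fixed across optimizer evaluations (common random numbers),
#' so two calls with identical data and configuration return identical
#' results.
#'
#' @param model Model id or [model_spec()].
#' @param trials Trial data frame with baseline and operant rows.
#' @param cfg [fit_config()].
#' @param params Optional [observer_params()] applied to every observer in
#'   place of the per-observer baseline estimates. Used by the recovery
#'   pipelines, where the generating sensory parameters are known and
#'   conditioning on them isolates the free parameters under study.
#' @return An object of class `binding_fit`: list with elements `model`,
#'   `estimates` (named list), `log_lik`, `k`, `aic` and `diagnostics`.
#' @export
#' @examples
#' \donttest{
#' trials <- simulate_observer("FC", list(phi = 300),
#'                             design = design_spec(trials_per_condition = 20),
#'                             seed = 1)
#' fit_model("FC", trials, fit_config(n_mc = 2000))
#' }
fit_model <- function(model, trials, cfg = fit_config(), params = NULL) {
  model <- as_model_spec(model)
  cfg <- as_fit_config(cfg)
  obj <- make_objective(model, trials, cfg, params = params)
  bounds <- free_param_bounds()
  k_free <- n_free(model)
  if (k_free == 0) {
    opt <- list(par = numeric(0), value = obj$fn(list()), n_eval = 1L)
  } else {
    lower <- vapply(model$free, function(nm) bounds[[nm]][1], numeric(1))
    upper <- vapply(model$free, function(nm) bounds[[nm]][2], numeric(1))
    fn <- function(v) {
      free <- as.list(v)
      names(free) <- model$free
      obj$fn(free)
    }
    opt <- optim_grid_refine(fn, lower, upper, cfg$optimizer)
  }
  estimates <- as.list(opt$par)
  names(estimates) <- model$free
  ll <- opt$value + obj$base_ll
  k <- k_free + cfg$aic_k_offset
  structure(
    list(model = model$id, estimates = estimates, log_lik = ll, k = k,
         aic = aic(ll, k),
         diagnostics = list(n_eval = opt$n_eval, converged = TRUE,
                            baseline_log_lik = obj$base_ll,
                            n_observers = length(obj$ids),
                            operant_log_lik = opt$value)),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Model %s fit (%d observer%s)\n", x$model,
              x$diagnostics$n_observers,
              if (x$diagnostics$n_observers > 1) "s" else ""))
  if (length(x$estimates)) {
    cat("  estimates:",
        paste(sprintf("%s = %.4g", names(x$estimates),
                      unlist(x$estimates)), collapse = ", "), "\n")
  } else {
    cat("  estimates: (no free parameters)\n")
  }
  cat(sprintf("  log-likelihood %.2f, k = %d, AIC %.2f\n",
              x$log_lik, x$k, x$aic))
  invisible(x)
}

#' Fit several models to the same dataset
#'
#' @param models Character vector of model ids (default: the 12 candidate
#'   models, null model excluded).
#' @inheritParams fit_model
#' @return A list of `binding_fit` objects (class `binding_fit_list`), with
#'   an [as.data.frame()] method giving one row per model: estimates,
#'   log-likelihood, `k` and AIC.
#' @export
fit_models <- function(models = model_ids(candidates_only = TRUE), trials,
                       cfg = fit_config(), params = NULL) {
  fits <- lapply(models, fit_model, trials = trials, cfg = cfg,
                 params = params)
  names(fits) <- models
  structure(fits, class = "binding_fit_list")
}

#' @export
as.data.frame.binding_fit_list <- function(x, ...) {
  pars <- names(free_param_bounds())
  rows <- lapply(x, function(f) {
    row <- data.frame(model = f$model, stringsAsFactors = FALSE)
    for (p in pars) {
      row[[p]] <- if (p %in% names(f$estimates)) f$estimates[[p]] else NA_real_
    }
    row$log_lik <- f$log_lik
    row$k <- f$k
    row$aic <- f$aic
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# AIC-ranked best model with deterministic tie-breaking: minimum AIC, ties
# broken toward fewer free parameters, then alphabetical model id
best_fit <- function(fits) {
  tab <- as.data.frame(fits)
  kf <- vapply(tab$model, function(m) n_free(model_spec(m)), numeric(1))
  ord <- order(tab$aic, kf, tab$model)
  tab$model[ord[1]]
}
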