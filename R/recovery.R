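# Parameter- and model-recovery pipelines: simulate ideal observers with
# known parameters, refit, and ask whether parameters and generating models
# are identifiable under the experimental design.

recoverable_models <- function() {
  ids <- model_ids(candidates_only = TRUE)
  ids[vapply(ids, function(m) n_free(model_spec(m)) > 0, logical(1))]
}

#' Parameter recovery
#'
#' For each model with at least one free parameter: draw ground-truth
#' parameters uniformly from their ranges, simulate a full session for each
#' ideal observer, refit the generating model, and collect (true, recovered)
#' pairs. `summary()` reports the Pearson correlation per model-parameter
#' pair together with the t statistic and p value of the test of no
#' correlation (descriptive only).
#'
#' @param models Model ids to recover (default: all candidate models with
#'   free parameters; models without free parameters are rejected).
#' @param n_observers Simulated observers per model.
#' @param design [design_spec()] for each simulated session.
#' @param cfg [fit_config()] used for every fit.
#' @param seed Master seed; every sampled parameter set, simulated session
#'   and fit derives its own child stream from it.
#' @param params Sensory parameters of the ideal observers (default: the
#'   study's group baselines; recovery keeps them fixed across observers).
#'   The refits condition on these known generating values instead of
#'   re-estimating them from the simulated baselines, so the recovery
#'   isolates the free parameters under study.
#' @param keep_data Keep the simulated trial tables (needed by
#'   [run_model_recovery()]).
#' @param verbose Print progress per model.
#' @return An object of class `parameter_recovery`: list with `pairs` (data
#'   frame model/parameter/observer/true/recovered), `datasets`, `seed`,
#'   `design`, `cfg`, `params`.
#' @export
#' @examples
#' \donttest{
#' rec <- run_parameter_recovery("FC", n_observers = 3,
#'                               design = design_spec(trials_per_condition = 10),
#'                               cfg = fit_config(n_mc = 2000), seed = 1)
#' summary(rec)
#' }
run_parameter_recovery <- function(models = recoverable_models(),
                                   n_observers = 20,
                                   design = design_spec(),
                                   cfg = fit_config(n_mc = 20000),
                                   seed = 1L,
                                   params = default_observer_params(),
                                   keep_data = TRUE,
                                   verbose = FALSE) {
  cfg <- as_fit_config(cfg)
  for (m in models) {
    if (n_free(model_spec(m)) == 0) {
      stop(sprintf("model %s has no free parameters to recover", m),
           call. = FALSE)
    }
  }
  pairs <- list()
  datasets <- list()
  n_failed <- 0L
  for (m in models) {
    spec <- model_spec(m)
    m_idx <- match(m, model_ids())
    if (verbose) message("recovering ", m)
    for (i in seq_len(n_observers)) {
      sseed <- derive_seed(seed, m_idx, i)
      truth <- sample_free_params(spec, seed = derive_seed(sseed, 1L))
      trials <- simulate_observer(spec, truth, params, design,
                                  seed = derive_seed(sseed, 2L),
                                  observer_id = i)
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(sseed, 3L)
      fit <- tryCatch(fit_model(spec, trials, cfg_i, params = params),
                      error = identity)
      if (inherits(fit, "error")) {
        n_failed <- n_failed + 1L
        warning(sprintf("fit failed for %s observer %d: %s", m, i,
                        conditionMessage(fit)), call. = FALSE)
        next
      }
      pairs[[length(pairs) + 1L]] <- data.frame(
        model = m, parameter = spec$free, observer = i,
        true = unlist(truth[spec$free]),
        recovered = unlist(fit$estimates[spec$free]),
        stringsAsFactors = FALSE
      )
      if (keep_data) {
        datasets[[length(datasets) + 1L]] <- list(
          model = m, observer = i, free = truth, trials = trials,
          seed = sseed
        )
      }
    }
  }
  pairs <- do.call(rbind, c(pairs, list(make.row.names = FALSE)))
  structure(
    list(pairs = pairs, datasets = datasets, seed = seed, design = design,
         cfg = cfg, params = params, n_failed = n_failed),
    class = "parameter_recovery"
  )
}

#' @export
summary.parameter_recovery <- function(object, ...) {
  sp <- split(object$pairs,
              list(object$pairs$model, object$pairs$parameter), drop = TRUE)
  rows <- lapply(sp, function(d) {
    n <- nrow(d)
    r <- if (stats::sd(d$true) > 0 && stats::sd(d$recovered) > 0) {
      stats::cor(d$true, d$recovered)
    } else {
      NA_real_
    }
    tt <- if (is.finite(r) && abs(r) < 1 && n > 2) {
      r * sqrt(n - 2) / sqrt(1 - r^2)
    } else {
      NA_real_
    }
    data.frame(model = d$model[1], parameter = d$parameter[1], n = n,
               r = r, t = tt,
               p = if (is.na(tt)) NA_real_ else
                 2 * stats::pt(-abs(tt), n - 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$model, model_ids()), out$parameter), ]
  rownames(out) <- NULL
  attr(out, "mean_r") <- mean(out$r, na.rm = TRUE)
  class(out) <- c("parameter_recovery_summary", "data.frame")
  out
}

#' @export
print.parameter_recovery_summary <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 3)
  cat(sprintf("\nMean Pearson r across model-parameter pairs: %.3f\n",
              attr(x, "mean_r")))
  invisible(x)
}

#' @export
print.parameter_recovery <- function(x, ...) {
  cat(sprintf(
    "Parameter recovery: %d models, %d (true, recovered) pairs%s\n",
    length(unique(x$pairs$model)), nrow(x$pairs),
    if (x$n_failed) sprintf(" (%d failed fits excluded)", x$n_failed) else ""))
  print(summary(x))
  invisible(x)
}

#' Model recovery (best-fit confusion matrix)
#'
#' Fits every candidate model to every dataset simulated during parameter
#' recovery and tabulates, per generating model, the proportion of datasets
#' each candidate explains best under the AIC (minimum AIC; ties broken
#' toward fewer free parameters, then alphabetical id). Generating models
#' absent from the parameter-recovery run because they have no free
#' parameters (the unity-prior mandatory-integration model) get their
#' datasets simulated here, seeded from the recovery's master seed, so the
#' matrix covers all 12 candidates.
#'
#' @param recovery A [run_parameter_recovery()] result with `keep_data = TRUE`.
#' @param models Candidate (row) models; default all 12.
#' @param cfg [fit_config()] for the refits (default: the recovery's).
#' @param max_observers Optional cap on datasets per generating model (the
#'   first `max_observers` observers), to bound refit cost.
#' @param verbose Print progress per generator.
#' @return An object of class `model_recovery`: `proportions` and `counts`
#'   matrices (rows = fitted model, columns = generating model) and
#'   `n_per_column`.
#' @export
run_model_recovery <- function(recovery,
                               models = model_ids(candidates_only = TRUE),
                               cfg = recovery$cfg,
                               max_observers = NULL,
                               verbose = FALSE) {
  if (!inherits(recovery, "parameter_recovery")) {
    stop("`recovery` must come from run_parameter_recovery()", call. = FALSE)
  }
  if (!length(recovery$datasets)) {
    stop("recovery was run with keep_data = FALSE; no datasets to refit",
         call. = FALSE)
  }
  cfg <- as_fit_config(cfg)
  datasets <- recovery$datasets
  gens <- vapply(datasets, `[[`, character(1), "model")
  # simulate datasets for parameter-free generators missing from recovery
  missing <- setdiff(models, unique(gens))
  n_obs <- max(table(gens))
  if (!is.null(max_observers)) n_obs <- min(n_obs, max_observers)
  for (m in missing) {
    spec <- model_spec(m)
    if (n_free(spec) > 0) next  # only parameter-free models are synthesised
    m_idx <- match(m, model_ids())
    for (i in seq_len(n_obs)) {
      sseed <- derive_seed(recovery$seed, m_idx, i)
      trials <- simulate_observer(spec, list(), recovery$params,
                                  recovery$design,
                                  seed = derive_seed(sseed, 2L),
                                  observer_id = i)
      datasets[[length(datasets) + 1L]] <- list(model = m, observer = i,
                                                free = list(),
                                                trials = trials, seed = sseed)
    }
  }
  gens <- vapply(datasets, `[[`, character(1), "model")
  keep <- gens %in% models
  if (!is.null(max_observers)) {
    obs <- vapply(datasets, `[[`, numeric(1), "observer")
    keep <- keep & obs <= max_observers
  }
  datasets <- datasets[keep]
  gens <- gens[keep]
  counts <- matrix(0L, length(models), length(models),
                   dimnames = list(fitted = models, generator = models))
  for (j in seq_along(datasets)) {
    d <- datasets[[j]]
    if (verbose) message(sprintf("refit %d/%d (generator %s)",
                                 j, length(datasets), d$model))
    cfg_j <- cfg
    cfg_j$seed <- derive_seed(d$seed, 4L)
    fits <- fit_models(models, d$trials, cfg_j, params = recovery$params)
    winner <- best_fit(fits)
    counts[winner, d$model] <- counts[winner, d$model] + 1L
  }
  n_col <- colSums(counts)
  if (any(n_col == 0)) {
    stop("no datasets for generating model(s): ",
         paste(models[n_col == 0], collapse = ", "), call. = FALSE)
  }
  structure(
    list(proportions = sweep(counts, 2, n_col, "/"), counts = counts,
         n_per_column = n_col),
    class = "model_recovery"
  )
}

#' @export
print.model_recovery <- function(x, ...) {
  cat("Model recovery matrix (column = generating model,",
      "cell = proportion best-fit by row model):\n")
  print(round(x$proportions, 2))
  invisible(x)
}
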