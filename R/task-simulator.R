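# Synthetic Libet-clock experiment: 2 baseline tasks (keypress, tone) and
# 2 operant tasks (report keypress / report tone) crossed with the
# action-outcome intervals. Baseline reports are raw percepts; operant
# reports pass through a model's decision rule.

#' Experimental design of the simulated clock study
#'
#' The default reproduces the reference design: intervals 0/250/500 ms and
#' 60 trials per condition, i.e. 8 condition cells (baseline action, baseline
#' outcome, operant action x 3 intervals, operant outcome x 3 intervals) and
#' 480 trials per observer, for 76 observers.
#'
#' @param intervals Operant action-outcome intervals (ms).
#' @param trials_per_condition Trials per condition cell.
#' @param n_observers Number of observers simulated by [simulate_experiment()].
#' @return An object of class `design_spec`.
#' @export
#' @examples
#' design_spec()
design_spec <- function(intervals = c(0, 250, 500),
                        trials_per_condition = 60,
                        n_observers = 76) {
  if (length(intervals) < 1 || anyNA(intervals)) {
    stop("`intervals` must contain at least one interval", call. = FALSE)
  }
  if (trials_per_condition < 1) {
    stop("`trials_per_condition` must be >= 1", call. = FALSE)
  }
  if (n_observers < 1) stop("`n_observers` must be >= 1", call. = FALSE)
  structure(
    list(intervals = as.numeric(intervals),
         trials_per_condition = as.integer(trials_per_condition),
         n_observers = as.integer(n_observers)),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  n_cells <- 2 + 2 * length(x$intervals)
  cat(sprintf(
    "Design: intervals [%s] ms, %d trials/condition, %d observers\n",
    paste(x$intervals, collapse = ", "), x$trials_per_condition,
    x$n_observers))
  cat(sprintf("  %d condition cells x %d trials = %d trials per observer\n",
              n_cells, x$trials_per_condition,
              n_cells * x$trials_per_condition))
  invisible(x)
}

#' Draw free parameters uniformly from their ranges
#'
#' Each of the model's free parameters is sampled independently and uniformly
#' from its bound in [free_param_bounds()]; this defines the ground-truth
#' parameter distribution of the recovery analyses.
#'
#' @param model Model id or [model_spec()]; must have at least one free
#'   parameter.
#' @param seed Optional integer seed.
#' @return Named list of sampled values.
#' @export
#' @examples
#' sample_free_params("PMcp", seed = 1)
sample_free_params <- function(model, seed = NULL) {
  model <- as_model_spec(model)
  if (n_free(model) == 0) {
    stop(sprintf("model %s has no free parameters to sample", model$id),
         call. = FALSE)
  }
  bounds <- free_param_bounds()
  with_seed(seed, {
    vals <- lapply(model$free, function(nm) {
      b <- bounds[[nm]]
      stats::runif(1, b[1], b[2])
    })
    names(vals) <- model$free
    vals
  })
}

.trial_cols <- c("observer_id", "task", "target", "t_ao", "report", "error")

check_trials <- function(trials) {
  if (!is.data.frame(trials) || !all(.trial_cols %in% names(trials))) {
    stop(sprintf("trial table must contain columns: %s",
                 paste(.trial_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(trials)
}

#' Simulate one observer's full session under a generating model
#'
#' Baseline trials report the raw percept of the single event; operant trials
#' report the generating model's response for the block's target event. The
#' estimation error is the report minus the physical target time (which is 0
#' for action targets and `t_ao` for outcome targets). One uniform draw per
#' operant trial feeds the stochastic models.
#'
#' @param model Generating model id or [model_spec()].
#' @param free Named list of the model's free-parameter values (empty for
#'   parameter-free models).
#' @param params [observer_params()] of the simulated observer.
#' @param design [design_spec()] (its `n_observers` field is ignored here).
#' @param seed Optional integer seed giving this observer its own stream.
#' @param observer_id Identifier stored in the trial table.
#' @return A trial data frame with columns `observer_id`, `task`
#'   (baseline/operant), `target` (action/outcome), `t_ao`, `report`, `error`.
#' @seealso [simulate_experiment()] for a multi-observer dataset.
#' @export
#' @examples
#' trials <- simulate_observer("NULL", list(), default_observer_params(),
#'                             design_spec(trials_per_condition = 5), seed = 1)
#' table(trials$task, trials$target)
simulate_observer <- function(model, free = list(),
                              params = default_observer_params(),
                              design = design_spec(), seed = NULL,
                              observer_id = 1L) {
  model <- as_model_spec(model)
  free <- validate_free_params(model, free)
  params <- as_observer_params(params)
  if (!inherits(design, "design_spec")) {
    stop("`design` must be a design_spec()", call. = FALSE)
  }
  k <- design$trials_per_condition
  cell <- function(task, target, t_ao, report) {
    actual <- if (target == "action") 0 else t_ao
    data.frame(observer_id = observer_id, task = task, target = target,
               t_ao = t_ao, report = report, error = report - actual,
               stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    out <- vector("list", 2 + 2 * length(design$intervals))
    # baseline cells: single event, raw percept, frame anchored at the event
    out[[1]] <- cell("baseline", "action", 0,
                     params$b_a + params$sigma_a * stats::rnorm(k))
    out[[2]] <- cell("baseline", "outcome", 0,
                     params$b_o + params$sigma_o * stats::rnorm(k))
    i <- 3
    for (t_ao in design$intervals) {
      for (target in c("action", "outcome")) {
        pp <- data.frame(
          tau_a = params$b_a + params$sigma_a * stats::rnorm(k),
          tau_o = t_ao + params$b_o + params$sigma_o * stats::rnorm(k)
        )
        u <- stats::runif(k)
        rep_t <- respond(model, free, pp, params, target, u)
        out[[i]] <- cell("operant", target, t_ao, rep_t)
        i <- i + 1
      }
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Simulate a multi-observer experiment
#'
#' Stacks [simulate_observer()] sessions for `design$n_observers` observers,
#' all generated by the same model and free parameters. Each observer gets an
#' independent child stream derived from the master seed, so any single
#' observer can be regenerated in isolation.
#'
#' @inheritParams simulate_observer
#' @param seed Master seed; observer `i` uses `derive_seed(seed, i)`.
#' @return A trial data frame covering all observers.
#' @export
simulate_experiment <- function(model, free = list(),
                                params = default_observer_params(),
                                design = design_spec(), seed = 1L) {
  out <- lapply(seq_len(design$n_observers), function(i) {
    simulate_observer(model, free, params, design,
                      seed = derive_seed(seed, i), observer_id = i)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read / write trial tables
#'
#' Plain CSV with the canonical column header
#' `observer_id, task, target, t_ao, report, error`; the round trip is
#' loss-free to numeric precision.
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @return `read_trials()` returns the trial data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  utils::write.csv(trials[, .trial_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_trials(trials)
  trials
}
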