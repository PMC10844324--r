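# Descriptive summaries of trial tables: per-cell estimation errors and the
# classic temporal-binding indices (perceptual shifts from baseline and their
# summed compression).

#' Per-condition estimation-error summaries
#'
#' Mean, SD and trial count of the estimation error for every
#' observer x task x target x interval cell present in the data.
#'
#' @param trials Trial data frame (see [simulate_observer()] for the layout).
#' @return Data frame with columns `observer_id`, `task`, `target`, `t_ao`,
#'   `mean_error`, `sd_error`, `n`.
#' @export
estimation_errors <- function(trials) {
  check_trials(trials)
  key <- list(observer_id = trials$observer_id, task = trials$task,
              target = trials$target, t_ao = trials$t_ao)
  mu <- stats::aggregate(trials["error"], key, mean)
  sdv <- stats::aggregate(trials["error"], key, stats::sd)
  nn <- stats::aggregate(trials["error"], key, length)
  out <- mu
  names(out)[names(out) == "error"] <- "mean_error"
  out$sd_error <- sdv$error
  out$n <- nn$error
  out <- out[order(out$observer_id, out$task, out$target, out$t_ao), ]
  rownames(out) <- NULL
  out
}

#' Temporal-binding indices per observer and interval
#'
#' For each observer and operant interval: the action shift (mean operant
#' action error minus mean baseline action error), the outcome shift (same
#' for the outcome event), and the summed compression
#' `action_shift - outcome_shift`. Binding overestimates the action (positive
#' shift) and underestimates the outcome (negative shift), so compression is
#' positive exactly when the perceived interval contracted. The indices are
#' invariant to shifting all reports and physical times by a constant.
#'
#' @param x Either a trial data frame or an error table from
#'   [estimation_errors()].
#' @return Data frame with columns `observer_id`, `t_ao`, `action_shift`,
#'   `outcome_shift`, `compression` (all ms).
#' @export
#' @examples
#' trials <- simulate_observer("MIup", list(),
#'                             design = design_spec(trials_per_condition = 20),
#'                             seed = 1)
#' binding_indices(trials)
binding_indices <- function(x) {
  errors <- if (is.data.frame(x) && "report" %in% names(x)) {
    estimation_errors(x)
  } else {
    x
  }
  need <- c("observer_id", "task", "target", "t_ao", "mean_error")
  if (!is.data.frame(errors) || !all(need %in% names(errors))) {
    stop("input must be a trial table or an estimation_errors() table",
         call. = FALSE)
  }
  out <- lapply(unique(errors$observer_id), function(id) {
    e <- errors[errors$observer_id == id, , drop = FALSE]
    base_a <- e$mean_error[e$task == "baseline" & e$target == "action"]
    base_o <- e$mean_error[e$task == "baseline" & e$target == "outcome"]
    if (length(base_a) != 1 || length(base_o) != 1) {
      stop(sprintf("observer %s lacks a baseline cell for one of the events",
                   id), call. = FALSE)
    }
    op <- e[e$task == "operant", , drop = FALSE]
    rows <- lapply(sort(unique(op$t_ao)), function(t_ao) {
      oa <- op$mean_error[op$target == "action" & op$t_ao == t_ao]
      oo <- op$mean_error[op$target == "outcome" & op$t_ao == t_ao]
      if (length(oa) != 1 || length(oo) != 1) {
        stop(sprintf(
          "observer %s lacks an operant cell at interval %g",
          id, t_ao), call. = FALSE)
      }
      a_shift <- oa - base_a
      o_shift <- oo - base_o
      data.frame(observer_id = id, t_ao = t_ao, action_shift = a_shift,
                 outcome_shift = o_shift, compression = a_shift - o_shift)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  out
}
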