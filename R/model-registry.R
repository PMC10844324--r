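# Registry of the thirteen observer models (12 candidates + the null model).
#
# Naming follows the field's shorthand: the capital letters give the response
# strategy (JP joint posterior, MS model selection, MA model averaging,
# PM probability matching, MI mandatory integration, FC fixed criterion,
# FR false report), the lowercase suffix the temporal prior (up = unity prior,
# mu_AO fixed at 0; cp = coupling prior, mu_AO free).

.model_registry <- local({
  mk <- function(id, prior, strategy, free, fixed = list()) {
    list(id = id, prior = prior, strategy = strategy,
         free = free, fixed = fixed)
  }
  specs <- list(
    mk("JPup", "unity",    "joint_posterior",      "p_causal", list(mu_ao = 0)),
    mk("MSup", "unity",    "model_selection",      "p_causal", list(mu_ao = 0)),
    mk("MAup", "unity",    "model_averaging",      "p_causal", list(mu_ao = 0)),
    mk("PMup", "unity",    "probability_matching", "p_causal", list(mu_ao = 0)),
    mk("MIup", "unity",    "mandatory",            character(0),
       list(p_causal = 1, mu_ao = 0)),
    mk("JPcp", "coupling", "joint_posterior",      c("p_causal", "mu_ao")),
    mk("MScp", "coupling", "model_selection",      c("p_causal", "mu_ao")),
    mk("MAcp", "coupling", "model_averaging",      c("p_causal", "mu_ao")),
    mk("PMcp", "coupling", "probability_matching", c("p_causal", "mu_ao")),
    mk("MIcp", "coupling", "mandatory",            "mu_ao", list(p_causal = 1)),
    mk("FC",   "none",     "fixed_criterion",      "phi"),
    mk("FR",   "none",     "false_report",         "p_fr"),
    mk("NULL", "none",     "null",                 character(0))
  )
  names(specs) <- vapply(specs, `[[`, character(1), "id")
  specs
})

#' Model identifiers
#'
#' @param candidates_only If `TRUE`, return only the 12 candidate models,
#'   dropping the parameter-free null model.
#' @return Character vector of model ids in canonical (display) order.
#' @export
#' @examples
#' model_ids()
model_ids <- function(candidates_only = FALSE) {
  ids <- names(.model_registry)
  if (candidates_only) ids <- setdiff(ids, "NULL")
  ids
}

#' Look up a model specification
#'
#' Returns the specification of one of the thirteen observer models: its
#' temporal-prior type (`unity`, `coupling` or `none`), response strategy,
#' free-parameter names (in fitting order) and fixed-parameter values.
#'
#' @param id Model id, one of [model_ids()].
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("PMcp")
model_spec <- function(id) {
  id <- as.character(id)[1]
  spec <- .model_registry[[id]]
  if (is.null(spec)) {
    stop(sprintf("unknown model id '%s'; see model_ids()", id), call. = FALSE)
  }
  structure(spec, class = "model_spec")
}

as_model_spec <- function(x) {
  if (inherits(x, "model_spec")) return(x)
  model_spec(x)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %s: strategy '%s', temporal prior '%s'\n",
              x$id, x$strategy, x$prior))
  if (length(x$free)) {
    cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  } else {
    cat("  free parameters: none\n")
  }
  if (length(x$fixed)) {
    cat("  fixed:", paste(sprintf("%s = %g", names(x$fixed),
                                  unlist(x$fixed)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bounds of the free parameters
#'
#' The closed search/sampling ranges shared by parameter recovery and model
#' fitting: `p_causal` in \[0, 1\], `mu_ao` in \[0, 500\] ms, `phi` in
#' \[0, 1000\] ms, `p_fr` in \[0, 1\].
#'
#' @return Named list of `c(lower, upper)` vectors.
#' @export
free_param_bounds <- function() {
  list(p_causal = c(0, 1), mu_ao = c(0, 500),
       phi = c(0, 1000), p_fr = c(0, 1))
}

n_free <- function(model) length(as_model_spec(model)$free)

#' Validate a set of free-parameter values for a model
#'
#' Checks that exactly the model's free parameters are supplied, each a finite
#' scalar inside its bound.
#'
#' @param model Model id or `model_spec`.
#' @param free Named list (or named numeric vector) of free-parameter values.
#' @return The validated free parameters as a named list.
#' @export
validate_free_params <- function(model, free) {
  model <- as_model_spec(model)
  if (is.null(free)) free <- list()
  free <- as.list(free)
  if (length(free) && is.null(names(free))) {
    stop("free parameters must be named", call. = FALSE)
  }
  missing <- setdiff(model$free, names(free))
  extra <- setdiff(names(free), model$free)
  if (length(missing)) {
    stop(sprintf("model %s requires free parameter(s): %s",
                 model$id, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(extra)) {
    stop(sprintf("model %s does not use parameter(s): %s",
                 model$id, paste(extra, collapse = ", ")), call. = FALSE)
  }
  bounds <- free_param_bounds()
  for (nm in model$free) {
    v <- free[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("parameter '%s' must be a finite numeric scalar", nm),
           call. = FALSE)
    }
    b <- bounds[[nm]]
    if (v < b[1] || v > b[2]) {
      stop(sprintf("parameter '%s' = %g outside its range [%g, %g]",
                   nm, v, b[1], b[2]), call. = FALSE)
    }
  }
  free[model$free]
}

# effective (free + fixed) BCI parameters for a model
bci_params <- function(model, free) {
  p_causal <- if (!is.null(model$fixed$p_causal)) model$fixed$p_causal
              else free[["p_causal"]]
  mu_ao <- if (!is.null(model$fixed$mu_ao)) model$fixed$mu_ao
           else free[["mu_ao"]]
  list(p_causal = p_causal, mu_ao = mu_ao)
}
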