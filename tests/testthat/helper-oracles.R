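# Independent oracles used across tests. These re-derive quantities by brute
# force (grid integration / maximisation, moment algebra) and never call the
# package's analytic implementations.

# Peak ratio of the causal vs acausal joint posterior by brute-force grid
# maximisation of the (unnormalised) joint density over (t_a, t_o).
grid_joint_ratio <- function(tau_a, tau_o, params, p_causal, mu_ao,
                             step = 1, halfwidth = NULL) {
  if (is.null(halfwidth)) {
    halfwidth <- 4 * max(params$sigma_a, params$sigma_o, params$sigma_ao)
  }
  t_a <- seq(tau_a - halfwidth, tau_a + halfwidth, by = step)
  t_o <- seq(tau_o - halfwidth, tau_o + halfwidth, by = step)
  lik <- outer(dnorm(tau_a, t_a, params$sigma_a),
               dnorm(tau_o, t_o, params$sigma_o))
  gap <- outer(-t_a, t_o, `+`)  # t_o - t_a
  prior1 <- dnorm(gap, mu_ao, params$sigma_ao) / params$t_range
  num <- p_causal * max(lik * prior1)
  den <- (1 - p_causal) / params$t_range^2 * max(lik)
  num / den
}

# Marginal causal posterior by numerical double integration of the joint
# density (the hierarchical observer's quantity), on a 2-D grid.
numeric_marginal_posterior <- function(tau_a, tau_o, params, p_causal, mu_ao,
                                       step = 2, halfwidth = NULL) {
  if (is.null(halfwidth)) {
    halfwidth <- 6 * max(params$sigma_a, params$sigma_o, params$sigma_ao)
  }
  t_a <- seq(tau_a - halfwidth, tau_a + halfwidth, by = step)
  t_o <- seq(tau_o - halfwidth, tau_o + halfwidth, by = step)
  lik <- outer(dnorm(tau_a, t_a, params$sigma_a),
               dnorm(tau_o, t_o, params$sigma_o))
  gap <- outer(-t_a, t_o, `+`)
  prior1 <- dnorm(gap, mu_ao, params$sigma_ao) / params$t_range
  l1 <- p_causal * sum(lik * prior1) * step^2
  l0 <- (1 - p_causal) / params$t_range^2 * sum(lik) * step^2
  l1 / (l1 + l0)
}

# Exact response moments for cells with closed-form Gaussian responses.
# Null model: the report is the raw percept of the target event.
null_cell_moments <- function(params, t_ao, target) {
  if (target == "action") {
    c(mean = params$b_a, sd = params$sigma_a)
  } else {
    c(mean = t_ao + params$b_o, sd = params$sigma_o)
  }
}

# Mandatory integration: the response is a fixed linear map of the Gaussian
# percepts, hence exactly Gaussian with these moments.
mi_cell_moments <- function(params, t_ao, target, mu_ao) {
  s2 <- params$sigma_a^2 + params$sigma_o^2 + params$sigma_ao^2
  mu_a <- params$b_a
  mu_o <- t_ao + params$b_o
  if (target == "action") {
    w <- params$sigma_a^2 / s2
    c(mean = (1 - w) * mu_a + w * mu_o - w * mu_ao,
      sd = sqrt((1 - w)^2 * params$sigma_a^2 + w^2 * params$sigma_o^2))
  } else {
    w <- params$sigma_o^2 / s2
    c(mean = (1 - w) * mu_o + w * mu_a + w * mu_ao,
      sd = sqrt((1 - w)^2 * params$sigma_o^2 + w^2 * params$sigma_a^2))
  }
}

# small configurations for fast unit-level fits
quick_design <- function(k = 10) design_spec(trials_per_condition = k)
quick_cfg <- function(n_mc = 2000, seed = 1L, ...) {
  fit_config(n_mc = n_mc, seed = seed, ...)
}
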