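test_that("percept sampling follows the sensory model", {
  # noiseless limit: percepts collapse onto the biased physical times
  p0 <- observer_params(b_a = -10, sigma_a = 1e-9, b_o = 5, sigma_o = 1e-9)
  pp <- sample_percepts(p0, t_ao = 250, n = 50, seed = 1)
  expect_equal(pp$tau_a, rep(-10, 50), tolerance = 1e-6)
  expect_equal(pp$tau_o, rep(255, 50), tolerance = 1e-6)

  # law of large numbers at the study's noise level
  p <- default_observer_params()
  pp <- sample_percepts(p, t_ao = 0, n = 1e5, seed = 2)
  expect_lt(abs(mean(pp$tau_a) - p$b_a), 3 * p$sigma_a / sqrt(1e5))
  expect_lt(abs(mean(pp$tau_o) - p$b_o), 3 * p$sigma_o / sqrt(1e5))
  # pairs independent across trials: correlation consistent with zero
  expect_lt(abs(cor(pp$tau_a, pp$tau_o)), 4 / sqrt(1e5))

  # reproducible given seed
  expect_identical(sample_percepts(p, 250, 10, seed = 7),
                   sample_percepts(p, 250, 10, seed = 7))

  expect_error(observer_params(0, -1, 0, 10), "must be > 0")
  expect_error(observer_params(0, 10, 0, 0), "must be > 0")
})

test_that("conditional MAP estimates shrink toward the prior interval", {
  p <- observer_params(0, 50, 0, 60, sigma_ao = 10, t_range = 250)

  # hand-evaluated: sigma_tot^2 = 6200
  ce <- conditional_estimates(data.frame(tau_a = 0, tau_o = 250), p, mu_ao = 0)
  expect_equal(ce$t_a_causal, 250 * 2500 / 6200, tolerance = 1e-12)
  expect_equal(ce$t_o_causal, 250 - 250 * 3600 / 6200, tolerance = 1e-12)
  expect_equal(ce$t_a_acausal, 0)
  expect_equal(ce$t_o_acausal, 250)

  # zero discrepancy: causal estimates equal the raw percepts
  ce0 <- conditional_estimates(data.frame(tau_a = 20, tau_o = 120), p,
                               mu_ao = 100)
  expect_equal(ce0$t_a_causal, 20)
  expect_equal(ce0$t_o_causal, 120)

  # interval-shrinkage identity and direction on random inputs
  set.seed(42)
  n <- 1e4
  pp <- data.frame(tau_a = rnorm(n, 0, 80), tau_o = rnorm(n, 200, 120))
  mu <- runif(n, 0, 500)
  prm <- default_observer_params()
  s2 <- prm$sigma_a^2 + prm$sigma_o^2 + prm$sigma_ao^2
  for (i in c(1, 2)) { # two mu regimes: scalar and vector-wise check
    m <- if (i == 1) 0 else 250
    ce <- conditional_estimates(pp, prm, mu_ao = m)
    gap_hat <- ce$t_o_causal - ce$t_a_causal
    gap_exp <- m + (prm$sigma_ao^2 / s2) * (pp$tau_o - pp$tau_a - m)
    expect_equal(gap_hat, gap_exp, tolerance = 1e-9)
    # perceived interval ends closer to the prior than the raw interval
    expect_true(all(abs(gap_hat - m) <= abs(pp$tau_o - pp$tau_a - m) + 1e-9))
  }
})

test_that("causal shifts compress positive discrepancies and reverse below the prior", {
  prm <- default_observer_params()
  # unity prior, outcome after action: action pulled later, outcome earlier
  pp <- data.frame(tau_a = rep(0, 50), tau_o = seq(10, 500, length.out = 50))
  ce <- conditional_estimates(pp, prm, mu_ao = 0)
  expect_true(all(ce$t_a_causal > pp$tau_a))
  expect_true(all(ce$t_o_causal < pp$tau_o))
  # coupling prior above the perceived interval: repulsion
  ce2 <- conditional_estimates(data.frame(tau_a = 0, tau_o = 100), prm,
                               mu_ao = 400)
  expect_lt(ce2$t_a_causal, 0)
  expect_gt(ce2$t_o_causal, 100)
})

test_that("marginal causal posterior matches numerical integration of the joint", {
  p <- observer_params(0, 50, 0, 60, sigma_ao = 10, t_range = 250)
  pp <- data.frame(tau_a = 0, tau_o = 250)

  # degenerate priors
  expect_equal(marginal_causal_posterior(pp, p, 0), 0)
  expect_equal(marginal_causal_posterior(pp, p, 1), 1)

  # large-discrepancy value, against brute-force 2-D integration
  post <- marginal_causal_posterior(pp, p, 0.5, mu_ao = 0)
  expect_equal(post, 0.0081, tolerance = 0.02)
  expect_equal(post,
               numeric_marginal_posterior(0, 250, p, 0.5, 0),
               tolerance = 1e-3)

  # agreement across a spread of percepts, priors and parameters
  set.seed(9)
  for (i in 1:10) {
    prm <- observer_params(runif(1, -80, 0), runif(1, 40, 80),
                           runif(1, 0, 80), runif(1, 40, 80))
    pc <- runif(1, 0.05, 0.95)
    mu <- runif(1, 0, 500)
    ta <- rnorm(1, 0, 60)
    to <- rnorm(1, 250, 120)
    expect_equal(
      marginal_causal_posterior(data.frame(tau_a = ta, tau_o = to), prm,
                                pc, mu),
      numeric_marginal_posterior(ta, to, prm, pc, mu),
      tolerance = 1e-3
    )
  }

  # strictly decreasing in the absolute discrepancy from the prior interval
  dd <- seq(0, 600, by = 10)
  post_grid <- marginal_causal_posterior(
    data.frame(tau_a = 0, tau_o = 100 + dd), p, 0.5, mu_ao = 100)
  expect_true(all(diff(post_grid) < 0))
  # complement closes to one by construction
  expect_equal(post_grid + (1 - post_grid), rep(1, length(post_grid)))
})

test_that("joint-posterior peak ratio matches a brute-force grid oracle", {
  p <- default_observer_params()
  pp <- data.frame(tau_a = 0, tau_o = 250)
  expect_equal(joint_posterior_ratio(pp, p, 0), 0)
  expect_equal(joint_posterior_ratio(pp, p, 1), Inf)

  set.seed(3)
  for (i in 1:25) {
    prm <- observer_params(runif(1, -80, 0), runif(1, 40, 80),
                           runif(1, 0, 80), runif(1, 40, 80))
    pc <- runif(1, 0.05, 0.95)
    mu <- runif(1, 0, 500)
    ta <- rnorm(1, prm$b_a, prm$sigma_a)
    to <- sample(c(0, 250, 500), 1) + rnorm(1, prm$b_o, prm$sigma_o)
    r_an <- joint_posterior_ratio(data.frame(tau_a = ta, tau_o = to),
                                  prm, pc, mu)
    r_gr <- grid_joint_ratio(ta, to, prm, pc, mu, step = 0.5)
    expect_equal(r_an, r_gr, tolerance = 1e-3)
  }

  # the r > 1 region is a contiguous interval of the perceived gap
  gap <- seq(-800, 1200, by = 1)
  r <- joint_posterior_ratio(data.frame(tau_a = 0, tau_o = gap), p,
                             0.7, mu_ao = 100)
  causal <- which(r > 1)
  expect_gt(length(causal), 0)
  expect_identical(causal, seq(min(causal), max(causal)))
})
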