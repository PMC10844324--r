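test_that("fixed-criterion responses average within the threshold", {
  prm <- default_observer_params()
  pp <- data.frame(tau_a = -10, tau_o = 150)
  # gap 160 <= 200: both targets report the average
  expect_equal(respond("FC", list(phi = 200), pp, prm, "action"), 70)
  expect_equal(respond("FC", list(phi = 200), pp, prm, "outcome"), 70)
  # gap above the threshold: raw percepts
  expect_equal(respond("FC", list(phi = 100), pp, prm, "action"), -10)
  expect_equal(respond("FC", list(phi = 100), pp, prm, "outcome"), 150)
  # the comparison is signed: a negative perceived gap always integrates
  neg <- data.frame(tau_a = 100, tau_o = -50)
  expect_equal(respond("FC", list(phi = 0), neg, prm, "action"), 25)
  # boundary is inclusive
  eq <- data.frame(tau_a = 0, tau_o = 200)
  expect_equal(respond("FC", list(phi = 200), eq, prm, "action"), 100)
})

test_that("false-report responses swap events with probability p_fr", {
  prm <- default_observer_params()
  pp <- data.frame(tau_a = rnorm(20), tau_o = rnorm(20, 250))
  u <- runif(20)
  expect_equal(respond("FR", list(p_fr = 0), pp, prm, "action", u), pp$tau_a)
  expect_equal(respond("FR", list(p_fr = 0), pp, prm, "outcome", u), pp$tau_o)
  expect_equal(respond("FR", list(p_fr = 1), pp, prm, "action", u), pp$tau_o)
  expect_equal(respond("FR", list(p_fr = 1), pp, prm, "outcome", u), pp$tau_a)
  # swap frequency tracks p_fr
  set.seed(1)
  n <- 2e4
  pp <- data.frame(tau_a = rep(0, n), tau_o = rep(250, n))
  u <- runif(n)
  rep_a <- respond("FR", list(p_fr = 0.3), pp, prm, "action", u)
  expect_lt(abs(mean(rep_a == 250) - 0.3), 4 * sqrt(0.3 * 0.7 / n))
})

test_that("model-averaging reports are convex combinations of the scenario estimates", {
  prm <- default_observer_params()
  set.seed(5)
  pp <- data.frame(tau_a = rnorm(500, prm$b_a, prm$sigma_a),
                   tau_o = rnorm(500, 250 + prm$b_o, prm$sigma_o))
  free <- list(p_causal = 0.6, mu_ao = 120)
  ce <- conditional_estimates(pp, prm, mu_ao = free$mu_ao)
  for (target in c("action", "outcome")) {
    rep_t <- respond("MAcp", free, pp, prm, target)
    e1 <- if (target == "action") ce$t_a_causal else ce$t_o_causal
    e0 <- if (target == "action") ce$t_a_acausal else ce$t_o_acausal
    expect_true(all(rep_t >= pmin(e0, e1) - 1e-12 &
                    rep_t <= pmax(e0, e1) + 1e-12))
  }
})

test_that("probability matching samples the causal scenario at its posterior rate", {
  prm <- default_observer_params()
  pp1 <- data.frame(tau_a = -20, tau_o = 120)
  free <- list(p_causal = 0.6)
  post <- marginal_causal_posterior(pp1, prm, free$p_causal, 0)
  set.seed(11)
  n <- 2e4
  u <- runif(n)
  pp <- pp1[rep(1, n), ]
  rep_a <- respond("PMup", free, pp, prm, "action", u)
  ca <- conditional_estimates(pp1, prm, 0)$t_a_causal
  freq <- mean(rep_a == ca)
  expect_lt(abs(freq - post), 4 * sqrt(post * (1 - post) / n))
})

test_that("selection and matching strategies coincide at posterior certainty", {
  prm <- default_observer_params()
  set.seed(13)
  pp <- data.frame(tau_a = rnorm(200, prm$b_a, prm$sigma_a),
                   tau_o = rnorm(200, 250 + prm$b_o, prm$sigma_o))
  u <- runif(200)
  for (pc in c(0, 1)) { # posterior exactly 0 or 1
    free <- list(p_causal = pc)
    expect_equal(respond("MSup", free, pp, prm, "action", u),
                 respond("PMup", free, pp, prm, "action", u))
    expect_equal(respond("MSup", free, pp, prm, "outcome", u),
                 respond("PMup", free, pp, prm, "outcome", u))
  }
})

test_that("joint-posterior decision agrees with grid maximisation of the joint density", {
  prm <- default_observer_params()
  free <- list(p_causal = 0.6, mu_ao = 150)
  set.seed(17)
  pp <- data.frame(tau_a = rnorm(30, prm$b_a, prm$sigma_a),
                   tau_o = rnorm(30, 250 + prm$b_o, prm$sigma_o))
  rep_a <- respond("JPcp", free, pp, prm, "action")
  ce <- conditional_estimates(pp, prm, free$mu_ao)
  for (i in seq_len(nrow(pp))) {
    r_grid <- grid_joint_ratio(pp$tau_a[i], pp$tau_o[i], prm,
                               free$p_causal, free$mu_ao)
    expected <- if (r_grid > 1) ce$t_a_causal[i] else ce$t_a_acausal[i]
    expect_equal(rep_a[i], expected)
  }
})

test_that("null and mandatory-integration responses follow their limits", {
  prm <- default_observer_params()
  pp <- data.frame(tau_a = c(-30, 10), tau_o = c(200, 300))
  expect_equal(respond("NULL", list(), pp, prm, "action"), pp$tau_a)
  expect_equal(respond("NULL", list(), pp, prm, "outcome"), pp$tau_o)
  ce <- conditional_estimates(pp, prm, mu_ao = 0)
  expect_equal(respond("MIup", list(), pp, prm, "action"), ce$t_a_causal)
  expect_equal(respond("MIup", list(), pp, prm, "outcome"), ce$t_o_causal)
})

test_that("model/parameter mismatches and missing draws are rejected", {
  prm <- default_observer_params()
  pp <- data.frame(tau_a = 0, tau_o = 250)
  expect_error(respond("FC", list(), pp, prm, "action"), "requires free")
  expect_error(respond("FC", list(phi = 100, p_fr = 0.1), pp, prm, "action"),
               "does not use")
  expect_error(respond("FC", list(phi = 2000), pp, prm, "action"),
               "outside its range")
  expect_error(respond("PMup", list(p_causal = 0.5), pp, prm, "action"),
               "stochastic")
  expect_error(respond("FR", list(p_fr = 0.5), pp, prm, "action"),
               "stochastic")
})
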