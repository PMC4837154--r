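test_that("change-point probability limits and symmetry", {
  st <- belief_state(1, 0.5, 0)
  expect_identical(cpm_change_probability(st, 2, cpm_params(h = 0)), 0)
  expect_identical(cpm_change_probability(st, 2, cpm_params(h = 1)), 1)
  # symmetric construction: h = 1/2 and equal predictive variances with
  # mu = 0 makes both mixture components identical, so Omega = 1/2
  p <- suppressWarnings(cpm_params(h = 0.5, s = 1, w1 = 0.5, w2 = 1.0))
  st0 <- belief_state(0, 0.5, 0) # sigma1 + w1 + s = 2 = s + w2
  for (o in c(-3, 0, 1.7)) {
    expect_equal(cpm_change_probability(st0, o, p), 0.5, tolerance = 1e-12)
    # Omega = 1/2 maps to a level-2 expectation of exactly zero when a = 1
    expect_equal(cpm_step(st0, o, p)$state$mu2, 0, tolerance = 1e-12)
  }
})

test_that("change-point probability matches direct density evaluation", {
  for (inp in random_cpm_inputs(1000)) {
    got <- cpm_change_probability(inp$state, inp$o, inp$params)
    want <- oracle_cpm_omega(inp$state, inp$o, inp$params)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("cpm_step agrees with the conditional-posterior mixture oracle", {
  for (inp in random_cpm_inputs(1000, seed = 77)) {
    got <- cpm_step(inp$state, inp$o, inp$params)
    want <- oracle_cpm_step(inp$state, inp$o, inp$params)
    expect_equal(got$state$mu1, want$mu1, tolerance = 1e-10)
    expect_equal(got$state$sigma1, want$sigma1, tolerance = 1e-10)
    expect_equal(got$internals$alpha1, want$alpha1, tolerance = 1e-10)
    expect_equal(got$internals$eps1, want$eps1, tolerance = 1e-10)
    expect_equal(got$internals$omega, want$omega, tolerance = 1e-10)
    # the logit amplifies the non-log oracle's rounding when Omega saturates;
    # compare the level-2 reparameterisation away from the saturated region
    if (want$omega > 1e-6 && want$omega < 1 - 1e-6)
      expect_equal(got$state$mu2, want$mu2, tolerance = 1e-10)
  }
})

test_that("with h = 0 the CPM reduces exactly to a Kalman filter", {
  blk <- simulate_switching(switching_params(h = 0, w1 = 0.05), 200, seed = 4)
  p <- cpm_params(mu0_1 = 0.3, sigma0_1 = 2, s = 1.5, w1 = 0.05, h = 0)
  tr <- run_filter("CPM", p, blk)
  kal <- oracle_kalman(blk$observations, p$mu0_1, p$sigma0_1, p$w1, p$s)
  expect_equal(tr$internals$mu1, kal$mu, tolerance = 1e-10)
  expect_equal(tr$internals$sigma1, kal$sigma, tolerance = 1e-10)
  # the learning rate is the Kalman gain (sigma + w1) / (sigma + w1 + s)
  expect_equal(tr$internals$alpha1, kal$gain, tolerance = 1e-10)
  # and the surprise is the Gaussian predictive log-density of the Kalman case
  st <- belief_state(p$mu0_1, p$sigma0_1, 0)
  expect_equal(cpm_trial_surprise(st, blk$observations[1], p),
               -dnorm(blk$observations[1], p$mu0_1,
                      sqrt(p$sigma0_1 + p$w1 + p$s), log = TRUE),
               tolerance = 1e-12)
})

test_that("trial surprise is a proper predictive density and matches the oracle", {
  st <- belief_state(0.8, 0.6, 0)
  p <- cpm_params(s = 1.2, w1 = 0.05, w2 = 8, h = 0.15)
  dens <- function(o) {
    vapply(o, function(oo) exp(-cpm_trial_surprise(st, oo, p)), numeric(1))
  }
  mass <- integrate(dens, -Inf, Inf, rel.tol = 1e-9)$value
  expect_equal(mass, 1, tolerance = 1e-6)
  for (inp in random_cpm_inputs(300, seed = 12)) {
    expect_equal(cpm_trial_surprise(inp$state, inp$o, inp$params),
                 oracle_cpm_surprise(inp$state, inp$o, inp$params),
                 tolerance = 1e-10)
  }
})

test_that("Omega rises with distance from the origin when w2 dominates", {
  p <- cpm_params(s = 1, w1 = 0.01, w2 = 50, h = 0.1)
  st <- belief_state(0, 0.2, 0)
  o_grid <- seq(0.5, 5, by = 0.25) # beyond ~6 Omega saturates at 1 in doubles
  om <- vapply(o_grid, function(o) cpm_change_probability(st, o, p), numeric(1))
  expect_true(all(diff(om) > 0))
})

test_that("CPM learning rate and variance respect their bounds", {
  set.seed(17)
  for (rep in 1:20) {
    blk <- simulate_switching(switching_params(), 100, seed = 100 + rep)
    p <- suppressWarnings(
      cpm_params(s = exp(rnorm(1, 0, 0.5)), w1 = exp(rnorm(1, -3, 1)),
                 w2 = exp(rnorm(1, 2, 0.5)), h = plogis(rnorm(1, -2, 1))))
    tr <- run_filter("CPM", p, blk)
    expect_true(all(tr$internals$alpha1 > 0 & tr$internals$alpha1 <= 1))
    expect_true(all(tr$internals$sigma1 <= p$s + 1e-12))
  }
})

test_that("matched CPM parameters explain switching stimuli better than mismatched ones", {
  p_true <- cpm_params()
  p_off <- cpm_params(h = 0.45, w2 = 2, w1 = 0.5)
  blocks <- simulate_session(switching_params(), 20, 100, seed = 23)
  expect_lt(total_surprise("CPM", p_true, blocks),
            total_surprise("CPM", p_off, blocks))
})

test_that("level-2 state starts at the scaled prior logit of the hazard", {
  p <- cpm_params(h = 0.2, a = 2)
  expect_equal(cpm_mu0_2(p), log(0.2 / 0.8) / 2, tolerance = 1e-12)
  blk <- simulate_switching(switching_params(), 3, seed = 1)
  tr <- run_filter("CPM", p, blk)
  st <- belief_state(p$mu0_1, p$sigma0_1, cpm_mu0_2(p))
  expect_equal(tr$internals$eps2[1],
               cpm_step(st, blk$observations[1], p)$internals$eps2,
               tolerance = 1e-12)
})
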