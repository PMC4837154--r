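test_that("zero prediction error leaves the level-1 expectation unchanged", {
  st <- belief_state(1.3, 0.8, -0.5, 0.6)
  p <- hgf_params(s = 1.2, eta = 0.3)
  out <- hgf_step(st, o = st$mu1, p)
  expect_equal(out$internals$eps1, 0)
  expect_equal(out$state$mu1, st$mu1)
  # delta2 = sigma_t(1)/g - 1 < 0 when the prediction error vanishes
  g <- st$sigma1 + exp(st$mu2)
  expect_equal(out$internals$delta2, out$state$sigma1 / g - 1)
  expect_lt(out$internals$delta2, 0)
})

test_that("hand-evaluated precision update: s = 1, sigma1 = 1, mu2 = 0", {
  out <- hgf_step(belief_state(0, 1, 0, 1), o = 0.7,
                  hgf_params(s = 1, eta = 0.1))
  expect_equal(out$state$sigma1, 2 / 3, tolerance = 1e-12)
  expect_equal(out$internals$alpha1, 2 / 3, tolerance = 1e-12)
})

test_that("hgf_step agrees with the conjugate/Newton oracle on random inputs", {
  inputs <- random_hgf_inputs(1000)
  for (inp in inputs) {
    got <- tryCatch(hgf_step(inp$state, inp$o, inp$params),
                    cpmhgf_invalid_update = function(e) NULL)
    if (is.null(got)) next # invalid-update region, checked elsewhere
    want <- oracle_hgf_step(inp$state, inp$o, inp$params)
    expect_equal(got$state$mu1, want$mu1, tolerance = 1e-10)
    expect_equal(got$state$sigma1, want$sigma1, tolerance = 1e-10)
    expect_equal(got$state$mu2, want$mu2, tolerance = 1e-10)
    expect_equal(got$state$sigma2, want$sigma2, tolerance = 1e-10)
    expect_equal(got$internals$alpha1, want$alpha1, tolerance = 1e-10)
    expect_equal(got$internals$eps1, want$eps1, tolerance = 1e-10)
    expect_equal(got$internals$eps2, want$eps2, tolerance = 1e-10)
  }
})

test_that("the analytic level-2 oracle itself matches numerical differentiation", {
  for (inp in random_hgf_inputs(25, seed = 9)) {
    want <- oracle_hgf_step(inp$state, inp$o, inp$params)
    num <- oracle_hgf_level2_numeric(inp$state, inp$o, inp$params)
    expect_equal(want$mu2, num$mu2, tolerance = 1e-5)
    expect_equal(want$sigma2, num$sigma2, tolerance = 1e-5)
  }
})

test_that("trial free energy matches the density-plus-entropy decomposition", {
  for (inp in random_hgf_inputs(200, seed = 5)) {
    stp <- tryCatch(hgf_step(inp$state, inp$o, inp$params),
                    cpmhgf_invalid_update = function(e) NULL)
    if (is.null(stp)) next
    got <- hgf_trial_free_energy(inp$state, stp$state, inp$o, inp$params)
    want <- oracle_hgf_free_energy(inp$state, stp$state, inp$o, inp$params)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("per-trial surprise sums to the trajectory total", {
  blk <- simulate_switching(switching_params(), 150, seed = 2)
  tr <- run_filter("HGF", hgf_params(), blk)
  expect_equal(sum(tr$internals$surprise), tr$total_surprise, tolerance = 1e-12)
})

test_that("compiled and pure-R filters produce identical trajectories", {
  blk <- simulate_diffusive(diffusive_params(), 120, seed = 8)
  for (model in c("HGF", "CPM")) {
    p <- if (model == "HGF") hgf_params() else cpm_params()
    a <- run_filter(model, p, blk, compiled = TRUE)
    b <- run_filter(model, p, blk, compiled = FALSE)
    expect_equal(as.matrix(a$internals), as.matrix(b$internals),
                 tolerance = 1e-12)
    expect_equal(a$total_surprise, b$total_surprise, tolerance = 1e-12)
  }
})

test_that("learning rate stays in (0, 1] and posterior variance below s", {
  set.seed(31)
  for (rep in 1:20) {
    blk <- simulate_switching(switching_params(), 100, seed = rep)
    p <- hgf_params(s = exp(rnorm(1, 0, 0.5)), eta = exp(rnorm(1, -1, 0.5)))
    tr <- run_filter("HGF", p, blk, on_invalid = "flag")
    if (!is.null(tr$invalid_at)) next
    expect_true(all(tr$internals$alpha1 > 0 & tr$internals$alpha1 <= 1))
    expect_true(all(tr$internals$sigma1 < p$s))
  }
})

test_that("a non-positive level-2 precision update signals the invalid condition", {
  st <- belief_state(0, 3, 0, 10) # sigma1 >> exp(mu2), huge surprise ahead
  p <- hgf_params(s = 1, eta = 1)
  expect_error(hgf_step(st, o = 10, p), class = "cpmhgf_invalid_update")
  # run_filter propagates the trial index when raising, flags when asked
  obs <- c(0, 30)
  pp <- hgf_params(mu0_1 = 0, sigma0_1 = 3, s = 5, mu0_2 = -2, sigma0_2 = 10,
                   eta = 1)
  expect_error(run_filter("HGF", pp, obs), "trial 2")
  tr <- run_filter("HGF", pp, obs, on_invalid = "flag")
  expect_identical(tr$invalid_at, 2L)
  expect_identical(tr$total_surprise, Inf)
})

test_that("empty observation streams give an empty trajectory with zero surprise", {
  tr <- run_filter("HGF", hgf_params(), numeric(0))
  expect_identical(tr$T, 0L)
  expect_identical(tr$total_surprise, 0)
})
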