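test_that("belief RMSE against the hidden state has its closed forms", {
  blk <- simulate_switching(switching_params(), 50, seed = 41)
  tr <- run_filter("CPM", cpm_params(), blk)
  # perfect beliefs
  fake <- tr; fake$internals$mu1 <- blk$hidden1
  expect_identical(performance_rmse(fake, blk), 0)
  # constant offset c gives |c|
  fake$internals$mu1 <- blk$hidden1 - 1.3
  expect_equal(performance_rmse(fake, blk), 1.3, tolerance = 1e-12)
  # random pair matches direct arithmetic
  expect_equal(performance_rmse(tr, blk),
               sqrt(mean((tr$internals$mu1 - blk$hidden1)^2)),
               tolerance = 1e-12)
})

test_that("group model selection is symmetric, dominance-consistent and matches MC", {
  L0 <- matrix(0, 12, 2)
  g0 <- group_bms(L0)
  expect_equal(g0$expected_frequencies, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(g0$exceedance_probabilities, c(0.5, 0.5), tolerance = 1e-6)

  L1 <- cbind(rep(100, 20), rep(0, 20))
  g1 <- group_bms(L1)
  expect_gt(g1$exceedance_probabilities[1], 0.9999)
  expect_identical(g1$winner, 1L)

  set.seed(47)
  for (i in 1:10) {
    L <- matrix(rnorm(40, 0, 3), 20, 2)
    g <- group_bms(L)
    mc <- mc_exceedance(g$alpha, n = 1e6, seed = i)
    expect_lt(abs(g$exceedance_probabilities[1] - mc$p),
              3 * mc$se + 1e-9)
  }
  expect_error(group_bms(matrix(c(1, NA), 1, 2)), class = "cpmhgf_param_error")
})

test_that("confusion matrices are row-stochastic and dominance gives the identity", {
  pool <- data.frame(
    true_model = rep(c("HGF", "CPM"), each = 25),
    logev_hgf = c(rnorm(25, 0), rnorm(25, -30)),
    logev_cpm = c(rnorm(25, -30), rnorm(25, 0))
  )
  cm <- confusion_experiment(pool, k = 10, n_groups = 50, seed = 2)
  expect_equal(unname(rowSums(cm$proportions)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(diag(cm$proportions)), c(1, 1))
  expect_error(confusion_experiment(pool, k = 100), class = "cpmhgf_param_error")
})

test_that("recovery diagnostics report exact recovery and calibrated coverage", {
  mk_fit <- function(rho, sd) {
    structure(list(rho_star = rho, sd = sd,
                   covariance = diag(sd^2, length(rho))),
              class = "fit_result")
  }
  nm <- c("a", "b", "c")
  truths <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, nm))
  fits <- lapply(1:10, function(i) {
    mk_fit(setNames(truths[i, ], nm), setNames(rep(1, 3), nm))
  })
  rd <- recovery_diagnostics(fits, truths)
  expect_equal(rd$rmse, rep(0, 3))
  expect_equal(rd$coverage, rep(1, 3))

  # a perfectly calibrated Gaussian estimator covers ~ 95.45% at +/- 2 sd
  set.seed(48)
  n <- 4000
  tru <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "p"))
  fits2 <- lapply(1:n, function(i) {
    mk_fit(setNames(tru[i, 1] + rnorm(1), "p"), setNames(1, "p"))
  })
  rd2 <- recovery_diagnostics(fits2, tru)
  nominal <- pnorm(2) - pnorm(-2)
  expect_lt(abs(rd2$coverage - nominal), 3 * sqrt(nominal * (1 - nominal) / n))

  # coverage is invariant under a consistent affine reparameterisation
  sc <- 3.2; off <- -1.4
  fits3 <- lapply(fits2, function(f) {
    mk_fit(setNames(sc * f$rho_star + off, "p"), setNames(sc * f$sd, "p"))
  })
  rd3 <- recovery_diagnostics(fits3, sc * tru + off)
  expect_equal(rd3$coverage, rd2$coverage)
})

test_that("trajectory correlations are 1 at the truth and -1 for sign flips", {
  ds <- make_fixture("cpm-switching-easy", seed = 51)
  truth_rho <- transform_params(
    c(unlist(unclass(ds$perc_params))[param_info("CPM", TRUE)$name],
      sigma_r = ds$sigma_r), "CPM")
  fake_fit <- structure(list(rho_star = truth_rho, model = "CPM",
                             sd = rep(1, 7)), class = "fit_result")
  cc <- trajectory_correlation(ds, fake_fit)
  expect_equal(unname(cc[c("mu1", "alpha1", "eps1", "mu2", "eps2")]),
               rep(1, 5), tolerance = 1e-10)
})

test_that("exceedance against a median behaves at its limits", {
  set.seed(53)
  x <- rnorm(4000)
  expect_lt(abs(exceedance_vs_median(x, rnorm(4000)) - 0.5), 0.05)
  expect_identical(exceedance_vs_median(c(0.1, 0.2), c(0.5, 0.9, 0.8)), 0)
  expect_error(exceedance_vs_median(numeric(0), 1),
               class = "cpmhgf_param_error")
})
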