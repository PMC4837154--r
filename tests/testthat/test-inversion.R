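test_that("Laplace evidence matches quadrature in a one-parameter Gaussian toy", {
  # flat belief trajectory (mu = 0), only the response-noise variance free:
  # the evidence integral is one-dimensional and can be computed by quadrature
  set.seed(55)
  T <- 300
  r <- rnorm(T, 0, sqrt(2))
  logjoint <- function(rho) {
    v <- exp(rho)
    sum(dnorm(r, 0, sqrt(v), log = TRUE)) + dnorm(rho, 0, sqrt(5), log = TRUE)
  }
  opt <- cmaes_minimize(function(rho) -logjoint(rho), x0 = 0, sigma0 = 1,
                        max_evals = 400, restarts = 2, seed = 3)
  H <- fd_hessian(function(rho) logjoint(rho[1]), opt$par)
  la <- -opt$value + 0.5 * log(2 * pi) - 0.5 * log(-H[1, 1])
  scale <- logjoint(opt$par)
  quad <- log(integrate(function(rho) {
    vapply(rho, function(x) exp(logjoint(x) - scale), numeric(1))
  }, -20, 20, rel.tol = 1e-10)$value) + scale
  expect_equal(la, quad, tolerance = 1e-3)
})

test_that("stored evidence is reproducible from the returned mode and covariance", {
  ds <- make_fixture("cpm-switching-easy", seed = 9)
  cfg <- optimizer_config(max_evals = 800, restarts = 2)
  f <- fit_bi_la(ds, "CPM", config = cfg, seed = 2)
  relog <- f$log_at_mode + 0.5 * f$d * log(2 * pi) +
    0.5 * determinant(f$covariance, logarithm = TRUE)$modulus[1]
  expect_equal(f$log_evidence, relog, tolerance = 1e-6)
  expect_true(isSymmetric(f$covariance, tol = 1e-10))
  expect_true(all(eigen(f$covariance, only.values = TRUE)$values > 0))

  g <- fit_mle(ds, "CPM", config = cfg, seed = 2)
  expect_equal(g$log_evidence, g$log_at_mode - (7 / 2) * log(ds$T),
               tolerance = 1e-12)
  # BIC penalty at d = 7, T = 100
  expect_equal((7 / 2) * log(100), 16.11810, tolerance = 1e-5)
})

test_that("a nearly flat prior makes the Bayesian mode coincide with the MLE", {
  ds <- make_fixture("cpm-switching-easy", seed = 12)
  cfg <- optimizer_config(max_evals = 1500, restarts = 2)
  flat <- prior_spec("CPM", var = setNames(rep(1e8, 7), param_info("CPM")$name))
  fb <- fit_bi_la(ds, "CPM", prior = flat, config = cfg, seed = 4)
  fm <- fit_mle(ds, "CPM", config = cfg, seed = 4)
  ll <- function(rho) response_loglik(ds$responses, "CPM",
                                      params_from_rho(rho, "CPM")$perc,
                                      exp(rho[["sigma_r"]]), ds$observations)
  expect_equal(ll(fb$rho_star), ll(fm$rho_star), tolerance = 0.05)
})

test_that("fits are deterministic given the seed", {
  ds <- make_fixture("kalman-limit", seed = 3)
  cfg <- optimizer_config(max_evals = 600, restarts = 2)
  f1 <- fit_mle(ds, "CPM", config = cfg, seed = 11)
  f2 <- fit_mle(ds, "CPM", config = cfg, seed = 11)
  expect_identical(f1$rho_star, f2$rho_star)
  expect_identical(f1$log_evidence, f2$log_evidence)
})

test_that("the HGF response likelihood is translation equivariant", {
  ds <- make_fixture("hgf-diffusive-noisy", seed = 21)
  p <- hgf_params(mu0_1 = 0.4, eta = 0.2)
  base <- response_loglik(ds$responses, "HGF", p, 1.5, ds$observations)
  cshift <- 3.7
  p_shift <- hgf_params(mu0_1 = 0.4 + cshift, eta = 0.2)
  shifted <- response_loglik(ds$responses + cshift, "HGF", p_shift, 1.5,
                             ds$observations + cshift)
  expect_equal(base, shifted, tolerance = 1e-9)
})

test_that("optimizer handles rejected (-Inf) candidates and stays seeded", {
  # minimise a quadratic with a forbidden half-space
  fn <- function(x) if (x[1] < -0.5) Inf else sum((x - c(1, 2))^2)
  r1 <- cmaes_minimize(fn, c(0, 0), max_evals = 2000, restarts = 2, seed = 6)
  r2 <- cmaes_minimize(fn, c(0, 0), max_evals = 2000, restarts = 2, seed = 6)
  expect_identical(r1$par, r2$par)
  expect_lt(r1$value, 1e-6)
  # a multimodal standard test function (Rastrigin-like in 2-D)
  ras <- function(x) 20 + sum(x^2 - 10 * cos(2 * pi * x))
  rr <- cmaes_minimize(ras, c(2.5, -2.5), sigma0 = 1.5, max_evals = 6000,
                       restarts = 3, seed = 8)
  expect_lt(rr$value, 1e-4)
})

test_that("finite-difference Hessian is exact on quadratics and repair flags", {
  A <- matrix(c(3, 1, 0.5, 1, 2, 0.2, 0.5, 0.2, 1.5), 3, 3)
  A <- (A + t(A)) / 2
  f <- function(x) -0.5 * drop(t(x) %*% A %*% x) + sum(x)
  H <- fd_hessian(f, c(0.3, -0.2, 1))
  expect_equal(H, -A, tolerance = 1e-5)
  rep1 <- pd_repair(diag(c(2, -1)))
  expect_true(rep1$repaired)
  expect_gte(min(eigen(rep1$M, only.values = TRUE)$values), 1e-8 - 1e-12)
  rep2 <- pd_repair(diag(c(2, 1)))
  expect_false(rep2$repaired)
})
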