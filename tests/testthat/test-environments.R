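test_that("simulators are deterministic and sessions derive per-block seeds", {
  p <- switching_params()
  b1 <- simulate_switching(p, 200, seed = 7)
  b2 <- simulate_switching(p, 200, seed = 7)
  expect_identical(b1, b2)

  d <- diffusive_params()
  expect_identical(simulate_diffusive(d, 100, 3), simulate_diffusive(d, 100, 3))

  ses1 <- simulate_session(p, 5, 50, seed = 9)
  ses2 <- simulate_session(p, 5, 50, seed = 9)
  expect_identical(ses1, ses2)
  # N = 1 equals a single call with the derived seed
  expect_identical(simulate_session(p, 1, 50, seed = 9)[[1]],
                   simulate_switching(p, 50, derive_seed(9, 1)))
  # blocks differ from one another
  expect_false(identical(ses1[[1]]$observations, ses1[[2]]$observations))
})

test_that("degenerate limits of the switching process hold", {
  # h = 0, w1 = 0: state frozen at x0, observations pure noise around it
  b <- simulate_switching(switching_params(h = 0, w1 = 0, x0 = 2.5), 2000, 1)
  expect_true(all(b$hidden1 == 2.5))
  expect_true(all(b$hidden2 == 1L))
  expect_lt(abs(sd(b$observations - 2.5) - 1), 3 / sqrt(2 * 2000))
  # h = 1: every state an i.i.d. redraw
  b1 <- simulate_switching(switching_params(h = 1, w2 = 10), 20000, 2)
  expect_true(all(b1$hidden2 == 2L))
  expect_lt(abs(var(b1$hidden1) - 10), 3 * 10 * sqrt(2 / 19999))
  expect_lt(abs(cor(b1$hidden1[-1], b1$hidden1[-20000])), 0.03)
})

test_that("switching environment matches its stated change rate and redraw variance", {
  p <- switching_params(h = 0.1, w1 = 0.01, w2 = 10, s = 1)
  b <- simulate_switching(p, 100000, seed = 11)
  frac <- mean(b$hidden2 == 2L)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
  x_change <- b$hidden1[b$hidden2 == 2L]
  n <- length(x_change)
  expect_lt(abs(var(x_change) - 10), 3 * 10 * sqrt(2 / (n - 1)))
})

test_that("diffusive environment matches its stated volatility diffusion", {
  d <- diffusive_params(eta = 0.1, s = 1)
  b <- simulate_diffusive(d, 100000, seed = 13)
  incr2 <- diff(c(d$x0_2, b$hidden2))
  expect_lt(abs(var(incr2) - 0.1), 3 * 0.1 * sqrt(2 / (1e5 - 1)))
  # eta = 0: level-1 increments have variance exp(x0_2)
  b0 <- simulate_diffusive(diffusive_params(eta = 0, x0_2 = log(0.5)), 50000, 5)
  incr1 <- diff(c(0, b0$hidden1))
  expect_lt(abs(var(incr1) - 0.5), 3 * 0.5 * sqrt(2 / (5e4 - 1)))
  # s = 0: observations equal the hidden state
  bs <- simulate_diffusive(diffusive_params(s = 0), 100, 6)
  expect_identical(bs$observations, bs$hidden1)
})

test_that("switching with h = 0 and diffusive with matched constant volatility agree", {
  w1 <- 0.2
  bs <- simulate_switching(switching_params(h = 0, w1 = w1), 20000, 21)
  bd <- simulate_diffusive(diffusive_params(eta = 0, x0_2 = log(w1)), 20000, 22)
  vt <- var.test(diff(bs$hidden1), diff(bd$hidden1))
  expect_gt(vt$p.value, 0.001)
})

test_that("parameter validation rejects malformed environments", {
  expect_error(switching_params(h = 1.2), class = "cpmhgf_param_error")
  expect_error(switching_params(w1 = -1), class = "cpmhgf_param_error")
  expect_error(diffusive_params(eta = NaN), class = "cpmhgf_param_error")
  expect_error(simulate_switching(switching_params(), 0), class = "cpmhgf_param_error")
  expect_warning(switching_params(w2 = 0.5, s = 1), "w2 <= s")
})
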