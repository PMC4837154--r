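# Independent oracles used to validate the filter implementations.
# Each one takes a route DIFFERENT from the package code: the HGF oracle does
# the conjugate-Gaussian algebra and the calculus on the variational energy
# directly (no delta-rule auxiliaries); the CPM oracle mixes the conditional
# posteriors instead of using the precision-sum update; the Kalman oracle is
# the textbook predict/update recursion.

# --- HGF -------------------------------------------------------------------

# Variational energy of the level-2 state given the freshly updated level-1
# posterior (A = sigma1_new + (mu1_new - mu1_prev)^2).
hgf_I2 <- function(x2, A, sigma1_prev, mu2_prev, sigma2_prev, eta) {
  g <- exp(x2) + sigma1_prev
  -0.5 * (A / g + log(g) + (x2 - mu2_prev)^2 / (sigma2_prev + eta))
}

oracle_hgf_step <- function(state, o, params) {
  s <- params$s; eta <- params$eta
  E <- exp(state$mu2)
  gv <- state$sigma1 + E
  # level 1: conjugate normal posterior (precision-weighted mean form)
  prec1 <- 1 / s + 1 / gv
  sigma1 <- 1 / prec1
  mu1 <- sigma1 * (o / s + state$mu1 / gv)
  # level 2: single Newton step at the prior expectation using the analytic
  # first/second derivatives of the variational energy
  A <- sigma1 + (mu1 - state$mu1)^2
  g <- E + state$sigma1
  I2p <- -0.5 * (E / g - A * E / g^2)
  I2pp <- -0.5 * (E * state$sigma1 / g^2 - A * E * (state$sigma1 - E) / g^3 +
                    2 / (state$sigma2 + eta))
  sigma2 <- -1 / I2pp
  mu2 <- state$mu2 - I2p / I2pp
  list(mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
       alpha1 = sigma1 / s, eps1 = mu1 - state$mu1, eps2 = mu2 - state$mu2)
}

# Numerical-derivative crosscheck of the analytic oracle itself (coarser
# tolerance; validates the calculus, not the package).
oracle_hgf_level2_numeric <- function(state, o, params, h = 1e-4) {
  st <- oracle_hgf_step(state, o, params)
  A <- st$sigma1 + st$eps1^2
  f <- function(x) hgf_I2(x, A, state$sigma1, state$mu2, state$sigma2,
                          params$eta)
  x <- state$mu2
  d1 <- (8 * (f(x + h) - f(x - h)) - (f(x + 2 * h) - f(x - 2 * h))) / (12 * h)
  d2 <- (-f(x + 2 * h) + 16 * f(x + h) - 30 * f(x) + 16 * f(x - h) -
           f(x - 2 * h)) / (12 * h^2)
  list(mu2 = x - d1 / d2, sigma2 = -1 / d2)
}

# Free energy as Gaussian log-densities plus entropies (alternative
# decomposition of the same bound).
oracle_hgf_free_energy <- function(prev, new, o, params) {
  g <- prev$sigma1 + exp(new$mu2)
  V <- prev$sigma2 + params$eta
  entropy <- function(v) 0.5 * log(2 * pi * exp(1) * v)
  dnorm(o, new$mu1, sqrt(params$s), log = TRUE) - new$sigma1 / (2 * params$s) +
    dnorm(new$mu1, prev$mu1, sqrt(g), log = TRUE) - new$sigma1 / (2 * g) +
    dnorm(new$mu2, prev$mu2, sqrt(V), log = TRUE) - new$sigma2 / (2 * V) +
    entropy(new$sigma1) + entropy(new$sigma2)
}

# --- CPM -------------------------------------------------------------------

oracle_cpm_omega <- function(state, o, params) {
  d_change <- dnorm(o, 0, sqrt(params$s + params$w2)) * params$h
  d_stay <- dnorm(o, state$mu1, sqrt(state$sigma1 + params$w1 + params$s)) *
    (1 - params$h)
  d_change / (d_stay + d_change)
}

# Mixture-of-conditional-posteriors route: posterior given "no change" is the
# Kalman update, given "change" has mean (sigma|2/s) * o with sigma|2 = s;
# the variational posterior combines their precisions and precision-weighted
# means with weights (1 - Omega, Omega).
oracle_cpm_step <- function(state, o, params) {
  om <- oracle_cpm_omega(state, o, params)
  sig_c1 <- params$s * (state$sigma1 + params$w1) /
    (params$s + params$w1 + state$sigma1)
  mu_c1 <- state$mu1 + (sig_c1 / params$s) * (o - state$mu1)
  sig_c2 <- params$s
  mu_c2 <- (sig_c2 / params$s) * o
  prec <- (1 - om) / sig_c1 + om / sig_c2
  sigma1 <- 1 / prec
  mu1 <- sigma1 * ((1 - om) * mu_c1 / sig_c1 + om * mu_c2 / sig_c2)
  om_c <- min(max(om, 1e-12), 1 - 1e-12)
  mu2 <- log(om_c / (1 - om_c)) / params$a
  list(mu1 = mu1, sigma1 = sigma1, mu2 = mu2, omega = om,
       alpha1 = sigma1 / params$s, eps1 = mu1 - state$mu1,
       eps2 = mu2 - state$mu2)
}

oracle_cpm_surprise <- function(state, o, params) {
  -log(dnorm(o, state$mu1, sqrt(state$sigma1 + params$w1 + params$s)) *
         (1 - params$h) +
       dnorm(o, 0, sqrt(params$s + params$w2)) * params$h)
}

# --- Kalman filter (textbook predict/update) -------------------------------

oracle_kalman <- function(obs, mu0, sigma0, q, r) {
  T <- length(obs)
  mu <- sig <- gain <- numeric(T)
  m <- mu0; P <- sigma0
  for (t in seq_len(T)) {
    P_pred <- P + q
    K <- P_pred / (P_pred + r)
    m <- m + K * (obs[t] - m)
    P <- (1 - K) * P_pred
    mu[t] <- m; sig[t] <- P; gain[t] <- K
  }
  list(mu = mu, sigma = sig, gain = gain)
}

# --- Dirichlet exceedance by Monte Carlo -----------------------------------

mc_exceedance <- function(alpha, n = 1e6, seed = 1) {
  set.seed(seed)
  g1 <- rgamma(n, alpha[1]); g2 <- rgamma(n, alpha[2])
  p <- mean(g1 / (g1 + g2) > 0.5)
  list(p = p, se = sqrt(p * (1 - p) / n))
}

# --- random input tuples ---------------------------------------------------

random_hgf_inputs <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(state = belief_state(rnorm(1, 0, 3), exp(rnorm(1, 0, 1)),
                              rnorm(1, 0, 1.5), exp(rnorm(1, 0, 1))),
         o = rnorm(1, 0, 4),
         params = hgf_params(s = exp(rnorm(1, 0, 0.8)),
                             eta = exp(rnorm(1, -1, 0.8))))
  })
}

random_cpm_inputs <- function(n, seed = 43) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(state = belief_state(rnorm(1, 0, 3), exp(rnorm(1, 0, 1)),
                              rnorm(1, 0, 1)),
         o = rnorm(1, 0, 4),
         params = suppressWarnings(
           cpm_params(s = exp(rnorm(1, 0, 0.8)),
                      w1 = exp(rnorm(1, -3, 1)),
                      w2 = exp(rnorm(1, 2, 1)),
                      h = plogis(rnorm(1, -2, 1)))))
  })
}
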