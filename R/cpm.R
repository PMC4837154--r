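## Variational Change Point Model: change-point probability, single-trial
## update, and exact per-trial surprise.

OMEGA_CLAMP <- 1e-12

logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  ifelse(is.infinite(m) & m < 0, -Inf, m + log(exp(a - m) + exp(b - m)))
}

#' Change-point probability
#'
#' Posterior probability, given the current observation, that the hidden state
#' was just redrawn rather than continuing its random walk. Computed from the
#' two predictive densities (walk vs. redraw) weighted by the hazard `h`;
#' evaluated in log space for numerical stability. `h = 0` and `h = 1` are
#' exact limits.
#'
#' @param state A [belief_state()] (only `mu1`, `sigma1` enter).
#' @param o The current observation.
#' @param params A [cpm_params()] object.
#' @return The change-point probability in \[0, 1\].
#' @export
cpm_change_probability <- function(state, o, params) {
  if (state$sigma1 <= 0) stop_param("'sigma1' must be > 0")
  h <- params$h
  if (h == 0) return(0)
  if (h == 1) return(1)
  l_stay <- stats::dnorm(o, state$mu1,
                         sqrt(state$sigma1 + params$w1 + params$s),
                         log = TRUE) + log1p(-h)
  l_change <- stats::dnorm(o, 0, sqrt(params$s + params$w2),
                           log = TRUE) + log(h)
  1 / (1 + exp(l_stay - l_change))
}

#' Exact per-trial surprise of the CPM
#'
#' Negative log of the two-component predictive mixture (walk vs. redraw)
#' evaluated at the current observation; exact, unlike the HGF's variational
#' bound.
#'
#' @inheritParams cpm_change_probability
#' @return The surprise (negative predictive log-density), a scalar.
#' @export
cpm_trial_surprise <- function(state, o, params) {
  if (state$sigma1 <= 0) stop_param("'sigma1' must be > 0")
  h <- params$h
  l_stay <- stats::dnorm(o, state$mu1,
                         sqrt(state$sigma1 + params$w1 + params$s),
                         log = TRUE)
  l_change <- stats::dnorm(o, 0, sqrt(params$s + params$w2), log = TRUE)
  if (h == 0) return(-l_stay)
  if (h == 1) return(-l_change)
  -logsumexp2(l_stay + log1p(-h), l_change + log(h))
}

#' One CPM belief update
#'
#' The change-point probability inflates the learning rate: the posterior
#' precision mixes the walk-conditional precision (weight `1 - Omega`) with
#' the observation precision. The level-2 expectation is the (scaled) logit
#' of the change-point probability, giving a volatility-like quantity
#' comparable to the HGF's level 2; `Omega` is clamped to
#' `[1e-12, 1 - 1e-12]` before the logit so it stays finite.
#'
#' @inheritParams cpm_change_probability
#' @return A list with elements `state` (new `belief_state`, `sigma2 = NA`)
#'   and `internals` (named list: `alpha1`, `eps1`, `eps2`, `omega`).
#' @export
cpm_step <- function(state, o, params) {
  omega <- cpm_change_probability(state, o, params)
  sigma1 <- 1 / ((1 - omega) / (state$sigma1 + params$w1) + 1 / params$s)
  alpha1 <- sigma1 / params$s
  eps1 <- alpha1 * (o - state$mu1)
  mu1 <- state$mu1 + eps1
  om_c <- min(max(omega, OMEGA_CLAMP), 1 - OMEGA_CLAMP)
  mu2 <- log(om_c / (1 - om_c)) / params$a
  eps2 <- mu2 - state$mu2
  list(
    state = belief_state(mu1, sigma1, mu2, NA_real_),
    internals = list(alpha1 = alpha1, eps1 = eps1, eps2 = eps2, omega = omega)
  )
}

#' Initial level-2 expectation of the CPM
#'
#' The prior change-point probability (before any data) is the hazard `h`, so
#' the level-2 state is seeded at its clamped logit divided by `a`.
#' @param params A [cpm_params()] object.
#' @return A scalar.
#' @export
cpm_mu0_2 <- function(params) {
  h_c <- min(max(params$h, OMEGA_CLAMP), 1 - OMEGA_CLAMP)
  log(h_c / (1 - h_c)) / params$a
}
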