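## Two-level Hierarchical Gaussian Filter: single-trial belief update and
## per-trial variational free energy. These R functions are the reference
## implementation; run_filter() uses a compiled transcription of the same
## update for speed (equality is enforced by the test suite).

#' Belief state of a perceptual filter
#'
#' @param mu1,sigma1 Level-1 posterior expectation and uncertainty (variance).
#' @param mu2,sigma2 Level-2 posterior expectation and uncertainty; `sigma2`
#'   is `NA` for the change-point filter, which carries no level-2 variance.
#' @return An object of class `belief_state`.
#' @export
belief_state <- function(mu1, sigma1, mu2 = 0, sigma2 = NA_real_) {
  if (sigma1 <= 0) stop_param("'sigma1' must be > 0")
  if (!is.na(sigma2) && sigma2 <= 0) stop_param("'sigma2' must be > 0")
  structure(list(mu1 = as.numeric(mu1), sigma1 = as.numeric(sigma1),
                 mu2 = as.numeric(mu2), sigma2 = as.numeric(sigma2)),
            class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state: mu1 = %.4g, sigma1 = %.4g, mu2 = %.4g, sigma2 = %s>\n",
              x$mu1, x$sigma1, x$mu2,
              if (is.na(x$sigma2)) "NA" else format(x$sigma2, digits = 4)))
  invisible(x)
}

hgf_invalid <- function(msg) {
  stop(structure(
    class = c("cpmhgf_invalid_update", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' One HGF belief update
#'
#' Updates the level-1 belief about the hidden state with a precision-weighted
#' prediction error, then propagates a volatility prediction error to level 2
#' via a single Newton step linearised at the prior expectation. Returns the
#' new state together with the trial internals (learning rate, prediction
#' errors, the level-2 auxiliaries and the trial free energy is computed
#' separately by [hgf_trial_free_energy()]).
#'
#' @param state A [belief_state()] with positive `sigma1`, `sigma2`.
#' @param o The current observation.
#' @param params An [hgf_params()] object (only `s` and `eta` enter the
#'   update; the prior-expectation fields seed the state at block start).
#' @return A list with elements `state` (new `belief_state`) and `internals`
#'   (named list: `alpha1`, `eps1`, `eps2`, `delta2`, `w2t`, `r2t`).
#'   Signals an invalid-update condition if the level-2 precision update is
#'   non-positive.
#' @export
hgf_step <- function(state, o, params) {
  s <- params$s; eta <- params$eta
  E <- exp(state$mu2)
  g <- state$sigma1 + E              # level-1 predictive variance (pre-noise)
  sigma1 <- 1 / (1 / s + 1 / g)
  alpha1 <- sigma1 / s
  eps1 <- alpha1 * (o - state$mu1)
  mu1 <- state$mu1 + eps1
  w2t <- E / g
  r2t <- (E - state$sigma1) / g
  delta2 <- (sigma1 + eps1^2) / g - 1
  prec2 <- 1 / (state$sigma2 + eta) + 0.5 * w2t * (w2t + r2t * delta2)
  if (!is.finite(prec2) || prec2 <= 0)
    hgf_invalid("level-2 precision update is non-positive")
  sigma2 <- 1 / prec2
  alpha2 <- 0.5 * sigma2 * w2t
  eps2 <- alpha2 * delta2
  mu2 <- state$mu2 + eps2
  list(
    state = belief_state(mu1, sigma1, mu2, sigma2),
    internals = list(alpha1 = alpha1, eps1 = eps1, eps2 = eps2,
                     delta2 = delta2, w2t = w2t, r2t = r2t)
  )
}

#' Per-trial variational free energy of the HGF
#'
#' Lower bound on the marginal log-likelihood of the current observation given
#' the past, evaluated from the pre- and post-update belief states. The trial
#' surprise used by [run_filter()] is its negative.
#'
#' @param prev Belief state before observing `o`.
#' @param new Belief state after the update ([hgf_step()]).
#' @param o The observation.
#' @param params An [hgf_params()] object.
#' @return The free-energy value F_t (a scalar; surprise is -F_t).
#' @export
hgf_trial_free_energy <- function(prev, new, o, params) {
  s <- params$s; eta <- params$eta
  if (s <= 0 || prev$sigma1 <= 0 || prev$sigma2 <= 0 ||
      new$sigma1 <= 0 || new$sigma2 <= 0)
    stop_param("variances must be positive")
  g_post <- prev$sigma1 + exp(new$mu2)
  -0.5 * log(s) - (new$sigma1 + (o - new$mu1)^2) / (2 * s) -
    0.5 * log(g_post) -
    (new$sigma1 + (new$mu1 - prev$mu1)^2) / (2 * g_post) -
    0.5 * log(prev$sigma2 + eta) -
    (new$sigma2 + (new$mu2 - prev$mu2)^2) / (2 * (prev$sigma2 + eta)) -
    0.5 * log(2 * pi) + 1 + 0.5 * log(new$sigma1 * new$sigma2)
}
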