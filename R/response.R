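## Gaussian response model: responses are the level-1 posterior expectation
## corrupted by noise of variance sigma_r, and the response likelihood is the
## product of per-trial normal densities around the filtered mu1 trajectory.

#' Generate noisy behavioural responses from a belief trajectory
#'
#' @param trajectory A `belief_trajectory` (from [run_filter()]).
#' @param sigma_r Response-noise VARIANCE (>= 0); typical low and high noise
#'   conditions are 1 and 5.
#' @param seed Integer seed.
#' @return Numeric vector of responses, one per trial.
#' @export
generate_responses <- function(trajectory, sigma_r, seed = 1L) {
  stopifnot(inherits(trajectory, "belief_trajectory"))
  if (sigma_r < 0) stop_param("'sigma_r' must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trajectory$internals$mu1 + sqrt(sigma_r) * stats::rnorm(trajectory$T)
}

#' A simulated agent: stimuli, beliefs and responses with known truths
#'
#' Bundles one stimulus block with the responses of a simulated agent and the
#' generating model and parameters, for recovery scoring.
#'
#' @param stimuli A `stimulus_block` (or plain numeric observations).
#' @param responses Numeric responses, same length.
#' @param generating_model `"HGF"` or `"CPM"`.
#' @param perc_params The generating perceptual parameters.
#' @param sigma_r The generating response-noise variance.
#' @param seed Seed used to draw the responses.
#' @return An object of class `behavioral_dataset`.
#' @export
behavioral_dataset <- function(stimuli, responses, generating_model,
                               perc_params, sigma_r, seed = NA_integer_) {
  obs <- if (inherits(stimuli, "stimulus_block")) stimuli$observations
         else as.numeric(stimuli)
  if (length(responses) != length(obs))
    stop_param("responses and stimuli must have the same length")
  structure(list(stimuli = stimuli, observations = obs,
                 responses = as.numeric(responses),
                 generating_model = match_model(generating_model),
                 perc_params = perc_params, sigma_r = sigma_r,
                 seed = seed, T = length(obs)),
            class = "behavioral_dataset")
}

#' @export
print.behavioral_dataset <- function(x, ...) {
  cat(sprintf("<behavioral_dataset: %s agent, T = %d, sigma_r = %.3g>\n",
              x$generating_model, x$T, x$sigma_r))
  invisible(x)
}

#' Simulate one agent end to end
#'
#' Runs the stated filter over a stimulus block and draws noisy responses.
#'
#' @param model `"HGF"` or `"CPM"`.
#' @param perc_params Matching perceptual parameters.
#' @param stimuli A `stimulus_block` or numeric observations.
#' @param sigma_r Response-noise variance.
#' @param seed Integer seed for the response noise.
#' @return A `behavioral_dataset`.
#' @export
simulate_agent <- function(model, perc_params, stimuli, sigma_r, seed = 1L) {
  tr <- run_filter(model, perc_params, stimuli)
  r <- generate_responses(tr, sigma_r, seed)
  behavioral_dataset(stimuli, r, model, perc_params, sigma_r, seed)
}

#' Response log-likelihood of a behavioural model
#'
#' Sum of per-trial Gaussian log-densities of the responses around the mu1
#' trajectory obtained by running the stated filter on the stimuli. Parameter
#' sets that trigger an invalid filter update return `-Inf` rather than
#' raising, so optimisers treat them as rejected candidates.
#'
#' @param responses Numeric responses.
#' @param model `"HGF"` or `"CPM"`.
#' @param params Matching perceptual parameters.
#' @param sigma_r Response-noise variance (> 0).
#' @param stimuli Observations (numeric or `stimulus_block`).
#' @return The log-likelihood (scalar; `-Inf` for invalid parameter sets).
#' @export
response_loglik <- function(responses, model, params, sigma_r, stimuli) {
  model <- match_model(model)
  obs <- if (inherits(stimuli, "stimulus_block")) stimuli$observations
         else as.numeric(stimuli)
  if (length(responses) != length(obs))
    stop_param("responses and stimuli must have the same length")
  if (!is.finite(sigma_r) || sigma_r <= 0) return(-Inf)
  if (model == "HGF") {
    cpp_hgf_loglik(obs, responses, params$mu0_1, params$sigma0_1, params$s,
                   params$mu0_2, params$sigma0_2, params$eta, sigma_r)
  } else {
    cpp_cpm_loglik(obs, responses, params$mu0_1, params$sigma0_1, params$s,
                   params$w1, params$w2, params$h, params$a, sigma_r)
  }
}
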