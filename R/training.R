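## Training-session emulation: find the perceptual parameters that minimise
## total surprise (maximise summed free energy / marginal log-likelihood) over
## many stimulus blocks, under the transformed-space prior.

blocks_to_matrix <- function(blocks) {
  if (inherits(blocks, "stimulus_block")) blocks <- list(blocks)
  obs <- lapply(blocks, function(b) {
    if (inherits(b, "stimulus_block")) b$observations else as.numeric(b)
  })
  Ts <- vapply(obs, length, integer(1))
  if (length(unique(Ts)) != 1L)
    stop_param("all blocks must have the same number of trials")
  matrix(unlist(obs), nrow = Ts[1])
}

#' Total surprise of a perceptual model over a set of blocks
#'
#' Beliefs are reset to the prior state at every block start. For the HGF this
#' is the negative summed variational free energy; for the CPM the exact
#' negative marginal log-likelihood. Invalid updates give `Inf`.
#'
#' @param model `"HGF"` or `"CPM"`.
#' @param params Matching perceptual parameters.
#' @param blocks A list of `stimulus_block`s (or one block, or a numeric
#'   matrix with one block per column).
#' @return Scalar total surprise.
#' @export
total_surprise <- function(model, params, blocks) {
  model <- match_model(model)
  obs <- if (is.matrix(blocks)) blocks else blocks_to_matrix(blocks)
  if (model == "HGF") {
    cpp_hgf_total_surprise(obs, params$mu0_1, params$sigma0_1, params$s,
                           params$mu0_2, params$sigma0_2, params$eta)
  } else {
    cpp_cpm_total_surprise(obs, params$mu0_1, params$sigma0_1, params$s,
                           params$w1, params$w2, params$h, params$a)
  }
}

#' Train a perceptual model on a stimulus session
#'
#' Maximises `log p(theta) + sum_blocks sum_t F_t(theta)` over the
#' transformed perceptual-parameter space (prior as in [prior_spec()] with
#' the response-noise entry dropped). This emulates a participant's training
#' session: after it, the agent's internal model of the environment is as
#' good as the stimulus statistics allow.
#'
#' @param model `"HGF"` or `"CPM"`.
#' @param blocks List of `stimulus_block`s (beliefs reset at each block).
#' @param prior A `prior_spec` with `perceptual_only = TRUE` (default built
#'   from the model).
#' @param config An [optimizer_config()].
#' @param seed Optimiser seed.
#' @return An object of class `training_result`: `theta_star` (natural-scale
#'   perceptual parameter object), `rho_star`, `objective_value`
#'   (the maximised penalised free energy), `n_blocks`, `T`, `trace`.
#' @export
train_perceptual <- function(model, blocks, prior = NULL,
                             config = optimizer_config(max_evals = 3000),
                             seed = 1L) {
  model <- match_model(model)
  if (is.null(prior)) prior <- prior_spec(model, perceptual_only = TRUE)
  stopifnot(length(prior$names) == nrow(param_info(model, TRUE)))
  obs <- blocks_to_matrix(blocks)
  info <- param_info(model, perceptual_only = TRUE)
  tags <- info$transform

  neg_obj <- function(rho) {
    if (any(!is.finite(rho)) || any(abs(rho) > 50)) return(Inf)
    nat <- mapply(apply_untransform, rho, tags)
    if (any(!is.finite(nat))) return(Inf)
    srp <- if (model == "HGF") {
      cpp_hgf_total_surprise(obs, nat[1], nat[2], nat[3], nat[4], nat[5],
                             nat[6])
    } else {
      cpp_cpm_total_surprise(obs, nat[1], nat[2], nat[3], nat[4], nat[5],
                             nat[6], 1)
    }
    srp - log_prior(rho, prior)
  }

  res <- cmaes_minimize(neg_obj, x0 = prior$mean, sigma0 = config$sigma0,
                        max_evals = config$max_evals,
                        restarts = config$restarts, seed = seed,
                        polish = config$polish)
  rho_star <- stats::setNames(res$par, info$name)
  theta <- params_from_rho(rho_star, model, perceptual_only = TRUE)$perc
  structure(list(
    model = model,
    theta_star = theta,
    rho_star = rho_star,
    objective_value = -res$value,
    n_blocks = ncol(obs), T = nrow(obs),
    trace = list(evals = res$evals, converged = res$converged,
                 incumbents = -res$incumbents, seed = res$seed)
  ), class = "training_result")
}

#' @export
print.training_result <- function(x, ...) {
  cat(sprintf("<training_result: %s over %d blocks x %d trials>\n",
              x$model, x$n_blocks, x$T))
  cat(sprintf("  penalised free energy at optimum: %.4f (evals = %d)\n",
              x$objective_value, x$trace$evals))
  print(x$theta_star)
  invisible(x)
}
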