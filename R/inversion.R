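## Behavioural model inversion: seven-parameter fits of the full model
## (perceptual + response) in the unconstrained transformed space, either by
## Bayesian inference with a Laplace approximation of the evidence (BI-LA) or
## by maximum likelihood with the BIC as the evidence surrogate (MLE).

## Fast transformed-space log-likelihood closure (avoids constructing
## parameter objects in the optimiser's inner loop).
make_loglik_rho <- function(model, obs, resp, a = 1) {
  model <- match_model(model)
  tags <- param_info(model)$transform
  if (model == "HGF") {
    function(rho) {
      if (any(!is.finite(rho)) || any(abs(rho) > 50)) return(-Inf)
      nat <- mapply(apply_untransform, rho, tags)
      if (any(!is.finite(nat))) return(-Inf)
      cpp_hgf_loglik(obs, resp, nat[1], nat[2], nat[3], nat[4], nat[5],
                     nat[6], nat[7])
    }
  } else {
    function(rho) {
      if (any(!is.finite(rho)) || any(abs(rho) > 50)) return(-Inf)
      nat <- mapply(apply_untransform, rho, tags)
      if (any(!is.finite(nat))) return(-Inf)
      cpp_cpm_loglik(obs, resp, nat[1], nat[2], nat[3], nat[4], nat[5],
                     nat[6], a, nat[7])
    }
  }
}

new_fit_result <- function(method, model, rho_star, covariance, log_evidence,
                           log_at_mode, d, T, diagnostics) {
  dimnames(covariance) <- list(names(rho_star), names(rho_star))
  structure(list(method = method, model = model, rho_star = rho_star,
                 covariance = covariance, sd = sqrt(diag(covariance)),
                 log_evidence = log_evidence, log_at_mode = log_at_mode,
                 d = d, T = T, diagnostics = diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s / %s, d = %d, T = %d>\n",
              x$method, x$model, x$d, x$T))
  cat(sprintf("  log evidence = %.4f (evals = %d%s)\n", x$log_evidence,
              x$diagnostics$evals,
              if (isTRUE(x$diagnostics$repaired)) ", Hessian ridge-repaired" else ""))
  print(data.frame(rho = x$rho_star, sd = x$sd))
  invisible(x)
}

curvature_from <- function(fn, rho_star) {
  ## The mode can lie close to a region where the filter update is invalid
  ## (objective -Inf); shrink the probe step until all evaluations are
  ## finite, and as a last resort drop the offending cross terms.
  H <- NULL
  fallback <- FALSE
  for (step in c(1e-4, 2e-5, 4e-6)) {
    Htry <- fd_hessian(fn, rho_star, step_frac = step)
    if (all(is.finite(Htry))) { H <- Htry; break }
  }
  if (is.null(H)) {
    H <- Htry
    H[!is.finite(H)] <- 0
    dg <- diag(H)
    dg[!is.finite(dg) | dg >= 0] <- -1
    diag(H) <- dg
    fallback <- TRUE
  }
  ## invert through the eigendecomposition: the curvature can be extremely
  ## ill-conditioned when some direction is barely identified
  negH <- -(H + t(H)) / 2
  eg <- eigen(negH, symmetric = TRUE)
  lam <- eg$values
  repaired <- any(lam < 1e-8)
  ridge <- if (repaired) 1e-8 - min(lam) else 0
  lam <- pmax(lam, 1e-8)
  S <- eg$vectors %*% (t(eg$vectors) / lam)
  S <- (S + t(S)) / 2
  list(S = S, logdet_neg = sum(log(lam)), repaired = repaired || fallback,
       ridge = ridge)
}

#' Fit a behavioural model by Bayesian inference with Laplace approximation
#'
#' Maximises the log-joint `log p(R | rho, O, m) + log p(rho)` in the
#' transformed space by seeded CMA-ES, then approximates the posterior by a
#' Gaussian centred at the mode with covariance equal to the inverse negative
#' Hessian (central finite differences; ridge-repaired to positive definite if
#' necessary, flagged). The log model evidence is the Laplace value
#' `log-joint(rho*) + 1/2 log |2 pi S(rho*)|`.
#'
#' @param dataset A [behavioral_dataset()].
#' @param model Candidate model to fit, `"HGF"` or `"CPM"` (need not equal the
#'   generating model).
#' @param prior A full 7-parameter [prior_spec()] (default for the model).
#' @param config An [optimizer_config()].
#' @param seed Optimiser seed.
#' @return A `fit_result` with `method = "BI-LA"`.
#' @export
fit_bi_la <- function(dataset, model, prior = NULL,
                      config = optimizer_config(), seed = 1L) {
  model <- match_model(model)
  stopifnot(inherits(dataset, "behavioral_dataset"))
  if (is.null(prior)) prior <- prior_spec(model)
  if (length(prior$names) != 7L)
    stop_param("BI-LA requires the full 7-parameter prior")
  ll <- make_loglik_rho(model, dataset$observations, dataset$responses)
  logjoint <- function(rho) {
    v <- ll(rho)
    if (!is.finite(v)) return(-Inf)
    v + log_prior(rho, prior)
  }
  res <- cmaes_minimize(function(rho) -logjoint(rho), x0 = prior$mean,
                        sigma0 = config$sigma0, max_evals = config$max_evals,
                        restarts = config$restarts, seed = seed,
                        polish = config$polish)
  rho_star <- stats::setNames(res$par, prior$names)
  lj <- -res$value
  cv <- curvature_from(logjoint, rho_star)
  d <- length(rho_star)
  log_ev <- lj + 0.5 * d * log(2 * pi) - 0.5 * cv$logdet_neg
  new_fit_result("BI-LA", model, rho_star, cv$S, log_ev, lj, d, dataset$T,
                 list(evals = res$evals, converged = res$converged,
                      repaired = cv$repaired, ridge = cv$ridge,
                      seed = res$seed))
}

#' Fit a behavioural model by maximum likelihood with BIC evidence
#'
#' Maximises the response log-likelihood alone in the same transformed space
#' (no prior), reports `log evidence = loglik(rho*) - d/2 log T` (BIC) and
#' parameter uncertainty from the inverse negative Hessian of the
#' log-likelihood at the maximum.
#'
#' @inheritParams fit_bi_la
#' @return A `fit_result` with `method = "MLE"`.
#' @export
fit_mle <- function(dataset, model, config = optimizer_config(), seed = 1L) {
  model <- match_model(model)
  stopifnot(inherits(dataset, "behavioral_dataset"))
  info <- param_info(model)
  ll <- make_loglik_rho(model, dataset$observations, dataset$responses)
  x0 <- stats::setNames(info$prior_mean, info$name)
  res <- cmaes_minimize(function(rho) -ll(rho), x0 = x0,
                        sigma0 = config$sigma0, max_evals = config$max_evals,
                        restarts = config$restarts, seed = seed,
                        polish = config$polish)
  rho_star <- stats::setNames(res$par, info$name)
  lmax <- -res$value
  cv <- curvature_from(function(rho) {
    v <- ll(rho); if (is.finite(v)) v else -Inf
  }, rho_star)
  d <- length(rho_star)
  log_ev <- lmax - 0.5 * d * log(dataset$T)
  new_fit_result("MLE", model, rho_star, cv$S, log_ev, lmax, d, dataset$T,
                 list(evals = res$evals, converged = res$converged,
                      repaired = cv$repaired, ridge = cv$ridge,
                      seed = res$seed))
}
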