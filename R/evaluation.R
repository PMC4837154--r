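## Diagnostics reproducing the comparative analyses: filter performance,
## random-effects group Bayesian model selection, confusion matrices, recovery
## and coverage statistics, and trajectory correlations.

#' Root-mean-square error of posterior beliefs against the hidden state
#'
#' @param trajectory A `belief_trajectory`.
#' @param block The `stimulus_block` the filter was run on.
#' @return Scalar RMSE of `mu1` against `hidden1`; lower is better.
#' @export
performance_rmse <- function(trajectory, block) {
  stopifnot(inherits(trajectory, "belief_trajectory"),
            inherits(block, "stimulus_block"))
  if (trajectory$T != block$T) stop_param("trajectory/block length mismatch")
  sqrt(mean((trajectory$internals$mu1 - block$hidden1)^2))
}

#' Random-effects group Bayesian model selection
#'
#' Variational Dirichlet scheme for model frequencies in a population: given a
#' k-agents-by-m-models matrix of log evidences, iterates the posterior model
#' assignments and the Dirichlet pseudo-counts (uniform Dirichlet(1, ..., 1)
#' prior) to convergence. For two models the exceedance probability — the
#' posterior probability that one model is the more frequent in the population
#' — has the closed form `P(r1 > 1/2)` under a Beta posterior, computed with
#' the regularised incomplete beta function.
#'
#' @param log_evidence_matrix Numeric matrix, k agents x m models (m = 2 for
#'   the closed-form exceedance).
#' @param max_iter,tol Iteration controls for the variational update.
#' @return A `group_comparison` list: `alpha` (Dirichlet pseudo-counts),
#'   `expected_frequencies`, `exceedance_probabilities`, `winner` (column
#'   index with the highest exceedance).
#' @export
group_bms <- function(log_evidence_matrix, max_iter = 200, tol = 1e-8) {
  L <- as.matrix(log_evidence_matrix)
  if (any(!is.finite(L))) stop_param("log evidences must be finite")
  k <- nrow(L); m <- ncol(L)
  if (k < 1 || m < 2) stop_param("need >= 1 agents and >= 2 models")
  alpha0 <- rep(1, m)
  alpha <- alpha0 + k / m
  for (it in seq_len(max_iter)) {
    lw <- sweep(L, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  ef <- alpha / sum(alpha)
  xp <- if (m == 2) {
    p1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
    c(p1, 1 - p1)
  } else {
    rep(NA_real_, m) # closed form only implemented for two models
  }
  structure(list(alpha = alpha, expected_frequencies = ef,
                 exceedance_probabilities = xp,
                 winner = which.max(xp)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(data.frame(alpha = x$alpha,
                   expected_freq = x$expected_frequencies,
                   exceedance = x$exceedance_probabilities))
  invisible(x)
}

#' Model-recovery confusion matrix by group resampling
#'
#' Resamples groups of `k` agents (with replacement) from pools of fitted
#' agents, runs [group_bms()] on each group's two-model log-evidence matrix,
#' and tabulates which model wins (exceedance probability > 0.5) against the
#' model that truly generated the pool.
#'
#' @param pool A data frame with one row per fitted agent and columns
#'   `true_model` (`"HGF"`/`"CPM"`), `logev_hgf`, `logev_cpm`.
#' @param k Group size; behavioural group studies typically have about 20
#'   participants.
#' @param n_groups Number of resampled groups per true model.
#' @param seed Integer seed for the resampling.
#' @return A `confusion_matrix` object: 2 x 2 row-stochastic matrix of
#'   proportions (rows = true generating model, columns = inferred model),
#'   plus raw counts and the condition sizes.
#' @export
confusion_experiment <- function(pool, k = 20, n_groups = 500, seed = 1L) {
  stopifnot(all(c("true_model", "logev_hgf", "logev_cpm") %in% names(pool)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  models <- c("HGF", "CPM")
  counts <- matrix(0L, 2, 2, dimnames = list(true = models, inferred = models))
  for (tm in models) {
    sub <- pool[pool$true_model == tm, , drop = FALSE]
    if (nrow(sub) < k)
      stop_param("pool for ", tm, " has fewer than k = ", k, " agents")
    for (g in seq_len(n_groups)) {
      idx <- sample.int(nrow(sub), k, replace = TRUE)
      L <- cbind(sub$logev_hgf[idx], sub$logev_cpm[idx])
      win <- models[group_bms(L)$winner]
      counts[tm, win] <- counts[tm, win] + 1L
    }
  }
  structure(list(proportions = counts / n_groups, counts = counts,
                 k = k, n_groups = n_groups, seed = as.integer(seed)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: k = %d, %d groups per true model>\n",
              x$k, x$n_groups))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Parameter-recovery diagnostics: estimator RMSE and coverage
#'
#' For a set of fitted agents with known generating parameters, computes per
#' transformed-space parameter (i) the RMSE of the estimates against the
#' truths and (ii) the empirical coverage: the fraction of agents whose truth
#' lies within two posterior standard deviations of the estimate. A
#' calibrated Gaussian posterior gives coverage near 0.9545.
#'
#' @param fits List of `fit_result`s.
#' @param truths Matrix (agents x parameters) or list of named vectors of
#'   true transformed-space parameter values.
#' @return A `recovery_diagnostics` data frame: one row per parameter with
#'   `rmse` and `coverage`, plus attribute `n_excluded` (fits without a
#'   usable covariance).
#' @export
recovery_diagnostics <- function(fits, truths) {
  if (is.list(truths) && !is.matrix(truths)) truths <- do.call(rbind, truths)
  truths <- as.matrix(truths)
  stopifnot(length(fits) == nrow(truths))
  est <- do.call(rbind, lapply(fits, function(f) f$rho_star))
  sds <- do.call(rbind, lapply(fits, function(f) f$sd))
  ok <- apply(sds, 1, function(x) all(is.finite(x) & x > 0))
  n_excluded <- sum(!ok)
  est <- est[ok, , drop = FALSE]; sds <- sds[ok, , drop = FALSE]
  tru <- truths[ok, , drop = FALSE]
  err <- est - tru
  out <- data.frame(
    parameter = colnames(est),
    rmse = sqrt(colMeans(err^2)),
    coverage = colMeans(abs(err) <= 2 * sds),
    row.names = NULL
  )
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("recovery_diagnostics", "data.frame")
  out
}

#' Correlation between generating and inferred belief trajectories
#'
#' Runs the inference model's filter at a fitted point estimate on the same
#' stimuli and returns Pearson correlations of each internal variable against
#' the generating trajectory (matched by name: `mu1`, `alpha1`, `eps1`,
#' `mu2`, `eps2`). The first trial is skipped (the level-2 prediction error is
#' initialisation-dependent there). Zero-variance trajectories give `NA`.
#'
#' @param dataset A `behavioral_dataset` (carries the stimuli and the
#'   generating model + parameters).
#' @param fit A `fit_result` for the inference model.
#' @return Named numeric vector of correlation coefficients.
#' @export
trajectory_correlation <- function(dataset, fit) {
  stopifnot(inherits(dataset, "behavioral_dataset"),
            inherits(fit, "fit_result"))
  gen_tr <- run_filter(dataset$generating_model, dataset$perc_params,
                       dataset$observations)
  inf_par <- params_from_rho(fit$rho_star, fit$model)$perc
  inf_tr <- run_filter(fit$model, inf_par, dataset$observations,
                       on_invalid = "flag")
  vars <- c("mu1", "alpha1", "eps1", "mu2", "eps2")
  keep <- -1L # drop first trial
  out <- vapply(vars, function(v) {
    a <- gen_tr$internals[[v]][keep]
    b <- inf_tr$internals[[v]][keep]
    if (anyNA(a) || anyNA(b) ||
        stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  out
}

#' Probability that one correlation sample exceeds another's median
#'
#' Fraction of values in `corr_mle` strictly greater than the median of
#' `corr_bila`. Values below 0.5 indicate the BI-LA-based trajectories
#' correlate better with the truth than the MLE-based ones.
#'
#' @param corr_mle,corr_bila Numeric samples (NAs dropped).
#' @return Scalar probability.
#' @export
exceedance_vs_median <- function(corr_mle, corr_bila) {
  corr_mle <- corr_mle[!is.na(corr_mle)]
  corr_bila <- corr_bila[!is.na(corr_bila)]
  if (!length(corr_mle) || !length(corr_bila))
    stop_param("empty correlation sample")
  mean(corr_mle > stats::median(corr_bila))
}
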