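## Covariance Matrix Adaptation Evolution Strategy (CMA-ES), the stochastic
## global optimiser used for surprise minimisation and model inversion.
## Compact (mu/mu_w, lambda) implementation with rank-one + rank-mu covariance
## update and cumulative step-size adaptation, IPOP-style restarts (population
## doubling), and an optional local polish of the incumbent. No CMA-ES package
## is available in the target environment, hence this self-contained version.

cmaes_run <- function(fn, x0, sigma0, lambda, max_evals, tol_fun = 1e-9) {
  n <- length(x0)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0; sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n); B <- diag(n); D <- rep(1, n)
  invsqrtC <- diag(n)
  best_x <- x0; best_f <- fn(x0)
  evals <- 1L
  hist_f <- c()

  while (evals + lambda <= max_evals) {
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    f <- apply(arx, 2, fn)
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) { best_f <- f[ord[1]]; best_x <- arx[, ord[1]] }

    sel <- ord[seq_len(mu)]
    ymean <- drop(ary[, sel, drop = FALSE] %*% w)
    xmean <- xmean + sigma * ymean

    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * drop(invsqrtC %*% ymean)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * evals / lambda)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean
    artmp <- ary[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sigma) || sigma > 1e8) break

    C <- (C + t(C)) / 2
    eg <- eigen(C, symmetric = TRUE)
    if (any(eg$values <= 0) || any(!is.finite(eg$values))) break
    B <- eg$vectors; D <- sqrt(eg$values)
    invsqrtC <- B %*% (t(B) / D)

    hist_f <- c(hist_f, f[ord[1]])
    nh <- length(hist_f)
    if (nh > 15 && is.finite(best_f) &&
        abs(hist_f[nh] - hist_f[nh - 10]) < tol_fun * (abs(best_f) + 1e-12))
      break
    if (sigma * max(D) < 1e-11) break
  }
  list(par = best_x, value = best_f, evals = evals)
}

#' Minimise a function with seeded CMA-ES restarts
#'
#' @param fn Objective to minimise; may return `Inf` for rejected candidates.
#' @param x0 Starting point (also the restart centre).
#' @param sigma0 Initial global step size (default 1, matching the width of
#'   the transformed-space prior's central region).
#' @param max_evals Total evaluation budget across restarts.
#' @param restarts Number of CMA-ES runs; the population doubles each restart.
#' @param seed Integer seed (the optimiser is fully deterministic given it).
#' @param polish Run a Nelder-Mead refinement of the incumbent after the
#'   evolutionary search (recommended: sharpens the mode for curvature
#'   estimates).
#' @return A list: `par`, `value`, `evals`, `converged` (logical: at least
#'   one finite incumbent), `restarts`.
#' @export
cmaes_minimize <- function(fn, x0, sigma0 = 1, max_evals = 5000,
                           restarts = 3, seed = 1L, polish = TRUE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(x0)
  lambda0 <- 4L + floor(3 * log(n))
  best <- NULL
  evals_used <- 0L
  budget <- max(max_evals, 10 * lambda0)
  per_run <- ceiling(budget / restarts)
  incumbents <- numeric(0)
  for (r in seq_len(restarts)) {
    lambda <- lambda0 * 2L^(r - 1L)
    res <- cmaes_run(fn, x0, sigma0, lambda,
                     max_evals = min(per_run, budget - evals_used))
    evals_used <- evals_used + res$evals
    if (is.null(best) || res$value < best$value) best <- res
    incumbents <- c(incumbents, best$value)
    if (evals_used >= budget) break
  }
  if (polish && is.finite(best$value)) {
    pol <- tryCatch(
      if (n == 1L) {
        stats::optim(best$par, fn, method = "Brent",
                     lower = best$par - 5, upper = best$par + 5)
      } else {
        stats::optim(best$par, fn, method = "Nelder-Mead",
                     control = list(maxit = 400, reltol = 1e-12))
      },
      error = function(e) NULL)
    if (!is.null(pol) && is.finite(pol$value) && pol$value <= best$value) {
      best$par <- pol$par; best$value <- pol$value
      evals_used <- evals_used + pol$counts[["function"]]
    }
  }
  list(par = as.numeric(best$par), value = best$value, evals = evals_used,
       converged = is.finite(best$value), incumbents = incumbents,
       seed = as.integer(seed))
}

#' Optimiser configuration
#'
#' @param max_evals Total objective-evaluation budget.
#' @param restarts CMA-ES restarts (population doubles each time).
#' @param sigma0 Initial step size.
#' @param polish Nelder-Mead refinement of the incumbent.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(max_evals = 5000, restarts = 3, sigma0 = 1,
                             polish = TRUE) {
  structure(list(max_evals = max_evals, restarts = restarts,
                 sigma0 = sigma0, polish = polish),
            class = "optimizer_config")
}
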