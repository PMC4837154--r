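## Sequential application of a perceptual filter over a block of observations.

HGF_INTERNAL_COLS <- c("mu1", "sigma1", "mu2", "sigma2", "alpha1", "eps1",
                       "eps2", "delta2", "w2t", "r2t", "surprise")
CPM_INTERNAL_COLS <- c("mu1", "sigma1", "mu2", "alpha1", "eps1", "eps2",
                       "omega", "surprise")

new_belief_trajectory <- function(internals, total_surprise, model, params) {
  structure(list(internals = internals,
                 total_surprise = total_surprise,
                 model = model, params = params,
                 T = nrow(internals)),
            class = "belief_trajectory")
}

#' @export
print.belief_trajectory <- function(x, ...) {
  cat(sprintf("<belief_trajectory: %s, T = %d, total surprise = %.4f>\n",
              x$model, x$T, x$total_surprise))
  invisible(x)
}

#' @export
as.data.frame.belief_trajectory <- function(x, ...) {
  cbind(data.frame(trial = seq_len(x$T), model = x$model), x$internals)
}

#' Run a perceptual filter over a block of observations
#'
#' Applies [hgf_step()] or [cpm_step()] sequentially from the prior state
#' `(mu0, sigma0)`, accumulating per-trial internals and surprise. For the
#' HGF the per-trial surprise is the negative variational free energy
#' (a bound); for the CPM it is the exact negative predictive log-density.
#'
#' @param model `"HGF"` or `"CPM"`.
#' @param params The matching [hgf_params()] / [cpm_params()] object.
#' @param observations Numeric vector of observations (a `stimulus_block` is
#'   also accepted).
#' @param compiled Use the compiled filter (default). The pure-R path exists
#'   as the reference implementation; both give identical trajectories.
#' @param on_invalid What to do if the HGF level-2 precision update becomes
#'   non-positive: `"error"` (default; signals a condition carrying the trial
#'   index) or `"flag"` (returns a trajectory with `invalid_at` set and
#'   `total_surprise = Inf`, used during likelihood evaluation).
#' @return A `belief_trajectory`: data frame of per-trial internals,
#'   `total_surprise`, the model tag and parameters.
#' @export
#' @examples
#' blk <- simulate_switching(switching_params(), T = 50, seed = 1)
#' tr <- run_filter("CPM", cpm_params(), blk)
#' head(as.data.frame(tr))
run_filter <- function(model, params, observations, compiled = TRUE,
                       on_invalid = c("error", "flag")) {
  model <- match_model(model)
  on_invalid <- match.arg(on_invalid)
  if (inherits(observations, "stimulus_block"))
    observations <- observations$observations
  observations <- as.numeric(observations)
  if (length(observations) && any(!is.finite(observations)))
    stop_param("observations must be finite")
  if (model == "HGF") stopifnot(inherits(params, "hgf_params"))
  else stopifnot(inherits(params, "cpm_params"))

  T <- length(observations)
  cols <- if (model == "HGF") HGF_INTERNAL_COLS else CPM_INTERNAL_COLS
  if (T == 0L) {
    empty <- as.data.frame(matrix(numeric(0), 0, length(cols),
                                  dimnames = list(NULL, cols)))
    return(new_belief_trajectory(empty, 0, model, params))
  }

  if (compiled) {
    res <- if (model == "HGF") {
      cpp_hgf_filter(observations, params$mu0_1, params$sigma0_1, params$s,
                     params$mu0_2, params$sigma0_2, params$eta)
    } else {
      cpp_cpm_filter(observations, params$mu0_1, params$sigma0_1, params$s,
                     params$w1, params$w2, params$h, params$a)
    }
    if (res$invalid_at > 0) {
      if (on_invalid == "error")
        hgf_invalid(paste0("invalid filter update at trial ", res$invalid_at))
      internals <- as.data.frame(res$internals)
      names(internals) <- cols
      out <- new_belief_trajectory(internals, Inf, model, params)
      out$invalid_at <- res$invalid_at
      return(out)
    }
    internals <- as.data.frame(res$internals)
    names(internals) <- cols
    return(new_belief_trajectory(internals, res$total_surprise, model, params))
  }

  ## pure-R reference path
  mat <- matrix(NA_real_, T, length(cols), dimnames = list(NULL, cols))
  if (model == "HGF") {
    state <- belief_state(params$mu0_1, params$sigma0_1,
                          params$mu0_2, params$sigma0_2)
    for (t in seq_len(T)) {
      prev <- state
      step <- tryCatch(hgf_step(state, observations[t], params),
                       cpmhgf_invalid_update = function(e) e)
      if (inherits(step, "condition")) {
        if (on_invalid == "error")
          hgf_invalid(paste0("invalid filter update at trial ", t))
        internals <- as.data.frame(mat)
        out <- new_belief_trajectory(internals, Inf, model, params)
        out$invalid_at <- t
        return(out)
      }
      state <- step$state
      Ft <- hgf_trial_free_energy(prev, state, observations[t], params)
      mat[t, ] <- c(state$mu1, state$sigma1, state$mu2, state$sigma2,
                    step$internals$alpha1, step$internals$eps1,
                    step$internals$eps2, step$internals$delta2,
                    step$internals$w2t, step$internals$r2t, -Ft)
    }
  } else {
    state <- belief_state(params$mu0_1, params$sigma0_1, cpm_mu0_2(params))
    for (t in seq_len(T)) {
      surprise <- cpm_trial_surprise(state, observations[t], params)
      step <- cpm_step(state, observations[t], params)
      state <- step$state
      mat[t, ] <- c(state$mu1, state$sigma1, state$mu2,
                    step$internals$alpha1, step$internals$eps1,
                    step$internals$eps2, step$internals$omega, surprise)
    }
  }
  internals <- as.data.frame(mat)
  new_belief_trajectory(internals, sum(internals$surprise), model, params)
}
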