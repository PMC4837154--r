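## Generators for the two experimental environments. Both return a
## `stimulus_block`: the observation stream plus the hidden trajectories that
## produced it, with full seed bookkeeping.

#' Derive a per-block seed from a master seed
#'
#' Counter scheme used everywhere randomness is split across blocks or agents;
#' keeps derived seeds inside the 32-bit integer range.
#'
#' @param master Master seed (integer).
#' @param i Counter (1-based block/agent index, or any non-negative offset).
#' @return An integer seed.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.double(master) + 9973 * as.double(i)) %% 2147483647)
}

new_stimulus_block <- function(observations, hidden1, hidden2, env_kind,
                               seed, params) {
  stopifnot(length(observations) == length(hidden1),
            length(hidden2) == length(hidden1))
  structure(list(
    observations = observations,
    hidden1 = hidden1,
    hidden2 = hidden2,
    env_kind = env_kind,
    seed = seed,
    T = length(observations),
    params = params
  ), class = "stimulus_block")
}

#' @export
print.stimulus_block <- function(x, ...) {
  cat(sprintf("<stimulus_block: %s environment, T = %d, seed = %d>\n",
              x$env_kind, x$T, x$seed))
  invisible(x)
}

#' @export
as.data.frame.stimulus_block <- function(x, ...) {
  data.frame(trial = seq_len(x$T),
             observation = x$observations,
             hidden1 = x$hidden1,
             hidden2 = x$hidden2)
}

#' Simulate one block of the switching environment
#'
#' Per trial the hidden state is redrawn from N(0, w2) with probability `h`,
#' otherwise it continues a Gaussian random walk with variance `w1`;
#' observations add noise of variance `s`. `hidden2` records the change
#' indicator (1 = walk, 2 = redraw).
#'
#' @param params A [switching_params()] object.
#' @param T Number of trials (>= 1).
#' @param seed Integer seed; identical inputs give identical blocks.
#' @return A `stimulus_block`.
#' @export
#' @examples
#' blk <- simulate_switching(switching_params(), T = 100, seed = 1)
#' mean(blk$hidden2 == 2) # empirical change fraction, approx h
simulate_switching <- function(params, T, seed = 1L) {
  stopifnot(inherits(params, "switching_params"))
  T <- as.integer(T)
  if (T < 1L) stop_param("'T' must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- numeric(T); flag <- integer(T)
  prev <- params$x0
  change <- stats::runif(T) < params$h
  walk_noise <- stats::rnorm(T, 0, sqrt(params$w1))
  redraw <- stats::rnorm(T, 0, sqrt(params$w2))
  for (t in seq_len(T)) {
    if (change[t]) {
      prev <- redraw[t]; flag[t] <- 2L
    } else {
      prev <- prev + walk_noise[t]; flag[t] <- 1L
    }
    x[t] <- prev
  }
  o <- x + stats::rnorm(T, 0, sqrt(params$s))
  new_stimulus_block(o, x, flag, "switching", as.integer(seed), params)
}

#' Simulate one block of the diffusive environment
#'
#' The hidden state performs a Gaussian random walk whose variance is the
#' exponential of a latent log-volatility, itself a random walk with diffusion
#' variance `eta`. `hidden2` records the log-volatility trajectory.
#'
#' @inheritParams simulate_switching
#' @param params A [diffusive_params()] object.
#' @return A `stimulus_block`.
#' @export
simulate_diffusive <- function(params, T, seed = 1L) {
  stopifnot(inherits(params, "diffusive_params"))
  T <- as.integer(T)
  if (T < 1L) stop_param("'T' must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x2 <- params$x0_2 + cumsum(stats::rnorm(T, 0, sqrt(params$eta)))
  incr <- stats::rnorm(T, 0, 1) * exp(x2 / 2)
  x1 <- params$x0_1 + cumsum(incr)
  o <- x1 + stats::rnorm(T, 0, sqrt(params$s))
  new_stimulus_block(o, x1, x2, "diffusive", as.integer(seed), params)
}

#' Simulate a session of independent blocks
#'
#' Emulates an experimental session: `N` independent blocks of `T` trials,
#' hidden state re-initialised at every block start, per-block seeds derived
#' from the master seed with [derive_seed()].
#'
#' @param env A `switching_params` or `diffusive_params` object.
#' @param N Number of blocks.
#' @param T Trials per block.
#' @param seed Master seed.
#' @return A list of `stimulus_block`s of length `N`.
#' @export
simulate_session <- function(env, N, T, seed = 1L) {
  N <- as.integer(N)
  if (N < 1L) stop_param("'N' must be >= 1")
  sim <- if (inherits(env, "switching_params")) simulate_switching
         else simulate_diffusive
  lapply(seq_len(N), function(i) sim(env, T, derive_seed(seed, i)))
}

## Save/restore the global RNG state so seeded simulators do not disturb the
## caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
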