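## Parameter containers and validation for the two generative environments and
## the two perceptual filters. All Gaussian second arguments throughout the
## package are VARIANCES.

stop_param <- function(...) {
  stop(structure(
    class = c("cpmhgf_param_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop_param("'", name, "' must be a finite numeric scalar")
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  x <- check_scalar(x, name)
  if (x < 0) stop_param("'", name, "' must be >= 0, got ", x)
  x
}

check_pos <- function(x, name) {
  x <- check_scalar(x, name)
  if (x <= 0) stop_param("'", name, "' must be > 0, got ", x)
  x
}

#' Parameters of the switching (change-point) environment
#'
#' The hidden state follows a Gaussian random walk with variance `w1` and is,
#' with per-trial probability `h`, redrawn from a zero-mean Gaussian with
#' variance `w2`. Observations add Gaussian noise with variance `s`.
#'
#' @param h Per-trial change probability, in \[0, 1\].
#' @param w1 Diffusion variance of the stable random walk.
#' @param w2 Variance of the post-change redraw distribution.
#' @param s Observation-noise variance.
#' @param x0 Initial hidden state.
#'
#' @details The change-point filter's approximation assumes `w2 >> s`; a
#'   warning (not an error) is raised when `w2 <= s`.
#'
#' @return An object of class `switching_params`.
#' @export
#' @examples
#' switching_params() # the default environment: h = 0.1, w1 = 0.01, w2 = 10, s = 1
switching_params <- function(h = 0.1, w1 = 0.01, w2 = 10, s = 1, x0 = 0) {
  h <- check_scalar(h, "h")
  if (h < 0 || h > 1) stop_param("'h' must lie in [0, 1], got ", h)
  out <- structure(list(
    h = h,
    w1 = check_nonneg(w1, "w1"),
    w2 = check_nonneg(w2, "w2"),
    s = check_nonneg(s, "s"),
    x0 = check_scalar(x0, "x0")
  ), class = c("switching_params", "env_params"))
  if (out$w2 <= out$s)
    warning("w2 <= s: the change-point filter's conditional-uncertainty ",
            "approximation assumes w2 >> s", call. = FALSE)
  out
}

#' Parameters of the diffusive (volatility) environment
#'
#' The hidden state follows a Gaussian random walk whose log-variance (the
#' volatility) itself follows a random walk with diffusion variance `eta`.
#'
#' @param eta Diffusion variance of the volatility random walk.
#' @param s Observation-noise variance.
#' @param x0_1 Initial hidden state (level 1).
#' @param x0_2 Initial log-volatility (level 2). The default 0 starts the
#'   state diffusion at the scale of the observation noise, which keeps the
#'   environment comparable to the switching one and the learning-rate
#'   dynamics informative from the first trials.
#'
#' @return An object of class `diffusive_params`.
#' @export
diffusive_params <- function(eta = 0.1, s = 1, x0_1 = 0, x0_2 = 0) {
  structure(list(
    eta = check_nonneg(eta, "eta"),
    s = check_nonneg(s, "s"),
    x0_1 = check_scalar(x0_1, "x0_1"),
    x0_2 = check_scalar(x0_2, "x0_2")
  ), class = c("diffusive_params", "env_params"))
}

#' Perceptual parameters of the two-level Hierarchical Gaussian Filter
#'
#' @param mu0_1,sigma0_1 Prior expectation and uncertainty (variance) at
#'   level 1 at the start of a block.
#' @param s Believed observation-noise variance.
#' @param mu0_2,sigma0_2 Prior expectation and uncertainty at level 2
#'   (log-volatility).
#' @param eta Believed diffusion variance of the volatility random walk.
#'
#' @return An object of class `hgf_params`.
#' @export
hgf_params <- function(mu0_1 = 0, sigma0_1 = 1, s = 1,
                       mu0_2 = 0, sigma0_2 = 1, eta = 0.1) {
  structure(list(
    mu0_1 = check_scalar(mu0_1, "mu0_1"),
    sigma0_1 = check_pos(sigma0_1, "sigma0_1"),
    s = check_pos(s, "s"),
    mu0_2 = check_scalar(mu0_2, "mu0_2"),
    sigma0_2 = check_pos(sigma0_2, "sigma0_2"),
    eta = check_pos(eta, "eta")
  ), class = c("hgf_params", "perc_params"))
}

#' Perceptual parameters of the variational Change Point Model
#'
#' @param mu0_1,sigma0_1 Prior expectation and uncertainty (variance) at the
#'   start of a block.
#' @param s Believed observation-noise variance.
#' @param w1 Believed diffusion variance of the stable random walk.
#' @param w2 Believed redraw variance after a change.
#' @param h Believed per-trial change probability. The boundary values 0 and 1
#'   are accepted and handled as exact limits by the filter (h = 0 reduces the
#'   CPM to a Kalman filter); the logit transform used for inversion requires
#'   h strictly inside (0, 1).
#' @param a Positive scaling constant of the logit reparameterisation that
#'   maps the change-point probability onto a volatility-like level-2
#'   expectation; arbitrary, default 1.
#'
#' @return An object of class `cpm_params`.
#' @export
cpm_params <- function(mu0_1 = 0, sigma0_1 = 1, s = 1,
                       w1 = 0.01, w2 = 10, h = 0.1, a = 1) {
  h <- check_scalar(h, "h")
  if (h < 0 || h > 1) stop_param("'h' must lie in [0, 1], got ", h)
  structure(list(
    mu0_1 = check_scalar(mu0_1, "mu0_1"),
    sigma0_1 = check_pos(sigma0_1, "sigma0_1"),
    s = check_pos(s, "s"),
    w1 = check_pos(w1, "w1"),
    w2 = check_pos(w2, "w2"),
    h = h,
    a = check_pos(a, "a")
  ), class = c("cpm_params", "perc_params"))
}

#' @export
print.env_params <- function(x, ...) {
  kind <- if (inherits(x, "switching_params")) "switching" else "diffusive"
  cat(sprintf("<%s environment>\n", kind))
  flds <- vapply(x, function(v) format(v, digits = 6), character(1))
  cat(paste0("  ", names(flds), " = ", flds, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.perc_params <- function(x, ...) {
  kind <- if (inherits(x, "hgf_params")) "HGF" else "CPM"
  cat(sprintf("<%s perceptual parameters>\n", kind))
  flds <- vapply(x, function(v) format(v, digits = 6), character(1))
  cat(paste0("  ", names(flds), " = ", flds, collapse = "\n"), "\n")
  invisible(x)
}

## model tag helpers ---------------------------------------------------------

match_model <- function(model) {
  match.arg(toupper(model), c("HGF", "CPM"))
}

perc_params_for <- function(model) {
  if (model == "HGF") hgf_params else cpm_params
}
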