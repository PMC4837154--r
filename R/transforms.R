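## Unconstrained reparameterisation of the seven free parameters of each
## behavioural model, and the Gaussian prior placed on the transformed space.
## Location parameters stay as they are, variances are log-transformed and
## the hazard is logit-transformed.

#' Names, transforms and prior of a model's free parameters
#'
#' Each full behavioural model (perceptual + response) has seven free
#' parameters. `param_info` returns their canonical order, the per-parameter
#' transform tag and the default transformed-space prior (mean 0, variance 5,
#' except: volatility diffusion `eta` mean -2, redraw variance `w2` mean 7,
#' hazard `h` mean -3 with variance 2).
#'
#' @param model `"HGF"` or `"CPM"`.
#' @param perceptual_only If `TRUE`, drop the response-noise parameter
#'   (used when training perceptual parameters on stimuli alone).
#' @return A data frame with columns `name`, `transform`, `prior_mean`,
#'   `prior_var`.
#' @export
param_info <- function(model, perceptual_only = FALSE) {
  model <- match_model(model)
  if (model == "HGF") {
    out <- data.frame(
      name = c("mu0_1", "sigma0_1", "s", "mu0_2", "sigma0_2", "eta", "sigma_r"),
      transform = c("identity", "log", "log", "identity", "log", "log", "log"),
      prior_mean = c(0, 0, 0, 0, 0, -2, 0),
      prior_var = c(5, 5, 5, 5, 5, 5, 5),
      stringsAsFactors = FALSE
    )
  } else {
    out <- data.frame(
      name = c("mu0_1", "sigma0_1", "s", "w1", "w2", "h", "sigma_r"),
      transform = c("identity", "log", "log", "log", "log", "logit", "log"),
      prior_mean = c(0, 0, 0, 0, 7, -3, 0),
      prior_var = c(5, 5, 5, 5, 5, 2, 5),
      stringsAsFactors = FALSE
    )
  }
  if (perceptual_only) out <- out[out$name != "sigma_r", , drop = FALSE]
  out
}

apply_transform <- function(x, tag) {
  switch(tag,
         identity = x,
         log = {
           if (any(x <= 0)) stop_param("log transform requires x > 0")
           log(x)
         },
         logit = {
           if (any(x <= 0 | x >= 1)) stop_param("logit transform requires 0 < x < 1")
           log(x / (1 - x))
         },
         stop_param("unknown transform tag ", tag))
}

apply_untransform <- function(rho, tag) {
  switch(tag,
         identity = rho,
         log = exp(rho),
         logit = 1 / (1 + exp(-rho)),
         stop_param("unknown transform tag ", tag))
}

#' Map natural-scale parameters to the unconstrained space (and back)
#'
#' @param params A named numeric vector or a parameter object
#'   ([hgf_params()], [cpm_params()]) holding natural-scale values.
#' @param model `"HGF"` or `"CPM"`.
#' @param perceptual_only Drop `sigma_r` (see [param_info()]).
#' @return `transform_params`: named numeric vector `rho` in the transformed
#'   space. `untransform_params`: named numeric vector on the natural scale.
#' @export
transform_params <- function(params, model, perceptual_only = FALSE) {
  info <- param_info(model, perceptual_only)
  vals <- unlist(params)[info$name]
  if (any(is.na(vals)))
    stop_param("missing parameters: ",
               paste(info$name[is.na(vals)], collapse = ", "))
  rho <- mapply(apply_transform, vals, info$transform)
  stats::setNames(as.numeric(rho), info$name)
}

#' @rdname transform_params
#' @param rho Named (or ordered) numeric vector in the transformed space.
#' @export
untransform_params <- function(rho, model, perceptual_only = FALSE) {
  info <- param_info(model, perceptual_only)
  if (length(rho) != nrow(info))
    stop_param("expected ", nrow(info), " parameters, got ", length(rho))
  vals <- mapply(apply_untransform, as.numeric(rho), info$transform)
  stats::setNames(as.numeric(vals), info$name)
}

#' Rebuild a parameter object from a transformed-space vector
#'
#' @inheritParams untransform_params
#' @param a CPM logit scaling constant (fixed, not a free parameter).
#' @return A list with elements `perc` (an `hgf_params`/`cpm_params` object)
#'   and `sigma_r` (NA when `perceptual_only`).
#' @export
params_from_rho <- function(rho, model, perceptual_only = FALSE, a = 1) {
  model <- match_model(model)
  nat <- untransform_params(rho, model, perceptual_only)
  perc <- if (model == "HGF") {
    hgf_params(nat[["mu0_1"]], nat[["sigma0_1"]], nat[["s"]],
               nat[["mu0_2"]], nat[["sigma0_2"]], nat[["eta"]])
  } else {
    cpm_params(nat[["mu0_1"]], nat[["sigma0_1"]], nat[["s"]],
               nat[["w1"]], nat[["w2"]], nat[["h"]], a = a)
  }
  list(perc = perc,
       sigma_r = if (perceptual_only) NA_real_ else nat[["sigma_r"]])
}

#' Prior specification in the transformed space
#'
#' @param model `"HGF"` or `"CPM"`.
#' @param perceptual_only Drop the response-noise parameter.
#' @param mean,var Optional named overrides of prior means / variances.
#' @return An object of class `prior_spec` with fields `names`, `mean`, `var`.
#' @export
prior_spec <- function(model, perceptual_only = FALSE,
                       mean = NULL, var = NULL) {
  info <- param_info(model, perceptual_only)
  m <- stats::setNames(info$prior_mean, info$name)
  v <- stats::setNames(info$prior_var, info$name)
  if (!is.null(mean)) m[names(mean)] <- mean
  if (!is.null(var)) v[names(var)] <- var
  if (any(v <= 0)) stop_param("prior variances must be > 0")
  structure(list(names = info$name, mean = m, var = v,
                 model = match_model(model)),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec: %s, %d parameters (transformed space)>\n",
              x$model, length(x$names)))
  print(data.frame(mean = x$mean, var = x$var))
  invisible(x)
}

#' Log-density of the transformed-space prior
#'
#' Product of independent univariate normals (variance parameterisation).
#'
#' @param rho Numeric vector in the transformed space.
#' @param prior A [prior_spec()].
#' @return Scalar log-density.
#' @export
log_prior <- function(rho, prior) {
  stopifnot(inherits(prior, "prior_spec"))
  if (length(rho) != length(prior$mean))
    stop_param("dimension mismatch: rho has length ", length(rho))
  sum(stats::dnorm(as.numeric(rho), prior$mean, sqrt(prior$var), log = TRUE))
}
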