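## Plain-text persistence: tidy CSV tables with JSON sidecars carrying
## parameters and seeds, so every artifact is reproducible from disk.

params_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  out <- unclass(p)
  out[vapply(out, is.numeric, logical(1))]
}

#' Write / read a stimulus block
#'
#' CSV columns: `block`, `trial`, `observation`, `hidden1`, `hidden2`; a JSON
#' sidecar (`<path>.json`) records environment kind, parameters and seeds.
#' A list of blocks is written as one long table keyed by `block`.
#'
#' @param blocks A `stimulus_block` or list of them.
#' @param path Output CSV path.
#' @return `write_stimuli`: the path, invisibly. `read_stimuli`: a list of
#'   `stimulus_block`s.
#' @export
write_stimuli <- function(blocks, path) {
  if (inherits(blocks, "stimulus_block")) blocks <- list(blocks)
  tab <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    cbind(block = i, as.data.frame(blocks[[i]]))
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(
    env_kind = blocks[[1]]$env_kind,
    params = params_to_list(blocks[[1]]$params),
    seeds = vapply(blocks, function(b) b$seed, integer(1)),
    T = blocks[[1]]$T, N = length(blocks)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stimuli
#' @export
read_stimuli <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pars <- if (meta$env_kind == "switching") {
    do.call(switching_params, as.list(meta$params))
  } else {
    do.call(diffusive_params, as.list(meta$params))
  }
  lapply(split(tab, tab$block), function(d) {
    d <- d[order(d$trial), ]
    new_stimulus_block(d$observation, d$hidden1, d$hidden2, meta$env_kind,
                       meta$seeds[d$block[1]], pars)
  })
}

#' Write a belief trajectory as a tidy CSV
#'
#' One row per trial with every internal variable, plus a JSON sidecar with
#' the model tag and parameters.
#'
#' @param trajectory A `belief_trajectory`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  jsonlite::write_json(
    list(model = trajectory$model,
         params = params_to_list(trajectory$params),
         total_surprise = trajectory$total_surprise),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a behavioural dataset
#'
#' CSV columns `trial`, `observation`, `response`; the sidecar records the
#' generating model, its parameters, the response-noise variance and seeds.
#'
#' @param dataset A `behavioral_dataset`.
#' @param path Output CSV path.
#' @return `write_dataset`: the path, invisibly. `read_dataset`: a
#'   `behavioral_dataset` (stimuli as plain observations).
#' @export
write_dataset <- function(dataset, path) {
  tab <- data.frame(trial = seq_len(dataset$T),
                    observation = dataset$observations,
                    response = dataset$responses)
  utils::write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(
    list(generating_model = dataset$generating_model,
         perc_params = params_to_list(dataset$perc_params),
         sigma_r = dataset$sigma_r, seed = dataset$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ctor <- perc_params_for(match_model(meta$generating_model))
  behavioral_dataset(tab$observation, tab$response, meta$generating_model,
                     do.call(ctor, as.list(meta$perc_params)),
                     meta$sigma_r, meta$seed)
}

#' Serialise a fit result to JSON
#'
#' Arrays are written row-major; field names follow the `fit_result` object.
#'
#' @param fit A `fit_result`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(method = fit$method, model = fit$model,
         rho_star = as.list(fit$rho_star),
         covariance = fit$covariance,
         log_evidence = fit$log_evidence, log_at_mode = fit$log_at_mode,
         d = fit$d, T = fit$T, diagnostics = fit$diagnostics),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
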