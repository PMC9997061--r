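#' Save a model checkpoint
#'
#' A single archive holding the configuration and the named weight arrays,
#' with a versioned schema field.
#'
#' @param params A `model_params`.
#' @param config The matching [model_config()].
#' @param path Output path (conventionally `.ckpt`).
#' @export
save_checkpoint <- function(params, config, path) {
  saveRDS(list(schema = "invfold-checkpoint-v1",
               config = unclass(config),
               featurizer = unclass(config$featurizer),
               params = unclass(params)),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return List with `params` and `config`.
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$schema, "invfold-checkpoint-v1")) {
    stop("load_checkpoint: unrecognized checkpoint schema in ", path)
  }
  fz <- x$featurizer
  class(fz) <- "featurizer_config"
  cfg <- x$config
  cfg$featurizer <- fz
  class(cfg) <- "model_config"
  p <- x$params
  class(p) <- "model_params"
  list(params = p, config = cfg)
}
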