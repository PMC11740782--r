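#' Save and load trained models
#'
#' Checkpoints are written in R's native serialized format (`.rds`) holding
#' the layer parameters and the builder configuration, with a human-readable
#' JSON sidecar (`<path>.json`) recording the configuration, seed and
#' training history. Works for classifier models (`pocus_cnn`) and
#' translation models (`translator_pair`).
#'
#' @param model a trained `pocus_cnn` or `translator_pair`.
#' @param path checkpoint path (conventionally `.rds`).
#' @return `save_model` invisibly returns `path`; `load_model` returns the
#'   reconstructed model, whose predictions are identical to the original's.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "pocus_cnn")) {
    payload <- list(
      kind = "pocus_cnn", spec = model$spec, seed = model$seed,
      history = model$history, class_weights = model$class_weights,
      params = net_get_params(model$net)
    )
    sidecar <- list(kind = payload$kind, spec = unclass(model$spec),
                    seed = model$seed, history = model$history,
                    input_scale = "[0,1]")
  } else if (inherits(model, "translator_pair")) {
    payload <- list(
      kind = "translator_pair", config = model$config,
      history = model$history,
      params = lapply(model[c("g_st", "g_ts", "d_s", "d_t")], net_get_params)
    )
    sidecar <- list(kind = payload$kind, config = unclass(model$config),
                    history = model$history)
  } else {
    stop_pocusda("save_model supports pocus_cnn and translator_pair objects")
  }
  saveRDS(payload, path)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (identical(payload$kind, "pocus_cnn")) {
    model <- build_cnn(payload$spec, seed = payload$seed)
    net_set_params(model$net, payload$params)
    model$history <- payload$history
    model$class_weights <- payload$class_weights
    return(model)
  }
  if (identical(payload$kind, "translator_pair")) {
    pair <- with_seed(payload$config$seed, {
      list(g_st = build_generator(payload$config),
           g_ts = build_generator(payload$config),
           d_s = build_discriminator(payload$config),
           d_t = build_discriminator(payload$config))
    })
    for (nm in names(payload$params)) {
      net_set_params(pair[[nm]], payload$params[[nm]])
    }
    pair$config <- payload$config
    pair$history <- payload$history
    class(pair) <- "translator_pair"
    return(pair)
  }
  stop_pocusda("unrecognised checkpoint kind")
}
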