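#' Save a trained attention model to JSON
#'
#' Weights, normalization statistics and the full configuration are
#' written at full precision to a single JSON container, so a reloaded
#' model reproduces predictions bit-for-bit.
#'
#' @param model an `mha_model`.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  obj <- list(
    config = unclass(model$config),
    heads = lapply(model$heads, function(h)
      list(W = as.numeric(h$W), dim = dim(h$W), b = h$b)),
    W1 = as.numeric(model$W1), W1_dim = dim(model$W1), b1 = model$b1,
    w2 = model$w2, b2 = model$b2,
    norm = model$norm, trained = model$trained,
    param_counts = as.list(model$param_counts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved with [save_model()]
#'
#' @param path JSON path.
#' @return An `mha_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(mha_config, obj$config[setdiff(names(obj$config), NULL)])
  model <- init_model(cfg, seed = cfg$seed)
  if (is.data.frame(obj$heads)) obj$heads <- split(obj$heads, seq_len(nrow(obj$heads)))
  for (h in seq_along(model$heads)) {
    hh <- if (is.list(obj$heads) && !is.null(obj$heads[[h]])) obj$heads[[h]] else obj$heads[h, ]
    model$heads[[h]]$W <- matrix(unlist(hh$W), nrow = unlist(hh$dim)[1])
    model$heads[[h]]$b <- as.numeric(unlist(hh$b))
  }
  model$W1 <- matrix(obj$W1, nrow = obj$W1_dim[1])
  model$b1 <- as.numeric(obj$b1)
  model$w2 <- as.numeric(obj$w2)
  model$b2 <- as.numeric(obj$b2)
  if (!is.null(obj$norm))
    model$norm <- list(mu = as.numeric(obj$norm$mu),
                       sigma = as.numeric(obj$norm$sigma))
  model$trained <- isTRUE(obj$trained)
  model
}
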