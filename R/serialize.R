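# Plain-text (JSON) checkpoints for encoders and task models, so trained
# artifacts survive a session without any binary format.

tokenizer_to_spec <- function(tokenizer) {
  if (tokenizer$name == "word") list(name = "word")
  else list(name = "chunk", width = tokenizer$width,
            atomic = tokenizer$atomic)
}

tokenizer_from_spec <- function(spec) {
  if (spec$name == "word") word_tokenizer()
  else chunk_tokenizer(spec$width, unlist(spec$atomic))
}

#' Save / load an encoder checkpoint
#'
#' Serializes a [tiny_encoder()] (vocabulary, dimensions and weights) as
#' JSON text.
#'
#' @param encoder A `tiny_encoder`.
#' @param path Checkpoint path.
#' @return `write_encoder`: `path`, invisibly. `read_encoder`: the
#'   restored encoder.
#' @export
write_encoder <- function(encoder, path) {
  stopifnot(inherits(encoder, "tiny_encoder"))
  obj <- list(kind = "tiny_encoder", vocab = encoder$vocab,
              dim = encoder$dim, recurrent = encoder$recurrent,
              params = lapply(encoder$params, function(p)
                list(nrow = nrow(p), data = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$kind, "tiny_encoder"))
  params <- lapply(obj$params, function(p)
    matrix(p$data, nrow = p$nrow))
  structure(list(vocab = obj$vocab, dim = as.integer(obj$dim),
                 recurrent = isTRUE(obj$recurrent), params = params),
            class = "tiny_encoder")
}

#' Save / load a token-classification model checkpoint
#'
#' Serializes a `cue_model` or `scope_model` (encoder, head weights,
#' scheme and tokenizer settings) as JSON text.
#'
#' @param model A `cue_model` or `scope_model`.
#' @param path Checkpoint path.
#' @return `write_model`: `path`, invisibly. `read_model`: the restored
#'   model.
#' @export
write_model <- function(model, path) {
  kind <- if (inherits(model, "cue_model")) "cue_model"
          else if (inherits(model, "scope_model")) "scope_model"
          else stop("model must be a cue_model or scope_model")
  obj <- list(kind = kind,
              encoder = list(vocab = model$encoder$vocab,
                             dim = model$encoder$dim,
                             recurrent = model$encoder$recurrent,
                             params = lapply(model$encoder$params,
                                             function(p) list(nrow = nrow(p),
                                                              data = as.numeric(p)))),
              W = list(nrow = nrow(model$W), data = as.numeric(model$W)),
              b = as.numeric(model$b),
              n_classes = model$n_classes,
              max_length = model$max_length,
              tokenizer = tokenizer_to_spec(model$tokenizer),
              scheme = if (kind == "cue_model") model$scheme$name else NULL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc <- structure(list(vocab = obj$encoder$vocab,
                        dim = as.integer(obj$encoder$dim),
                        recurrent = isTRUE(obj$encoder$recurrent),
                        params = lapply(obj$encoder$params, function(p)
                          matrix(p$data, nrow = p$nrow))),
                   class = "tiny_encoder")
  model <- list(encoder = enc,
                W = matrix(obj$W$data, nrow = obj$W$nrow),
                b = matrix(obj$b, nrow = 1L),
                n_classes = as.integer(obj$n_classes),
                max_length = as.integer(obj$max_length),
                tokenizer = tokenizer_from_spec(obj$tokenizer),
                config = NULL,
                history = data.frame(epoch = integer(0),
                                     loss = numeric(0)))
  if (identical(obj$kind, "cue_model")) {
    model$scheme <- cue_label_scheme(obj$scheme)
    class(model) <- "cue_model"
  } else class(model) <- "scope_model"
  model
}

#' Write a training-history CSV
#'
#' @param fit A `supertune_fit`, `cue_model` or `scope_model`.
#' @param path Output CSV path (columns epoch, loss).
#' @export
write_history <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
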