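#' Cue-detection label scheme
#'
#' Two token-classification schemes: `bioscope4` distinguishes negation
#' from speculation cues (0 padding, 1 normal word, 2 negation cue, 3
#' speculation cue); `sherlock3` merges them (0 padding, 1 normal word,
#' 2 cue).
#'
#' @param name `"bioscope4"` or `"sherlock3"`.
#' @return An object of class `cue_label_scheme`.
#' @export
cue_label_scheme <- function(name = c("bioscope4", "sherlock3")) {
  name <- match.arg(name)
  classes <- if (name == "bioscope4")
    c(padding = 0L, normal = 1L, negation_cue = 2L, speculation_cue = 3L)
  else c(padding = 0L, normal = 1L, cue = 2L)
  structure(list(name = name, classes = classes,
                 n_classes = length(classes)),
            class = "cue_label_scheme")
}

cue_class_for <- function(scheme, cue_type) {
  if (scheme$name == "bioscope4") {
    if (cue_type == "negation") 2L else 3L
  } else 2L
}

#' Encode word-level cue-detection labels
#'
#' Every word inside a cue span gets that cue's class; all other words
#' get 1 (normal word). For "This may not be a lesion" with a
#' speculation cue on "may" and a negation cue on "not", the `bioscope4`
#' labels are `1,3,2,1,1,1`.
#'
#' @param sentence An `annotated_sentence`.
#' @param scheme A [cue_label_scheme()].
#' @return Integer label vector, one per word.
#' @export
encode_cue_labels <- function(sentence, scheme = cue_label_scheme()) {
  validate_sentence(sentence)
  stopifnot(inherits(scheme, "cue_label_scheme"))
  labels <- rep(1L, length(sentence$words))
  for (cue in sentence$cues) {
    cls <- cue_class_for(scheme, cue$cue_type)
    idx <- (cue$start + 1L):cue$end
    clash <- labels[idx] != 1L & labels[idx] != cls
    if (any(clash))
      stop("overlapping cues of different types on word(s) ",
           paste(idx[clash] - 1L, collapse = ", "), " in sentence '",
           sentence$sentence_id, "'")
    labels[idx] <- cls
  }
  labels
}

#' Train a cue-detection model
#'
#' Fits a linear softmax token-classification head (and the encoder
#' underneath it) by cross-entropy on the word-level cue labels of an
#' annotated corpus. Padding, sentence-start/end and marker positions
#' are excluded from the objective. Fully seeded via `config$seed`.
#'
#' @param encoder A trainable encoder, see [tiny_encoder()].
#' @param sentences List of `annotated_sentence` objects.
#' @param scheme A [cue_label_scheme()].
#' @param config A [train_config()].
#' @param tokenizer Tokenizer contract object.
#' @param max_length Padded token-sequence length.
#' @return An object of class `cue_model`.
#' @export
train_cue_model <- function(encoder, sentences, scheme = cue_label_scheme(),
                            config = train_config(),
                            tokenizer = word_tokenizer(),
                            max_length = 128L) {
  stopifnot(inherits(scheme, "cue_label_scheme"))
  if (length(sentences) == 0L) stop("training corpus must be non-empty")
  examples <- lapply(sentences, function(s) {
    list(words = s$words, labels = encode_cue_labels(s, scheme),
         drop = rep(FALSE, length(s$words)))
  })
  fit <- train_token_classifier(encoder, examples, scheme$n_classes,
                                config, tokenizer, max_length)
  structure(c(fit, list(scheme = scheme)), class = "cue_model")
}

#' @export
print.cue_model <- function(x, ...) {
  cat("<cue_model: scheme ", x$scheme$name, ", dim ", x$encoder$dim,
      ", epochs ", x$config$epochs, ">\n", sep = "")
  if (nrow(x$history) > 0L)
    cat(sprintf("  loss %.4f -> %.4f\n", x$history$loss[1],
                x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Predict cues in a sentence
#'
#' Runs tokenize -> classify -> decode: per-token class probabilities
#' from the model, argmax post-processing back to one label per word,
#' then merging of consecutive words with the same cue class into cue
#' spans. Adjacent cues of different types stay separate spans.
#'
#' @param model A `cue_model`.
#' @param sentence Sentence text or character vector of words.
#' @return List with `labels` (integer per word) and `cues` (data frame
#'   of `type`, `start`, `end`; 0-based half-open spans).
#' @export
predict_cues <- function(model, sentence) {
  stopifnot(inherits(model, "cue_model"))
  words <- if (length(sentence) > 1L) as.character(sentence)
           else split_words(sentence)
  if (length(words) == 0L) stop("cannot predict on an empty sentence")
  cl <- classify_tokens(model, words)
  labels <- decode_predictions(cl$prob, cl$alignment)
  list(labels = labels, cues = cue_spans_from_labels(labels, model$scheme))
}

cue_spans_from_labels <- function(labels, scheme) {
  cue_classes <- scheme$classes[!names(scheme$classes) %in%
                                  c("padding", "normal")]
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values %in% cue_classes
  type_of <- function(v) {
    if (scheme$name == "bioscope4") {
      if (v == 2L) "negation" else "speculation"
    } else "cue"
  }
  data.frame(type = vapply(r$values[keep], type_of, ""),
             start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

#' @export
predict.cue_model <- function(object, newdata, ...) {
  if (length(newdata) == 1L) return(predict_cues(object, newdata))
  lapply(newdata, function(s) predict_cues(object, s))
}
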