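#' Expand a sentence into per-cue scope instances
#'
#' Scope resolution is trained per cue: a sentence with several cues
#' yields one instance per cue, with that cue wrapped in marker tokens
#' (`[NEG]` for negation, `[SPE]` for speculation, placed before the
#' first and after the last cue word) and binary per-word labels marking
#' the cue's scope. Following the labeling convention of the worked
#' examples, the cue words themselves are labeled 0 (out of scope) by
#' default; set `exclude_cue = FALSE` to keep the corpus convention of
#' scopes that include their cue.
#'
#' @param sentence An `annotated_sentence`; every cue must have a linked
#'   scope.
#' @param exclude_cue Zero out the cue's own words in the scope labels.
#' @return List of `scope_instance` objects with fields `parent_id`,
#'   `cue_ref`, `cue_type`, `marked_words` (words plus two markers),
#'   `is_marker` (logical over `marked_words`), `word_labels` (binary,
#'   one per original word).
#' @export
expand_instances <- function(sentence, exclude_cue = TRUE) {
  validate_sentence(sentence)
  lapply(sentence$cues, function(cue) {
    scope <- linked_scope(sentence, cue)
    if (is.null(scope))
      stop("cue '", cue$ref_id, "' in sentence '", sentence$sentence_id,
           "' has no linked scope")
    marker <- if (cue$cue_type == "negation") TOK_NEG else TOK_SPE
    w <- sentence$words
    marked <- append(append(w, marker, after = cue$end), marker,
                     after = cue$start)
    is_marker <- rep(FALSE, length(marked))
    is_marker[c(cue$start + 1L, cue$end + 2L)] <- TRUE
    labels <- rep(0L, length(w))
    labels[(scope$start + 1L):scope$end] <- 1L
    if (exclude_cue) labels[(cue$start + 1L):cue$end] <- 0L
    structure(list(parent_id = sentence$sentence_id, cue_ref = cue$ref_id,
                   cue_type = cue$cue_type, marked_words = marked,
                   is_marker = is_marker, word_labels = labels),
              class = "scope_instance")
  })
}

#' @export
print.scope_instance <- function(x, ...) {
  cat("<scope_instance ", x$parent_id, "/", x$cue_ref, " (", x$cue_type,
      ")>\n  ", paste(x$marked_words, collapse = " "), "\n  labels: [",
      paste(x$word_labels, collapse = ","), "]\n", sep = "")
  invisible(x)
}

#' Encode a scope instance for token classification
#'
#' Aligns the instance's binary word labels onto the subword token
#' sequence. The `[NEG]`/`[SPE]` markers are atomic vocabulary items
#' (never subword-split), carry token label 0 and are excluded from
#' decoded word labels; all other conventions follow [align_labels()].
#'
#' @param instance A `scope_instance`.
#' @param tokenizer Tokenizer contract object.
#' @param max_length Padded token-sequence length.
#' @return A `token_alignment`; decoding it yields one binary label per
#'   original (unmarked) word.
#' @export
encode_scope_labels <- function(instance, tokenizer = word_tokenizer(),
                                max_length = 128L) {
  stopifnot(inherits(instance, "scope_instance"))
  labels_marked <- integer(length(instance$marked_words))
  labels_marked[!instance$is_marker] <- instance$word_labels
  align_labels(instance$marked_words, labels_marked, tokenizer, max_length,
               drop_words = instance$is_marker)
}

#' Train a scope-resolution model
#'
#' Binary token classification (in scope / out of scope) over marked
#' per-cue instances, using the same harness as cue detection with two
#' classes. The marker tokens are part of the encoder vocabulary, so the
#' model can condition on the cue's position and type.
#'
#' @param encoder A trainable encoder whose vocabulary includes the
#'   `[NEG]`/`[SPE]` markers (see [build_vocab()]). A recurrent encoder
#'   is recommended: scope labels depend on context, not just the word.
#' @param instances List of `scope_instance` objects.
#' @param config A [train_config()].
#' @param tokenizer Tokenizer contract object.
#' @param max_length Padded token-sequence length.
#' @return An object of class `scope_model`.
#' @export
train_scope_model <- function(encoder, instances, config = train_config(),
                              tokenizer = word_tokenizer(),
                              max_length = 128L) {
  if (length(instances) == 0L) stop("training corpus must be non-empty")
  examples <- lapply(instances, function(inst) {
    labels <- integer(length(inst$marked_words))
    labels[!inst$is_marker] <- inst$word_labels
    list(words = inst$marked_words, labels = labels, drop = inst$is_marker)
  })
  fit <- train_token_classifier(encoder, examples, 2L, config, tokenizer,
                                max_length)
  structure(fit, class = "scope_model")
}

#' @export
print.scope_model <- function(x, ...) {
  cat("<scope_model: binary, dim ", x$encoder$dim, ", epochs ",
      x$config$epochs, ">\n", sep = "")
  if (nrow(x$history) > 0L)
    cat(sprintf("  loss %.4f -> %.4f\n", x$history$loss[1],
                x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Predict the scope of a marked cue
#'
#' Classifies each word of a marked sentence as in or out of scope and
#' collapses the prediction to one contiguous span: the longest
#' contiguous run of in-scope words (earliest run on ties). Marker
#' tokens are dropped from the output, so labels and span refer to the
#' original words.
#'
#' @param model A `scope_model`.
#' @param instance A `scope_instance`, or a marked sentence (text or word
#'   vector containing the `[NEG]`/`[SPE]` markers).
#' @return List with `labels` (binary, one per original word) and `span`
#'   (0-based half-open interval, or `NULL` when nothing is in scope).
#' @export
predict_scope <- function(model, instance) {
  stopifnot(inherits(model, "scope_model"))
  if (inherits(instance, "scope_instance")) {
    words <- instance$marked_words
    drop <- instance$is_marker
  } else {
    words <- if (length(instance) > 1L) as.character(instance)
             else split_words(instance)
    drop <- words %in% MARKER_TOKENS
  }
  if (length(words) == 0L) stop("cannot predict on an empty instance")
  cl <- classify_tokens(model, words, drop_words = drop)
  labels <- decode_predictions(cl$prob, cl$alignment)
  list(labels = labels, span = longest_run_span(labels))
}

# longest contiguous run of 1s as a 0-based half-open span; ties ->
# earliest; NULL when no 1s
longest_run_span <- function(labels) {
  r <- rle(labels == 1L)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  c(starts[best], ends[best])
}

#' @export
predict.scope_model <- function(object, newdata, ...) {
  if (inherits(newdata, "scope_instance") || length(newdata) == 1L)
    return(predict_scope(object, newdata))
  lapply(newdata, function(inst) predict_scope(object, inst))
}

#' Write scope instances as TSV
#'
#' Columns: parent sentence id, cue reference, marked sentence, and
#' space-joined binary labels.
#'
#' @param instances List of `scope_instance` objects.
#' @param path TSV path.
#' @export
write_instances <- function(instances, path) {
  d <- data.frame(
    parent_id = vapply(instances, `[[`, "", "parent_id"),
    cue_ref = vapply(instances, `[[`, "", "cue_ref"),
    marked_sentence = vapply(instances, function(x)
      paste(x$marked_words, collapse = " "), ""),
    labels = vapply(instances, function(x)
      paste(x$word_labels, collapse = " "), ""))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
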