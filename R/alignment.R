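TOK_CLS <- "[CLS]"
TOK_SEP <- "[SEP]"
TOK_PAD <- "[PAD]"
TOK_NEG <- "[NEG]"
TOK_SPE <- "[SPE]"
MARKER_TOKENS <- c(TOK_NEG, TOK_SPE)

#' Whole-word tokenizer
#'
#' The simplest tokenizer satisfying the tokenizer contract: every word is
#' one token. This reproduces the whole-word token arrays used in the
#' worked label-alignment examples.
#'
#' @return An object of class `nsr_tokenizer`.
#' @export
word_tokenizer <- function() {
  structure(list(
    name = "word",
    tokenize = function(words) {
      list(tokens = as.character(words), word_index = seq_along(words))
    }),
    class = "nsr_tokenizer")
}

#' Fixed-width chunking subword tokenizer
#'
#' A deterministic subword tokenizer for exercising word/subword label
#' alignment: words longer than `width` characters are split into chunks of
#' at most `width` characters, continuation chunks prefixed with `"##"`.
#' Tokens listed in `atomic` (by default the `[NEG]`/`[SPE]` scope markers)
#' are never split.
#'
#' @param width Maximum chunk width in characters.
#' @param atomic Character vector of tokens kept whole.
#' @return An object of class `nsr_tokenizer`.
#' @export
chunk_tokenizer <- function(width = 4L, atomic = MARKER_TOKENS) {
  width <- as.integer(width)
  stopifnot(width >= 1L)
  structure(list(
    name = "chunk", width = width, atomic = atomic,
    tokenize = function(words) {
      toks <- character(0); widx <- integer(0)
      for (i in seq_along(words)) {
        w <- words[[i]]
        if (w %in% atomic || nchar(w) <= width) {
          toks <- c(toks, w); widx <- c(widx, i)
        } else {
          starts <- seq(1L, nchar(w), by = width)
          parts <- substring(w, starts, pmin(starts + width - 1L, nchar(w)))
          parts[-1] <- paste0("##", parts[-1])
          toks <- c(toks, parts); widx <- c(widx, rep(i, length(parts)))
        }
      }
      list(tokens = toks, word_index = widx)
    }),
    class = "nsr_tokenizer")
}

#' Align word labels to subword tokens
#'
#' Expands a word-level label vector onto the subword token sequence with
#' the padding conventions used by the token-classification tasks:
#' sentence-start (`[CLS]`) and sentence-end (`[SEP]`) tokens get label 1
#' (normal word), every subword token inherits its word's label, and
#' `[PAD]` tokens filling the sequence to `max_length` get label 0. For
#' "This may not be a lump" with word labels `c(1,3,2,1,1,1)` and
#' `max_length = 12` the token labels are `1,1,3,2,1,1,1,1,0,0,0,0`.
#'
#' Words flagged in `drop_words` (the `[NEG]`/`[SPE]` scope markers) are
#' forced to token label 0 and excluded from decoding.
#'
#' @param words Character vector of words.
#' @param word_labels Integer labels, one per word.
#' @param tokenizer A tokenizer contract object, see [word_tokenizer()].
#' @param max_length Padded sequence length (tokens, including
#'   `[CLS]`/`[SEP]`). Sentences tokenizing longer than `max_length - 2`
#'   are truncated with a warning.
#' @param drop_words Logical vector, one per word; `TRUE` marks words (the
#'   marker tokens) excluded from labels and decoding.
#' @return An object of class `token_alignment` with fields `tokens`,
#'   `word_index` (1-based word index per token, `NA` at special, pad and
#'   dropped positions), `token_labels`, `n_words`, `dropped`.
#' @export
align_labels <- function(words, word_labels, tokenizer = word_tokenizer(),
                         max_length = 128L, drop_words = NULL) {
  if (length(words) == 0L) stop("words must be non-empty")
  if (length(word_labels) != length(words))
    stop("word_labels must have one label per word")
  if (is.null(drop_words)) drop_words <- rep(FALSE, length(words))
  stopifnot(length(drop_words) == length(words))
  max_length <- as.integer(max_length)
  if (max_length < 4L) stop("max_length too small")

  tk <- tokenizer$tokenize(words)
  n_tok <- length(tk$tokens)
  if (n_tok > max_length - 2L) {
    warning("sentence tokenizes to ", n_tok, " tokens; truncating to ",
            max_length - 2L)
    keep <- seq_len(max_length - 2L)
    tk$tokens <- tk$tokens[keep]
    tk$word_index <- tk$word_index[keep]
    n_tok <- max_length - 2L
  }

  lab <- word_labels[tk$word_index]
  lab[drop_words[tk$word_index]] <- 0L
  widx <- tk$word_index
  widx[drop_words[tk$word_index]] <- NA_integer_

  n_pad <- max_length - 2L - n_tok
  structure(list(
    tokens = c(TOK_CLS, tk$tokens, TOK_SEP, rep(TOK_PAD, n_pad)),
    word_index = c(NA_integer_, widx, NA_integer_,
                   rep(NA_integer_, n_pad)),
    token_labels = as.integer(c(1L, lab, 1L, rep(0L, n_pad))),
    n_words = length(words),
    dropped = drop_words,
    max_length = max_length),
    class = "token_alignment")
}

#' @export
print.token_alignment <- function(x, ...) {
  np <- sum(x$tokens == TOK_PAD)
  cat("<token_alignment: ", x$n_words, " words, ",
      length(x$tokens) - np, " tokens + ", np, " pads>\n", sep = "")
  cat(" tokens: ", paste(x$tokens[x$tokens != TOK_PAD], collapse = " "),
      "\n labels: [", paste(x$token_labels, collapse = ","), "]\n",
      sep = "")
  invisible(x)
}

#' Decode a per-token probability matrix to word labels
#'
#' Post-processing from token-classifier output back to one label per
#' word: per-row argmax (ties resolved to the lowest class index), first
#' subword wins for multi-token words, and sentence-start, sentence-end,
#' padding and marker positions are dropped. Column `j` of the matrix is
#' class `j - 1`.
#'
#' @param prob Numeric matrix; one row per token (rows must cover at least
#'   all non-pad tokens; trailing pad rows may be omitted), one column per
#'   class.
#' @param alignment A `token_alignment` from [align_labels()].
#' @return Integer vector of word labels, one per non-dropped word
#'   (`NA` for words lost to truncation).
#' @export
decode_predictions <- function(prob, alignment) {
  stopifnot(inherits(alignment, "token_alignment"))
  prob <- as.matrix(prob)
  n_nonpad <- sum(alignment$tokens != TOK_PAD)
  if (nrow(prob) < n_nonpad)
    stop("probability matrix has ", nrow(prob), " rows but ", n_nonpad,
         " non-pad tokens")
  tok_lab <- max.col(prob, ties.method = "first") - 1L
  out <- integer(0)
  for (w in seq_len(alignment$n_words)) {
    if (alignment$dropped[w]) next
    t1 <- which(alignment$word_index == w)[1]
    out <- c(out, if (is.na(t1)) NA_integer_ else tok_lab[t1])
  }
  out
}
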