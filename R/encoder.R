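# Desk-scale trainable sentence encoder: an embedding table with an
# optional Elman recurrent layer. Forward/backward passes and the Adam
# optimizer are written out explicitly so the Siamese objective and the
# token classifiers train on CPU in seconds. Any object implementing the
# generics below (token_vectors, enc_forward, enc_backward, enc_params,
# enc_set_params, token_ids) plugs into the same training code, so larger
# transformer backends can be adapted behind the same contract.

# run expr with a private RNG stream, restoring the caller's stream
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Build a token vocabulary from texts
#'
#' Collects the unique tokens produced by a tokenizer over a set of texts
#' and adds the unknown-word token plus any extra special tokens (by
#' default the `[NEG]`/`[SPE]` scope markers and the sentence
#' start/end/pad tokens, registered as atomic vocabulary items).
#'
#' @param texts Character vector of sentences (whitespace-tokenized into
#'   words before subword tokenization).
#' @param tokenizer Tokenizer contract object.
#' @param extra Additional tokens always present in the vocabulary.
#' @return Character vector of unique tokens; element 1 is `"<unk>"`.
#' @export
build_vocab <- function(texts, tokenizer = word_tokenizer(),
                        extra = c(TOK_CLS, TOK_SEP, TOK_PAD, MARKER_TOKENS)) {
  toks <- unlist(lapply(texts, function(tx) {
    w <- split_words(tx)
    if (length(w) == 0L) return(character(0))
    tokenizer$tokenize(w)$tokens
  }))
  unique(c("<unk>", extra, sort(unique(toks))))
}

split_words <- function(text) {
  if (length(text) == 0L) return(character(0))
  w <- strsplit(trimws(text), "\\s+")[[1]]
  w[nzchar(w)]
}

#' Small trainable encoder
#'
#' The reference encoder behind the encoder contract: a trainable
#' embedding table over a fixed vocabulary, optionally followed by a
#' forward Elman recurrent layer (`h_t = tanh(x_t W_x + h_{t-1} W_h + b)`)
#' so that token representations can depend on left context — needed for
#' scope resolution, where a word's label depends on the marked cue
#' earlier in the sentence. Output is one vector of dimension `dim` per
#' input token.
#'
#' @param vocab Character vector of tokens (see [build_vocab()]).
#' @param dim Embedding/hidden dimension (kept small; <= 64).
#' @param recurrent If `TRUE`, add the recurrent layer.
#' @param seed Seed for the random initialization.
#' @return An object of class `tiny_encoder`.
#' @export
tiny_encoder <- function(vocab, dim = 32L, recurrent = FALSE, seed = 1L) {
  dim <- as.integer(dim)
  stopifnot(dim >= 1L, dim <= 64L, length(vocab) >= 1L)
  if (!"<unk>" %in% vocab) vocab <- c("<unk>", vocab)
  local_seed(seed, {
    params <- list(E = matrix(stats::rnorm(length(vocab) * dim, sd = 0.25),
                              nrow = length(vocab), ncol = dim))
    if (recurrent) {
      sd0 <- 0.5 / sqrt(dim)
      params$Wx <- matrix(stats::rnorm(dim * dim, sd = sd0), dim, dim)
      params$Wh <- matrix(stats::rnorm(dim * dim, sd = sd0), dim, dim)
      params$b <- matrix(0, 1L, dim)
    }
    structure(list(vocab = vocab, dim = dim, recurrent = recurrent,
                   params = params),
              class = "tiny_encoder")
  })
}

#' @export
print.tiny_encoder <- function(x, ...) {
  cat("<tiny_encoder: |vocab| = ", length(x$vocab), ", dim = ", x$dim,
      if (x$recurrent) ", recurrent" else "", ">\n", sep = "")
  invisible(x)
}

#' Map tokens to vocabulary ids
#'
#' @param encoder An encoder object.
#' @param tokens Character vector of tokens; out-of-vocabulary tokens map
#'   to the `"<unk>"` id.
#' @return Integer ids.
#' @export
token_ids <- function(encoder, tokens) UseMethod("token_ids")

#' @export
token_ids.tiny_encoder <- function(encoder, tokens) {
  ids <- match(tokens, encoder$vocab)
  ids[is.na(ids)] <- 1L
  ids
}

#' Per-token vectors for a token sequence
#'
#' The encoder contract: a fixed-dimension vector per input token.
#'
#' @param encoder An encoder object.
#' @param tokens Character vector of tokens.
#' @return Numeric matrix, one row per token.
#' @export
token_vectors <- function(encoder, tokens) UseMethod("token_vectors")

#' @export
token_vectors.tiny_encoder <- function(encoder, tokens) {
  enc_forward(encoder, token_ids(encoder, tokens))$H
}

# -- training-side generics ------------------------------------------------

enc_forward <- function(encoder, ids) UseMethod("enc_forward")
enc_backward <- function(encoder, cache, dH) UseMethod("enc_backward")
enc_params <- function(encoder) UseMethod("enc_params")
enc_set_params <- function(encoder, params) UseMethod("enc_set_params")

#' @export
enc_forward.tiny_encoder <- function(encoder, ids) {
  X <- encoder$params$E[ids, , drop = FALSE]
  if (!encoder$recurrent)
    return(list(H = X, cache = list(ids = ids)))
  d <- encoder$dim
  Tn <- length(ids)
  H <- matrix(0, Tn, d)
  h <- matrix(0, 1L, d)
  for (t in seq_len(Tn)) {
    h <- tanh(X[t, , drop = FALSE] %*% encoder$params$Wx +
                h %*% encoder$params$Wh + encoder$params$b)
    H[t, ] <- h
  }
  list(H = H, cache = list(ids = ids, X = X, H = H))
}

#' @export
enc_backward.tiny_encoder <- function(encoder, cache, dH) {
  ids <- cache$ids
  g <- zero_grads(encoder)
  if (!encoder$recurrent) {
    for (t in seq_along(ids))
      g$E[ids[t], ] <- g$E[ids[t], ] + dH[t, ]
    return(g)
  }
  X <- cache$X; H <- cache$H
  d <- encoder$dim; Tn <- length(ids)
  dh_next <- matrix(0, 1L, d)
  for (t in rev(seq_len(Tn))) {
    dh <- dH[t, , drop = FALSE] + dh_next
    dpre <- dh * (1 - H[t, ]^2)
    h_prev <- if (t > 1L) H[t - 1L, , drop = FALSE] else matrix(0, 1L, d)
    g$b <- g$b + dpre
    g$Wx <- g$Wx + t(X[t, , drop = FALSE]) %*% dpre
    g$Wh <- g$Wh + t(h_prev) %*% dpre
    dx <- dpre %*% t(encoder$params$Wx)
    g$E[ids[t], ] <- g$E[ids[t], ] + dx
    dh_next <- dpre %*% t(encoder$params$Wh)
  }
  g
}

#' @export
enc_params.tiny_encoder <- function(encoder) encoder$params

#' @export
enc_set_params.tiny_encoder <- function(encoder, params) {
  encoder$params <- params
  encoder
}

zero_grads <- function(encoder) {
  lapply(enc_params(encoder), function(p) p * 0)
}

# -- Adam optimizer over a named list of numeric arrays --------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Pool a sentence into one embedding vector
#'
#' Whitespace-splits the sentence into words, runs the tokenizer and the
#' encoder, and mean-pools the per-token vectors (no padding tokens are
#' ever fed, so the mean is over real tokens only).
#'
#' @param encoder An encoder object implementing [token_vectors()].
#' @param sentence Sentence text (or a character vector of words).
#' @param tokenizer Tokenizer contract object.
#' @return Numeric vector of length `encoder dim`.
#' @export
embed_sentence <- function(encoder, sentence, tokenizer = word_tokenizer()) {
  words <- if (length(sentence) > 1L) as.character(sentence)
           else split_words(sentence)
  if (length(words) == 0L) stop("cannot embed an empty sentence")
  H <- token_vectors(encoder, tokenizer$tokenize(words)$tokens)
  if (is.null(dim(H)) || nrow(H) == 0L)
    stop("encoder produced no token vectors")
  colMeans(H)
}
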