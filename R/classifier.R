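# Shared token-classification harness for the cue and scope tasks: a
# linear softmax head over the encoder's per-token vectors, trained with
# cross-entropy on word tokens only (padding, sentence start/end and the
# [NEG]/[SPE] markers are excluded from the objective), optimized with
# Adam. Examples are lists with elements words, labels and drop (logical
# marker mask).

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

train_token_classifier <- function(encoder, examples, n_classes, config,
                                   tokenizer = word_tokenizer(),
                                   max_length = 128L) {
  stopifnot(inherits(config, "train_config"))
  if (length(examples) == 0L) stop("training corpus must be non-empty")
  for (ex in examples)
    if (any(ex$labels[!ex$drop] >= n_classes | ex$labels[!ex$drop] < 0L))
      stop("labels exceed the ", n_classes, "-class scheme")

  prep <- lapply(examples, function(ex) {
    al <- align_labels(ex$words, ex$labels, tokenizer, max_length,
                       drop_words = ex$drop)
    nonpad <- al$tokens != TOK_PAD
    list(tokens = al$tokens[nonpad],
         labels = al$token_labels[nonpad],
         mask = !is.na(al$word_index[nonpad]))
  })

  d <- encoder$dim
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  fit_env <- local_seed(config$seed, {
    W <- matrix(stats::rnorm(d * n_classes, sd = 0.25), d, n_classes)
    bh <- matrix(0, 1L, n_classes)
    params <- c(enc_params(encoder), list(.W = W, .b = bh))
    opt <- adam_init(params)
    enc_names <- names(enc_params(encoder))
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(prep))
      losses <- numeric(0)
      for (batch in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        grads <- c(zero_grads(encoder), list(.W = W * 0, .b = bh * 0))
        bl <- 0
        for (i in batch) {
          px <- prep[[i]]
          ids <- token_ids(encoder, px$tokens)
          fw <- enc_forward(encoder, ids)
          logits <- fw$H %*% params$.W +
            matrix(params$.b, nrow(fw$H), n_classes, byrow = TRUE)
          P <- softmax_rows(logits)
          m <- which(px$mask)
          if (length(m) == 0L) next
          lab1 <- px$labels[m] + 1L
          bl <- bl - sum(log(pmax(P[cbind(m, lab1)], 1e-12))) / length(m)
          dlogits <- matrix(0, nrow(P), n_classes)
          dlogits[m, ] <- P[m, , drop = FALSE]
          dlogits[cbind(m, lab1)] <- dlogits[cbind(m, lab1)] - 1
          dlogits <- dlogits / (length(m) * length(batch))
          grads$.W <- grads$.W + t(fw$H) %*% dlogits
          grads$.b <- grads$.b + colSums(dlogits)
          dH <- dlogits %*% t(params$.W)
          ge <- enc_backward(encoder, fw$cache, dH)
          for (nm in enc_names) grads[[nm]] <- grads[[nm]] + ge[[nm]]
        }
        losses <- c(losses, bl / length(batch))
        step <- adam_step(params, grads, opt, config$lr)
        params <- step$params; opt <- step$state
        encoder <- enc_set_params(encoder, params[enc_names])
      }
      history[ep, ] <- list(ep, mean(losses))
    }
    list(encoder = encoder, W = params$.W, b = params$.b)
  })

  list(encoder = fit_env$encoder, W = fit_env$W, b = fit_env$b,
       n_classes = n_classes, tokenizer = tokenizer,
       max_length = as.integer(max_length), config = config,
       history = history)
}

# per-token class probabilities for a word sequence; returns the
# alignment and the probability matrix over its non-pad tokens
classify_tokens <- function(model, words, drop_words = NULL) {
  al <- align_labels(words, rep(1L, length(words)), model$tokenizer,
                     model$max_length, drop_words = drop_words)
  nonpad <- al$tokens != TOK_PAD
  ids <- token_ids(model$encoder, al$tokens[nonpad])
  H <- enc_forward(model$encoder, ids)$H
  logits <- H %*% model$W +
    matrix(model$b, nrow(H), model$n_classes, byrow = TRUE)
  list(alignment = al, prob = softmax_rows(logits))
}
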