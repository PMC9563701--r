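#' Cosine similarity between two embeddings
#'
#' `cos(theta) = sum(u_i v_i) / (||u|| ||v||)`, clamped to `[-1, 1]`
#' against floating-point overshoot. This is the similarity head of the
#' Siamese objective; pair scores are regressed against it.
#'
#' @param u,v Numeric vectors of equal dimension, both with non-zero norm.
#' @return A scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v))
    stop("u and v must have the same dimension")
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("embeddings must be finite")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity undefined for a zero-norm vector")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Mean squared error between predicted similarities and pair scores
#'
#' `(1/n) * sum((cos_i - Y_i)^2)` where `Y_i` is the target similarity
#' score of pair `i` (one of -1, 0, 1).
#'
#' @param predictions Numeric vector of predicted cosine similarities.
#' @param targets Numeric vector of target scores, same length.
#' @return Non-negative scalar; 0 iff predictions equal targets.
#' @export
mse_loss <- function(predictions, targets) {
  if (length(predictions) != length(targets))
    stop("predictions and targets must have equal length")
  if (length(predictions) < 1L) stop("need at least one prediction")
  mean((as.numeric(predictions) - as.numeric(targets))^2)
}

#' Training configuration
#'
#' @param lr Learning rate. The default matches the conventional
#'   transformer fine-tuning rate; from-scratch runs of the small
#'   reference encoder want a much larger value (around 0.05).
#' @param batch_size Pairs (or sentences) per gradient step.
#' @param epochs Passes over the training data.
#' @param seed Seed controlling shuffling and any initialization drawn
#'   inside training.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 2e-5, batch_size = 16L, epochs = 10L,
                         seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1L, epochs >= 0L)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "train_config")
}

# gradient of cosine(u, v) wrt u (and by symmetry v)
dcos_du <- function(u, v, cs, nu, nv) v / (nu * nv) - cs * u / nu^2

#' Super-tune an encoder on scored sentence pairs
#'
#' The Siamese similarity objective: both sentences of each pair pass
#' through one shared encoder, per-token vectors are mean-pooled into
#' sentence embeddings `u` and `v`, and the squared error between
#' `cos(u, v)` and the pair's target score (-1 opposite polarity, 0
#' unrelated, 1 equivalent) is minimized by gradient descent (Adam).
#' Training is fully seeded: the same configuration and seed reproduce
#' the same loss history and weights. `epochs = 0` returns the encoder
#' unchanged with an empty history.
#'
#' @param encoder A trainable encoder, see [tiny_encoder()].
#' @param pairs Data frame with columns `text_a`, `text_b`, `score`.
#' @param config A [train_config()].
#' @param tokenizer Tokenizer contract object.
#' @return An object of class `supertune_fit` with components `encoder`
#'   (trained), `encoder_init`, `history` (data frame of epoch and mean
#'   training loss), `config`, `tokenizer` and `pairs`.
#' @export
supertune <- function(encoder, pairs, config = train_config(),
                      tokenizer = word_tokenizer()) {
  stopifnot(inherits(config, "train_config"))
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 1L) stop("pairs must contain at least one sentence pair")
  if (!all(c("text_a", "text_b", "score") %in% names(pairs)))
    stop("pairs needs columns text_a, text_b, score")

  tok_cache <- lapply(seq_len(nrow(pairs)), function(i) {
    list(a = tokenizer$tokenize(split_words(pairs$text_a[i]))$tokens,
         b = tokenizer$tokenize(split_words(pairs$text_b[i]))$tokens)
  })
  y <- as.numeric(pairs$score)
  init <- encoder
  history <- data.frame(epoch = integer(0), loss = numeric(0))

  if (config$epochs > 0L) local_seed(config$seed, {
    params <- enc_params(encoder)
    opt <- adam_init(params)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(nrow(pairs))
      losses <- numeric(0)
      for (batch in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        grads <- zero_grads(encoder)
        bl <- 0
        for (i in batch) {
          ids_a <- token_ids(encoder, tok_cache[[i]]$a)
          ids_b <- token_ids(encoder, tok_cache[[i]]$b)
          fa <- enc_forward(encoder, ids_a)
          fb <- enc_forward(encoder, ids_b)
          u <- colMeans(fa$H); v <- colMeans(fb$H)
          nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
          if (nu == 0 || nv == 0) stop("zero-norm sentence embedding")
          cs <- sum(u * v) / (nu * nv)
          cs_cl <- min(1, max(-1, cs))
          bl <- bl + (cs_cl - y[i])^2
          dls <- 2 * (cs_cl - y[i]) / length(batch)
          du <- dls * dcos_du(u, v, cs, nu, nv)
          dv <- dls * dcos_du(v, u, cs, nv, nu)
          ga <- enc_backward(encoder, fa$cache,
                             matrix(du, nrow = nrow(fa$H), ncol = length(du),
                                    byrow = TRUE) / nrow(fa$H))
          gb <- enc_backward(encoder, fb$cache,
                             matrix(dv, nrow = nrow(fb$H), ncol = length(dv),
                                    byrow = TRUE) / nrow(fb$H))
          for (nm in names(grads))
            grads[[nm]] <- grads[[nm]] + ga[[nm]] + gb[[nm]]
        }
        losses <- c(losses, bl / length(batch))
        step <- adam_step(params, grads, opt, config$lr)
        params <- step$params; opt <- step$state
        encoder <- enc_set_params(encoder, params)
      }
      history[ep, ] <- list(ep, mean(losses))
    }
  })

  structure(list(encoder = encoder, encoder_init = init, history = history,
                 config = config, tokenizer = tokenizer, pairs = pairs),
            class = "supertune_fit")
}

#' @export
print.supertune_fit <- function(x, ...) {
  cat("Siamese super-tuning fit\n")
  cat("  pairs: ", nrow(x$pairs), " (scores: ",
      paste(names(table(x$pairs$score)), table(x$pairs$score),
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  epochs:", x$config$epochs, " lr:", x$config$lr,
      " batch:", x$config$batch_size, "\n")
  if (nrow(x$history) > 0L)
    cat(sprintf("  loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
                x$history$loss[1], x$history$loss[nrow(x$history)],
                nrow(x$history)))
  invisible(x)
}

#' @export
predict.supertune_fit <- function(object, newdata = object$pairs, ...) {
  newdata <- as.data.frame(newdata)
  vapply(seq_len(nrow(newdata)), function(i) {
    cosine_similarity(
      embed_sentence(object$encoder, newdata$text_a[i], object$tokenizer),
      embed_sentence(object$encoder, newdata$text_b[i], object$tokenizer))
  }, numeric(1))
}

#' @export
summary.supertune_fit <- function(object, ...) {
  cs <- predict(object)
  agg <- stats::aggregate(cs, list(score = object$pairs$score), mean)
  names(agg)[2] <- "mean_cosine"
  structure(list(history = object$history, class_means = agg),
            class = "summary.supertune_fit")
}

#' @export
print.summary.supertune_fit <- function(x, ...) {
  cat("Mean predicted cosine by target score:\n")
  print(x$class_means, row.names = FALSE)
  if (nrow(x$history) > 0L) {
    cat("Loss history (first/last):\n")
    print(x$history[unique(c(1L, nrow(x$history))), ], row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.supertune_fit <- function(x, ...) {
  if (nrow(x$history) == 0L) {
    warning("no training history to plot")
    return(invisible(x))
  }
  plot(x$history$epoch, x$history$loss, type = "b", xlab = "epoch",
       ylab = "mean training loss", main = "Super-tuning loss", ...)
  invisible(x)
}

#' Embedding separation before and after super-tuning
#'
#' For every sentence pair, computes cosine similarity and Euclidean
#' distance under two encoders (typically before and after super-tuning),
#' summarizes the means per target-score class, and reports the
#' after-minus-before deltas. A successful run drives the mean cosine of
#' opposite-polarity pairs down and orders the classes 1 > 0 > -1.
#'
#' @param encoder_before,encoder_after Encoder objects.
#' @param pairs Data frame with `text_a`, `text_b`, `score`.
#' @param tokenizer Tokenizer contract object.
#' @return An object of class `separation_report`: `pairs` (per-pair
#'   statistics) and `summary` (per-class means and deltas).
#' @export
separation_report <- function(encoder_before, encoder_after, pairs,
                              tokenizer = word_tokenizer()) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 1L) stop("pairs must be non-empty")
  one <- function(enc, i) {
    u <- embed_sentence(enc, pairs$text_a[i], tokenizer)
    v <- embed_sentence(enc, pairs$text_b[i], tokenizer)
    c(cos = cosine_similarity(u, v), euclid = sqrt(sum((u - v)^2)))
  }
  per <- t(vapply(seq_len(nrow(pairs)), function(i) {
    c(one(encoder_before, i), one(encoder_after, i))
  }, numeric(4)))
  per_df <- data.frame(pair = seq_len(nrow(pairs)), score = pairs$score,
                       cos_before = per[, 1], euclid_before = per[, 2],
                       cos_after = per[, 3], euclid_after = per[, 4])
  agg <- stats::aggregate(
    per_df[, c("cos_before", "cos_after", "euclid_before", "euclid_after")],
    list(score = per_df$score), mean)
  agg$delta_cos <- agg$cos_after - agg$cos_before
  agg$delta_euclid <- agg$euclid_after - agg$euclid_before
  structure(list(pairs = per_df, summary = agg), class = "separation_report")
}

#' @export
print.separation_report <- function(x, digits = 4, ...) {
  cat("Embedding separation by target score (means over",
      nrow(x$pairs), "pairs):\n")
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a separation report to CSV
#'
#' @param report A `separation_report`.
#' @param path Output CSV path (per-pair rows).
#' @export
write_separation_report <- function(report, path) {
  stopifnot(inherits(report, "separation_report"))
  utils::write.csv(report$pairs, path, row.names = FALSE)
  invisible(path)
}
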