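test_that("cue labels follow the four-class scheme on the flow example", {
  s <- worked_sentence("lesion")
  expect_equal(encode_cue_labels(s, cue_label_scheme("bioscope4")),
               c(1, 3, 2, 1, 1, 1))
  expect_equal(encode_cue_labels(s, cue_label_scheme("sherlock3")),
               c(1, 2, 2, 1, 1, 1))
  plain <- annotated_sentence("p", c("all", "perfectly", "normal"))
  expect_equal(encode_cue_labels(plain), c(1, 1, 1))
})

test_that("multi-word cues label every cue word", {
  s <- annotated_sentence(
    "m", c("the", "scan", "shows", "edema", "rather", "than", "a", "lump"),
    cues = list(cue_annotation("negation", 4, 6, "x1")),
    scopes = list(scope_annotation("x1", 4, 8)))
  expect_equal(encode_cue_labels(s), c(1, 1, 1, 1, 2, 2, 1, 1))
})

test_that("conflicting cue types on one word are an integrity error", {
  s <- worked_sentence()
  s$cues <- list(cue_annotation("speculation", 1, 3, "x1"),
                 cue_annotation("negation", 2, 3, "x2"))
  expect_error(encode_cue_labels(s), "overlapping")
})

test_that("training reduces loss and is reproducible per seed", {
  g <- tiny_corpus(n = 40, seed = 12, neg = 0.4, spe = 0.3)
  enc <- tiny_encoder(build_vocab(corpus_texts(g$gold)), dim = 16, seed = 3)
  cfg <- train_config(lr = 0.02, epochs = 5, seed = 3)
  m1 <- train_cue_model(enc, g$gold, cue_label_scheme(), cfg,
                        max_length = 32)
  expect_lt(m1$history$loss[5], m1$history$loss[1])
  m2 <- train_cue_model(enc, g$gold, cue_label_scheme(), cfg,
                        max_length = 32)
  s <- g$gold[[1]]
  expect_identical(predict_cues(m1, s$words), predict_cues(m2, s$words))
  expect_error(train_cue_model(enc, list(), cue_label_scheme(), cfg),
               "non-empty")
})

test_that("an untrained head still produces shape-valid predictions", {
  g <- tiny_corpus(n = 5, seed = 2)
  enc <- tiny_encoder(build_vocab(corpus_texts(g$gold)), dim = 8, seed = 1)
  m <- train_cue_model(enc, g$gold, cue_label_scheme(),
                       train_config(epochs = 0), max_length = 32)
  for (s in g$gold) {
    out <- predict_cues(m, s$words)
    expect_length(out$labels, length(s$words))
    expect_true(all(out$labels %in% 0:3))
  }
  expect_error(predict_cues(m, "  "), "empty")
})

test_that("predicted label runs merge into typed cue spans", {
  g <- tiny_corpus(n = 5, seed = 2)
  enc <- tiny_encoder(build_vocab(corpus_texts(g$gold)), dim = 8, seed = 1)
  m <- train_cue_model(enc, g$gold, cue_label_scheme(),
                       train_config(epochs = 0), max_length = 32)
  spans <- negscope:::cue_spans_from_labels(c(1, 3, 2, 1, 1, 1), m$scheme)
  expect_equal(spans$type, c("speculation", "negation"))
  expect_equal(spans$start, c(1, 2))
  expect_equal(spans$end, c(2, 3))
  # same class across adjacent words merges; different classes do not
  spans2 <- negscope:::cue_spans_from_labels(c(2, 2, 3, 3, 1), m$scheme)
  expect_equal(nrow(spans2), 2)
  expect_equal(spans2$end - spans2$start, c(2, 2))
  expect_equal(nrow(negscope:::cue_spans_from_labels(rep(1, 6),
                                                     m$scheme)), 0)
})

test_that("a tiny model memorizes a 20-sentence corpus perfectly", {
  g <- tiny_corpus(n = 20, seed = 4, neg = 0.5, spe = 0.5)
  enc <- tiny_encoder(build_vocab(corpus_texts(g$gold)), dim = 32,
                      seed = 2)
  m <- train_cue_model(enc, g$gold, cue_label_scheme(),
                       train_config(lr = 0.02, epochs = 30, seed = 2),
                       max_length = 32)
  gold <- lapply(g$gold, encode_cue_labels)
  pred <- lapply(g$gold, function(s) predict_cues(m, s$words)$labels)
  expect_equal(mean(unlist(pred) == unlist(gold)), 1.0)
  # span merge then re-encode is idempotent on model output
  for (i in seq_along(g$gold)) {
    sp <- predict_cues(m, g$gold[[i]]$words)$cues
    relab <- rep(1L, length(g$gold[[i]]$words))
    for (k in seq_len(nrow(sp)))
      relab[(sp$start[k] + 1):sp$end[k]] <-
        if (sp$type[k] == "negation") 2L else 3L
    expect_equal(relab, pred[[i]])
  }
})

test_that("cue models survive a checkpoint round trip", {
  g <- tiny_corpus(n = 10, seed = 5)
  enc <- tiny_encoder(build_vocab(corpus_texts(g$gold)), dim = 8, seed = 1)
  m <- train_cue_model(enc, g$gold, cue_label_scheme("sherlock3"),
                       train_config(lr = 0.02, epochs = 2, seed = 1),
                       max_length = 32)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_s3_class(back, "cue_model")
  expect_equal(back$scheme$name, "sherlock3")
  s <- g$gold[[3]]
  expect_equal(predict_cues(back, s$words), predict_cues(m, s$words))
})
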