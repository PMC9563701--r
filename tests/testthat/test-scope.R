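test_that("per-cue expansion reproduces both printed instances", {
  s <- worked_sentence("lump")
  inst <- expand_instances(s)
  expect_length(inst, 2)
  expect_equal(paste(inst[[1]]$marked_words, collapse = " "),
               "This [SPE] may [SPE] not be a lump")
  expect_equal(inst[[1]]$word_labels, c(0, 0, 1, 1, 1, 1))
  expect_equal(paste(inst[[2]]$marked_words, collapse = " "),
               "This may [NEG] not [NEG] be a lump")
  expect_equal(inst[[2]]$word_labels, c(0, 0, 0, 1, 1, 1))
  expect_equal(inst[[1]]$cue_type, "speculation")
  expect_equal(inst[[2]]$cue_type, "negation")
})

test_that("instance counts equal cue counts; broken links are errors", {
  expect_length(expand_instances(annotated_sentence("p", c("all", "good"))),
                0)
  s3 <- annotated_sentence(
    "t", c("it", "may", "not", "be", "benign", "perhaps"),
    cues = list(cue_annotation("speculation", 1, 2, "x1"),
                cue_annotation("negation", 2, 3, "x2"),
                cue_annotation("speculation", 5, 6, "x3")),
    scopes = list(scope_annotation("x1", 1, 6),
                  scope_annotation("x2", 2, 5),
                  scope_annotation("x3", 5, 6)))
  expect_length(expand_instances(s3), 3)
  broken <- worked_sentence()
  broken$scopes <- broken$scopes[1]
  expect_error(expand_instances(broken), "no linked scope")
  g <- tiny_corpus(n = 15, seed = 3)
  for (s in g$gold)
    expect_length(expand_instances(s), length(s$cues))
})

test_that("multi-word cues get markers around the whole cue span", {
  s <- annotated_sentence(
    "m", c("the", "scan", "shows", "edema", "rather", "than", "a", "lump"),
    cues = list(cue_annotation("negation", 4, 6, "x1")),
    scopes = list(scope_annotation("x1", 4, 8)))
  inst <- expand_instances(s)[[1]]
  expect_equal(paste(inst$marked_words, collapse = " "),
               "the scan shows edema [NEG] rather than [NEG] a lump")
  expect_equal(inst$word_labels, c(0, 0, 0, 0, 0, 0, 1, 1))
  with_cue <- expand_instances(s, exclude_cue = FALSE)[[1]]
  expect_equal(with_cue$word_labels, c(0, 0, 0, 0, 1, 1, 1, 1))
})

test_that("scope label encoding decodes back to per-original-word labels", {
  s <- worked_sentence("lump")
  inst <- expand_instances(s)
  al <- encode_scope_labels(inst[[2]], word_tokenizer(), max_length = 16)
  nonpad <- sum(al$tokens != "[PAD]")
  expect_equal(decode_predictions(one_hot_rows(al$token_labels[seq_len(nonpad)], 2),
                                  al),
               c(0, 0, 0, 1, 1, 1))
  # markers carry token label 0 and never reach the decoded output
  expect_equal(al$token_labels[al$tokens == "[NEG]"], c(0, 0))
  g <- tiny_corpus(n = 10, seed = 8)
  for (tok in list(word_tokenizer(), chunk_tokenizer(3))) {
    for (s2 in g$gold) for (inst2 in expand_instances(s2)) {
      al2 <- encode_scope_labels(inst2, tok, max_length = 48)
      np <- sum(al2$tokens != "[PAD]")
      dec <- decode_predictions(one_hot_rows(al2$token_labels[seq_len(np)], 2),
                                al2)
      expect_equal(dec, inst2$word_labels)
      expect_false(any(al2$tokens[seq_len(np)] %in% c("[NEG]", "[SPE]") &
                         !is.na(al2$word_index[seq_len(np)])))
    }
  }
})

test_that("gold labels form one contiguous block matching the scope span", {
  g <- tiny_corpus(n = 20, seed = 14)
  for (s in g$gold) for (inst in expand_instances(s)) {
    runs <- rle(inst$word_labels)
    expect_equal(sum(runs$values == 1), 1)
  }
})

test_that("predicted scopes collapse to the longest earliest run of 1s", {
  expect_equal(negscope:::longest_run_span(c(0, 1, 1, 0, 1, 0)), c(1, 3))
  expect_equal(negscope:::longest_run_span(c(1, 1, 0, 1, 1)), c(0, 2))
  expect_null(negscope:::longest_run_span(rep(0, 5)))
})

test_that("a tiny recurrent model memorizes 20 scope instances", {
  g <- tiny_corpus(n = 20, seed = 4, neg = 0.5, spe = 0.5)
  insts <- unlist(lapply(g$gold, expand_instances), recursive = FALSE)
  expect_length(insts, 20)
  enc <- tiny_encoder(build_vocab(corpus_texts(g$gold)), dim = 32,
                      recurrent = TRUE, seed = 3)
  m <- train_scope_model(enc, insts,
                         train_config(lr = 0.02, epochs = 30, seed = 3),
                         max_length = 32)
  gold <- lapply(insts, `[[`, "word_labels")
  pred <- lapply(insts, function(i) predict_scope(m, i)$labels)
  expect_equal(mean(unlist(pred) == unlist(gold)), 1.0)
  # predicted spans equal the gold scope blocks on the memorized set
  gold_spans <- lapply(gold, negscope:::longest_run_span)
  pred_spans <- lapply(insts, function(i) predict_scope(m, i)$span)
  expect_equal(exact_span_match(gold_spans, pred_spans), 1.0)
  expect_error(predict_scope(m, character(0)), "empty")
})

test_that("end-to-end: predicted cues feed scope instances that match gold", {
  g <- tiny_corpus(n = 20, seed = 4, neg = 0.5, spe = 0.5)
  vocab <- build_vocab(corpus_texts(g$gold))
  cm <- train_cue_model(tiny_encoder(vocab, dim = 32, seed = 2), g$gold,
                        cue_label_scheme(),
                        train_config(lr = 0.02, epochs = 30, seed = 2),
                        max_length = 32)
  insts <- unlist(lapply(g$gold, expand_instances), recursive = FALSE)
  sm <- train_scope_model(tiny_encoder(vocab, dim = 32, recurrent = TRUE,
                                       seed = 3),
                          insts,
                          train_config(lr = 0.02, epochs = 30, seed = 3),
                          max_length = 32)
  for (s in g$gold) {
    if (length(s$cues) == 0) next
    found <- predict_cues(cm, s$words)$cues
    expect_equal(nrow(found), length(s$cues))
    det <- annotated_sentence(
      s$sentence_id, s$words,
      cues = lapply(seq_len(nrow(found)), function(k)
        cue_annotation(found$type[k], found$start[k], found$end[k],
                       paste0("d", k))),
      scopes = lapply(seq_len(nrow(found)), function(k)
        scope_annotation(paste0("d", k), found$start[k],
                         length(s$words))))
    for (i in seq_along(det$cues)) {
      pred <- predict_scope(sm, expand_instances(det)[[i]])
      gold_inst <- expand_instances(s)[[i]]
      expect_equal(pred$labels, gold_inst$word_labels)
    }
  }
})

test_that("scope instances serialize to TSV", {
  insts <- expand_instances(worked_sentence())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_instances(insts, path)
  d <- utils::read.delim(path)
  expect_equal(nrow(d), 2)
  expect_equal(d$labels[2], "0 0 0 1 1 1")
})
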