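# Shared fixtures, all built in code.

# the six-word flow example: speculation cue on word 2, negation cue on
# word 3, scopes running from each cue to the end of the sentence
worked_sentence <- function(last_word = "lump") {
  annotated_sentence(
    "w1", c("This", "may", "not", "be", "a", last_word),
    cues = list(cue_annotation("speculation", 1, 2, "x1"),
                cue_annotation("negation", 2, 3, "x2")),
    scopes = list(scope_annotation("x1", 1, 6),
                  scope_annotation("x2", 2, 6)))
}

# the printed nine-row per-token class-probability matrix for
# [CLS] This may not be a lump [SEP] [PAD]
worked_prob_matrix <- function() {
  matrix(c(0.02, 0.95, 0.02, 0.01,
           0.01, 0.95, 0.01, 0.03,
           0.00, 0.04, 0.00, 0.96,
           0.01, 0.03, 0.95, 0.01,
           0.00, 0.96, 0.02, 0.02,
           0.02, 0.95, 0.02, 0.01,
           0.02, 0.96, 0.02, 0.01,
           0.02, 0.97, 0.02, 0.00,
           0.00, 0.98, 0.01, 0.01),
         ncol = 4, byrow = TRUE)
}

# one-hot probability rows for a token-label vector (n_classes columns)
one_hot_rows <- function(labels, n_classes) {
  P <- matrix(0, length(labels), n_classes)
  P[cbind(seq_along(labels), labels + 1L)] <- 1
  P
}

# small seeded generated corpus; returns list(xml, gold)
tiny_corpus <- function(n = 20, seed = 4, neg = 0.5, spe = 0.5) {
  generate_corpus(template_bank(), n, negation_fraction = neg,
                  speculation_fraction = spe, seed = seed)
}

corpus_texts <- function(gold)
  vapply(gold, function(s) paste(s$words, collapse = " "), "")

# hand-written BioScope-dialect XML: "It is not a lump", cue "not"
# scoping "not a lump"
hand_xml <- paste0(
  "<corpus><sentence id=\"h1\">It is ",
  "<xcope id=\"x1\"><cue type=\"negation\" ref=\"x1\">not</cue>",
  " a lump</xcope></sentence></corpus>")

# Sherlock-style CoNLL fixture writer; returns the file path
write_sherlock_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".conll",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
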