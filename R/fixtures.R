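# Synthetic corpus generation. Templates emulate the shape of annotated
# biomedical findings sentences: a subject noun phrase, a reporting verb
# and an object noun phrase, with negation/speculation transforms that
# record the cue they insert and the scope span it creates (scope runs
# from the cue word to the end of the sentence, the corpus convention for
# annotated scopes). Everything is seeded and byte-reproducible.

SYNONYMS <- list(
  shows = c("demonstrates", "displays", "exhibits"),
  show = c("demonstrate", "display", "exhibit"),
  reveals = c("depicts", "demonstrates", "displays"),
  scan = c("image", "study"),
  biopsy = c("specimen", "sample"),
  culture = c("isolate", "swab"),
  assay = c("test", "measurement"),
  radiograph = c("film", "x-ray"),
  smear = c("slide", "preparation"),
  lesion = c("abnormality", "anomaly"),
  lump = c("mass", "swelling"),
  nodule = c("growth", "focus"),
  infiltrate = c("opacity", "shadow"),
  effusion = c("collection", "fluid"),
  mutation = c("variant", "alteration"),
  effect = c("impact", "influence"),
  committee = c("board", "panel"),
  approved = c("endorsed", "accepted"),
  protocol = c("procedure", "plan"),
  yesterday = c("recently", "earlier"),
  laboratory = c("facility", "unit"),
  software = c("program", "application"),
  questionnaire = c("survey", "form"))

NEUTRAL_TAILS <- c("indeed", "overall", "notably", "additionally",
                   "furthermore", "likewise", "reportedly", "evidently")

# words that flip or hedge polarity; the paraphraser never touches them
POLARITY_WORDS <- c("not", "no", "nor", "never", "without", "may", "might",
                    "suggests", "suggest", "possibly", "rather", "than")

#' Default template bank for the synthetic corpus generator
#'
#' Affirmative subject/verb/object templates with negation and
#' speculation transforms. Each transform records the cue word(s) it
#' inserts and the scope span it creates; one negation transform uses the
#' multi-word cue "rather than". Also carries the unrelated-sentence pool
#' used for score-0 pairs.
#'
#' @return An object of class `template_bank`.
#' @export
template_bank <- function() {
  structure(list(
    subjects = list(c("the", "scan"), c("the", "biopsy"),
                    c("the", "culture"), c("the", "assay"),
                    c("the", "radiograph"), c("the", "smear")),
    objects = list(c("a", "lesion"), c("a", "lump"), c("an", "infiltrate"),
                   c("a", "nodule"), c("an", "effusion"), c("a", "mutation")),
    frames = c("shows", "reveals", "ratherthan"),
    unrelated = c("the committee approved the protocol yesterday",
                  "funding for the registry was renewed",
                  "the laboratory hired two new technicians",
                  "the software update improved file export",
                  "patients received the questionnaire by mail",
                  "the annual meeting moved to the spring"),
    synonyms = SYNONYMS),
    class = "template_bank")
}

# render one sentence; polarity in {"affirmative","negation","speculation"};
# returns list(words, cue_type, cue_span, scope_span) with NULL annotations
# for affirmatives. Indices are drawn from the caller's RNG stream.
render_template <- function(bank, polarity) {
  frame <- bank$frames[[sample.int(length(bank$frames), 1L)]]
  s <- bank$subjects[[sample.int(length(bank$subjects), 1L)]]
  oi <- sample.int(length(bank$objects), 2L)
  o <- bank$objects[[oi[1]]]; o2 <- bank$objects[[oi[2]]]
  ns <- length(s)
  mk <- function(words, type = NULL, cue = NULL) {
    scope <- if (is.null(cue)) NULL else c(cue[1], length(words))
    list(words = words, cue_type = type, cue_span = cue, scope_span = scope)
  }
  if (frame == "shows") {
    switch(polarity,
      affirmative = mk(c(s, "shows", o)),
      negation = mk(c(s, "does", "not", "show", o), "negation",
                    c(ns + 1L, ns + 2L)),
      speculation = mk(c(s, "may", "show", o), "speculation",
                       c(ns, ns + 1L)))
  } else if (frame == "reveals") {
    switch(polarity,
      affirmative = mk(c(s, "reveals", o)),
      negation = mk(c(s, "reveals", "no", o[length(o)]), "negation",
                    c(ns + 1L, ns + 2L)),
      speculation = mk(c(s, "suggests", o), "speculation", c(ns, ns + 1L)))
  } else {
    switch(polarity,
      affirmative = mk(c(s, "shows", o)),
      negation = mk(c(s, "shows", o, "rather", "than", o2), "negation",
                    c(ns + 1L + length(o), ns + 3L + length(o))),
      speculation = mk(c(s, "might", "show", o), "speculation",
                       c(ns, ns + 1L)))
  }
}

#' Generate a synthetic BioScope-dialect corpus with gold annotations
#'
#' Draws `n_sentences` template sentences with the requested fractions of
#' negation and speculation sentences (exact counts, rounded), serializes
#' them as BioScope-dialect XML and returns the XML together with the
#' gold annotations it encodes. The XML parses under [read_bioscope()]
#' to exactly the gold list; the same seed gives byte-identical output.
#'
#' @param bank A [template_bank()].
#' @param n_sentences Number of sentences (>= 1).
#' @param negation_fraction,speculation_fraction Fractions of sentences
#'   carrying a negation / speculation cue; non-negative, sum <= 1.
#' @param seed Integer seed.
#' @param sub_corpus Sub-corpus tag recorded in the gold annotations.
#' @return List with components `xml` (character scalar) and `gold`
#'   (list of `annotated_sentence`).
#' @export
generate_corpus <- function(bank, n_sentences, negation_fraction = 0.3,
                            speculation_fraction = 0.2, seed = 1L,
                            sub_corpus = "full_papers") {
  stopifnot(inherits(bank, "template_bank"))
  if (length(bank$frames) == 0L || length(bank$subjects) == 0L)
    stop("template bank is empty")
  if (n_sentences < 1L) stop("n_sentences must be >= 1")
  if (negation_fraction < 0 || speculation_fraction < 0 ||
      negation_fraction + speculation_fraction > 1)
    stop("fractions must be in [0,1] and sum to at most 1")
  n_neg <- round(n_sentences * negation_fraction)
  n_spe <- min(round(n_sentences * speculation_fraction),
               n_sentences - n_neg)
  gold <- local_seed(seed, {
    pol <- sample(c(rep("negation", n_neg), rep("speculation", n_spe),
                    rep("affirmative", n_sentences - n_neg - n_spe)))
    lapply(seq_len(n_sentences), function(i) {
      r <- render_template(bank, pol[i])
      cues <- list(); scopes <- list()
      if (!is.null(r$cue_span)) {
        cues <- list(cue_annotation(r$cue_type, r$cue_span[1],
                                    r$cue_span[2], "x1"))
        scopes <- list(scope_annotation("x1", r$scope_span[1],
                                        r$scope_span[2]))
      }
      annotated_sentence(paste0("s", i), r$words, cues, scopes, sub_corpus)
    })
  })
  list(xml = as.character(write_bioscope(gold)), gold = gold)
}

#' Deterministic stub paraphraser
#'
#' Produces `k` variants of a sentence by seeded synonym substitution
#' from a fixed dictionary, falling back to appending neutral adverbs
#' when the substitution space is too small. Negation and speculation cue
#' words are never inserted, deleted or replaced, so the polarity of the
#' input is preserved by construction. Serves as the test-time
#' implementation of the paraphrase contract (production paraphrasers
#' implement the same signature).
#'
#' @param sentence Non-empty sentence text.
#' @param k Number of variants (>= 1).
#' @param seed Integer seed; same arguments give identical output.
#' @return Character vector of `k` variants, pairwise distinct except for
#'   degenerate inputs (one-word sentences, flagged with a warning).
#' @export
stub_paraphrase <- function(sentence, k = 4L, seed = 1L) {
  if (length(sentence) != 1L || !nzchar(trimws(sentence)))
    stop("sentence must be a single non-empty string")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  words <- split_words(sentence)
  if (length(words) == 1L) {
    warning("one-word sentence; distinctness of variants waived")
    return(rep(sentence, k))
  }
  subst <- vapply(words, function(w) tolower(w) %in% names(SYNONYMS) &&
                    !tolower(w) %in% POLARITY_WORDS, logical(1))
  local_seed(seed, {
    variants <- character(0)
    attempts <- 0L
    while (length(variants) < k && attempts < 60L * k) {
      attempts <- attempts + 1L
      cand <- words
      for (j in which(subst)) {
        opts <- SYNONYMS[[tolower(words[j])]]
        pick <- sample.int(length(opts) + 1L, 1L)
        if (pick <= length(opts)) cand[j] <- opts[pick]
      }
      text <- paste(cand, collapse = " ")
      if (text != sentence && !text %in% variants)
        variants <- c(variants, text)
    }
    for (tail in sample(NEUTRAL_TAILS)) {
      if (length(variants) >= k) break
      text <- paste(c(words, tail), collapse = " ")
      if (text != sentence && !text %in% variants)
        variants <- c(variants, text)
    }
    if (length(variants) < k) {
      warning("could not produce ", k, " distinct variants; recycling")
      variants <- rep_len(c(variants, sentence), k)
    }
    variants[seq_len(k)]
  })
}

#' Generate a balanced scored sentence-pair corpus
#'
#' Builds `n_pairs_per_class` pairs for each similarity score: -1
#' (a negated template sentence against its affirmative counterpart), 1
#' (a sentence against its stub paraphrase) and 0 (a sentence against a
#' draw from the unrelated pool). Class labels are correct by
#' construction and the class balance is exact.
#'
#' @param bank A [template_bank()].
#' @param n_pairs_per_class Pairs per score class (>= 1).
#' @param seed Integer seed.
#' @return Data frame of sentence pairs (see [build_pairs()]).
#' @export
generate_pair_corpus <- function(bank, n_pairs_per_class, seed = 1L) {
  stopifnot(inherits(bank, "template_bank"))
  if (n_pairs_per_class < 1L) stop("n_pairs_per_class must be >= 1")
  if (length(bank$unrelated) < 2L)
    stop("unrelated pool must contain at least 2 sentences")
  local_seed(seed, {
    negated <- lapply(seq_len(n_pairs_per_class), function(i) {
      # draw the polarity pair from one template rendering so the two
      # sides differ only by the negation transform
      frame <- bank$frames[[sample.int(length(bank$frames), 1L)]]
      s <- bank$subjects[[sample.int(length(bank$subjects), 1L)]]
      oi <- sample.int(length(bank$objects), 2L)
      o <- bank$objects[[oi[1]]]; o2 <- bank$objects[[oi[2]]]
      if (frame == "shows")
        c(paste(c(s, "does", "not", "show", o), collapse = " "),
          paste(c(s, "shows", o), collapse = " "))
      else if (frame == "reveals")
        c(paste(c(s, "reveals", "no", o[length(o)]), collapse = " "),
          paste(c(s, "reveals", o), collapse = " "))
      else
        c(paste(c(s, "shows", o, "rather", "than", o2), collapse = " "),
          paste(c(s, "shows", o), collapse = " "))
    })
    equivalents <- lapply(seq_len(n_pairs_per_class), function(i) {
      r <- render_template(bank, "affirmative")
      txt <- paste(r$words, collapse = " ")
      c(txt, stub_paraphrase(txt, 1L, seed = seed + i))
    })
    build_pairs(negated, bank$unrelated, equivalents,
                seed = seed + 104729L)
  })
}
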