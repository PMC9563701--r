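# Scored sentence-pair corpus: the training data for the Siamese
# objective. Pairs live in a plain data frame with columns pair_id,
# text_a, text_b, score (-1 opposite polarity, 0 unrelated, 1
# equivalent), provenance (original/augmented) and parent_id (the
# originating pair for augmented rows).

new_pair_df <- function(text_a, text_b, score, provenance, parent_id = NA,
                        id_prefix = "p", id_offset = 0L) {
  n <- length(text_a)
  stopifnot(length(text_b) == n, length(score) == n)
  if (any(!nzchar(text_a)) || any(!nzchar(text_b)))
    stop("pair texts must be non-empty")
  score <- as.integer(score)
  if (!all(score %in% c(-1L, 0L, 1L)))
    stop("scores must be in {-1, 0, 1}")
  data.frame(pair_id = paste0(id_prefix, seq_len(n) + id_offset),
             text_a = as.character(text_a), text_b = as.character(text_b),
             score = score,
             provenance = rep_len(provenance, n),
             parent_id = rep_len(as.character(parent_id), n),
             stringsAsFactors = FALSE)
}

# lowercase, collapse internal whitespace, strip terminal punctuation
normalize_text <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\s+", " ", x)
  gsub("[.!?]+$", "", x)
}

#' Build a scored sentence-pair corpus
#'
#' Applies the three scoring rules: a negated sentence paired with its
#' affirmative counterpart gets score -1 (same topic, opposite
#' polarity), a sentence paired with a meaning-equivalent paraphrase gets
#' score 1, and each negated sentence crossed with a seeded draw from the
#' unrelated pool gets score 0 (different context). All output rows have
#' provenance `"original"`.
#'
#' @param negated List of length-2 character vectors (or a 2-column data
#'   frame): the negated sentence and its affirmative counterpart,
#'   aligned 1:1.
#' @param unrelated_pool Character vector of unrelated sentences.
#' @param paraphrase_equivalents List of length-2 character vectors (or
#'   2-column data frame): a sentence and its equivalent.
#' @param seed Seed for the unrelated-pool draws.
#' @return Data frame of pairs, one row per pair, scores balanced as
#'   `length(negated)` each of -1 and 0 plus
#'   `length(paraphrase_equivalents)` of 1.
#' @export
build_pairs <- function(negated, unrelated_pool,
                        paraphrase_equivalents = list(), seed = 1L) {
  as_two_col <- function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)),
                                 function(i) c(x[i, 1], x[i, 2]))
    else x
  }
  negated <- as_two_col(negated)
  paraphrase_equivalents <- as_two_col(paraphrase_equivalents)
  if (length(negated) == 0L) stop("negated list must be non-empty")
  if (length(unrelated_pool) < 1L) stop("unrelated_pool must be non-empty")
  neg_a <- vapply(negated, `[[`, "", 1L)
  neg_b <- vapply(negated, `[[`, "", 2L)
  eq_a <- vapply(paraphrase_equivalents, `[[`, "", 1L)
  eq_b <- vapply(paraphrase_equivalents, `[[`, "", 2L)
  zero_b <- local_seed(seed, vapply(neg_a, function(s) {
    pool <- setdiff(unrelated_pool, s)
    if (length(pool) == 0L)
      stop("unrelated pool only contains the sentence itself")
    pool[sample.int(length(pool), 1L)]
  }, "", USE.NAMES = FALSE))
  new_pair_df(c(neg_a, eq_a, neg_a),
              c(neg_b, eq_b, zero_b),
              c(rep(-1L, length(neg_a)), rep(1L, length(eq_a)),
                rep(0L, length(neg_a))),
              "original")
}

#' Augment a pair corpus with paraphrase variants
#'
#' For every input pair, paraphrases both sides `k` times and emits `k`
#' new pairs carrying the parent's score (paraphrasing preserves
#' polarity, so the score is conserved by construction). Originals are
#' returned alongside the augmented pairs. With `dedupe`, augmented
#' pairs identical (after normalization) to their parent or to any other
#' emitted pair are dropped.
#'
#' @param pairs Pair data frame (see [build_pairs()]).
#' @param paraphraser Function `(sentence, k, seed) -> k variants`
#'   satisfying the paraphrase contract; defaults to [stub_paraphrase()].
#' @param k New pairs per input pair (>= 1; the corpus recipe uses 4).
#' @param dedupe Drop exact duplicates and parent copies.
#' @param seed Integer seed.
#' @return Data frame: original pairs followed by augmented pairs with
#'   `provenance = "augmented"` and `parent_id` set.
#' @export
augment_pairs <- function(pairs, paraphraser = stub_paraphrase, k = 4L,
                          dedupe = TRUE, seed = 1L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) stop("pairs must be non-empty")
  aug <- list()
  for (i in seq_len(nrow(pairs))) {
    va <- paraphraser(pairs$text_a[i], k, seed + 2L * i)
    vb <- paraphraser(pairs$text_b[i], k, seed + 2L * i + 1L)
    aug[[i]] <- new_pair_df(va, vb, rep(pairs$score[i], k), "augmented",
                            parent_id = pairs$pair_id[i],
                            id_prefix = paste0(pairs$pair_id[i], "a"))
  }
  aug <- do.call(rbind, aug)
  if (dedupe) {
    key <- paste(normalize_text(aug$text_a), normalize_text(aug$text_b),
                 aug$score, sep = "\r")
    parent_key <- paste(normalize_text(pairs$text_a),
                        normalize_text(pairs$text_b), pairs$score,
                        sep = "\r")
    aug <- aug[!duplicated(key) & !key %in% parent_key, , drop = FALSE]
  }
  out <- rbind(pairs, aug)
  rownames(out) <- NULL
  out
}

#' Split a pair corpus into train/dev/test
#'
#' Seeded, grouped partition: all augmented children of a pair are
#' assigned to the same split as their parent, so no paraphrase of a
#' training pair can leak into dev or test. Group order is shuffled with
#' the seed, then groups fill train, dev and test up to the target pair
#' counts.
#'
#' @param pairs Pair data frame.
#' @param proportions Positive train/dev/test proportions summing to 1.
#' @param seed Integer seed.
#' @return Named list of data frames `train`, `dev`, `test`; disjoint and
#'   exhaustive.
#' @export
split_pairs <- function(pairs, proportions = c(0.70, 0.15, 0.15),
                        seed = 1L) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 3L) stop("need at least 3 pairs to split")
  if (length(proportions) != 3L || any(proportions <= 0) ||
      abs(sum(proportions) - 1) > 1e-8)
    stop("proportions must be 3 positive values summing to 1")
  root <- ifelse(is.na(pairs$parent_id) | pairs$parent_id == "NA",
                 pairs$pair_id, pairs$parent_id)
  groups <- split(seq_len(nrow(pairs)), root)
  ord <- local_seed(seed, sample.int(length(groups)))
  groups <- groups[ord]
  n <- nrow(pairs)
  target_train <- floor(proportions[1] * n)
  target_dev <- floor(proportions[2] * n)
  assign_split <- character(length(groups))
  count <- c(train = 0L, dev = 0L)
  for (gi in seq_along(groups)) {
    sz <- length(groups[[gi]])
    if (count["train"] + sz <= target_train) {
      assign_split[gi] <- "train"; count["train"] <- count["train"] + sz
    } else if (count["dev"] + sz <= target_dev) {
      assign_split[gi] <- "dev"; count["dev"] <- count["dev"] + sz
    } else assign_split[gi] <- "test"
  }
  take <- function(which_split) {
    idx <- sort(unlist(groups[assign_split == which_split],
                       use.names = FALSE))
    out <- pairs[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(train = take("train"), dev = take("dev"), test = take("test"))
}

#' Check for sentence leakage between super-tuning and fine-tuning data
#'
#' Returns the set of normalized sentence texts (lowercased, whitespace
#' collapsed, terminal punctuation stripped) appearing in both
#' collections. An empty result means the two stages share no data.
#'
#' @param supertune_texts Character vector of sentences, or a pair data
#'   frame (both text columns are used), or a list of
#'   `annotated_sentence` objects.
#' @param finetune_texts Same forms as `supertune_texts`.
#' @return Sorted character vector of shared normalized sentences
#'   (empty when the collections are disjoint).
#' @export
leakage_check <- function(supertune_texts, finetune_texts) {
  collect <- function(x) {
    if (is.data.frame(x)) c(x$text_a, x$text_b)
    else if (is.list(x))
      vapply(x, function(s)
        if (inherits(s, "annotated_sentence"))
          paste(s$words, collapse = " ") else as.character(s), "")
    else as.character(x)
  }
  sort(intersect(unique(normalize_text(collect(supertune_texts))),
                 unique(normalize_text(collect(finetune_texts)))))
}

#' Write / read a pair corpus as TSV
#'
#' Three data columns (`sentence_a`, `sentence_b`, `score`) plus
#' provenance bookkeeping columns.
#'
#' @param pairs Pair data frame.
#' @param path TSV path.
#' @return `write_pairs`: `path`, invisibly. `read_pairs`: the pair data
#'   frame.
#' @export
write_pairs <- function(pairs, path) {
  out <- data.frame(sentence_a = pairs$text_a, sentence_b = pairs$text_b,
                    score = pairs$score, provenance = pairs$provenance,
                    pair_id = pairs$pair_id, parent_id = pairs$parent_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sentence_a", "sentence_b", "score")
  if (!all(need %in% names(d)))
    stop("pair TSV needs columns ", paste(need, collapse = ", "))
  data.frame(
    pair_id = if ("pair_id" %in% names(d)) d$pair_id
              else paste0("p", seq_len(nrow(d))),
    text_a = d$sentence_a, text_b = d$sentence_b,
    score = as.integer(d$score),
    provenance = if ("provenance" %in% names(d)) d$provenance
                 else "original",
    parent_id = if ("parent_id" %in% names(d)) as.character(d$parent_id)
                else NA_character_,
    stringsAsFactors = FALSE)
}
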