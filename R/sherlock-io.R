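#' Read a Sherlock-style CoNLL negation corpus
#'
#' Reads the *SEM-2012 column layout: one token per line; sentences
#' separated by blank lines. The leading columns are chapter name,
#' sentence number, token number, word, lemma, part-of-speech and syntax;
#' after them comes either a single placeholder column (`"***"`, no
#' negation in the sentence) or one `(cue, scope, event)` column triple
#' per cue, with `"_"` marking unannotated cells. Each triple yields one
#' cue and one scope annotation; a triple whose scope cells are all empty
#' gets the cue span as its scope.
#'
#' @param path Path to the CoNLL file.
#' @param n_meta_cols Number of leading non-annotation columns (7 in the
#'   standard layout; configurable for dialects with extra columns).
#' @param word_col Column holding the word form.
#' @param placeholder Placeholder string used when a sentence has no
#'   annotation columns.
#' @param cue_type Cue type assigned to every cue (the Sherlock corpus is
#'   negation-only).
#' @param sub_corpus Sub-corpus tag for all sentences from this file.
#' @return List of `annotated_sentence` objects.
#' @export
read_sherlock <- function(path, n_meta_cols = 7L, word_col = 4L,
                          placeholder = "***", cue_type = "negation",
                          sub_corpus = "unknown") {
  lines <- readLines(path, warn = FALSE)
  blank <- !nzchar(trimws(lines))
  block_id <- cumsum(c(TRUE, blank[-length(blank)]))
  blocks <- split(lines[!blank], block_id[!blank])
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    rows <- strsplit(trimws(blocks[[bi]]), "[ \t]+")
    ncols <- lengths(rows)
    if (length(unique(ncols)) != 1L)
      stop("ragged column counts in sentence block ", bi, " (",
           paste(sort(unique(ncols)), collapse = " vs "), " columns)")
    nc <- ncols[1]
    if (nc < word_col)
      stop("sentence block ", bi, " has fewer than ", word_col, " columns")
    mat <- do.call(rbind, rows)
    words <- mat[, word_col]
    sid <- paste0(mat[1, 1], "_", mat[1, 2])
    cues <- list(); scopes <- list()
    anno <- nc - n_meta_cols
    has_placeholder <- anno == 1L && all(mat[, n_meta_cols + 1L] == placeholder)
    if (anno > 0L && !has_placeholder) {
      if (anno %% 3L != 0L)
        stop("sentence block ", bi, " has ", anno,
             " annotation columns; expected a multiple of 3")
      for (k in seq_len(anno %/% 3L)) {
        cue_col <- mat[, n_meta_cols + 3L * (k - 1L) + 1L]
        scope_col <- mat[, n_meta_cols + 3L * (k - 1L) + 2L]
        cue_rows <- which(cue_col != "_")
        if (length(cue_rows) == 0L) next
        scope_rows <- which(scope_col != "_")
        if (length(scope_rows) == 0L) scope_rows <- cue_rows
        rid <- paste0("x", k)
        cues <- c(cues, list(cue_annotation(
          cue_type, min(cue_rows) - 1L, max(cue_rows), rid)))
        scopes <- c(scopes, list(scope_annotation(
          rid, min(scope_rows) - 1L, max(scope_rows))))
      }
    }
    out[[bi]] <- annotated_sentence(sid, words, cues, scopes, sub_corpus)
  }
  out
}
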